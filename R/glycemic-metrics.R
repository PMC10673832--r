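#' Time in range
#'
#' Percent of non-missing CGM samples in a day window lying inside
#' `[low, high]` (bounds inclusive). The conventional target band is
#' 70-180 mg/dL for people with T2D and the tighter 70-140 mg/dL for
#' people without diabetes.
#'
#' @param trace A [glucose_trace()].
#' @param days Integer vector of program days forming the window.
#' @param low,high Range bounds in mg/dL.
#' @return Percent in \[0, 100\].
#' @export
time_in_range <- function(trace, days, low = 70, high = 140) {
  v <- trace$values[trace_window(trace, days)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no CGM data in the requested window")
  100 * mean(v >= low & v <= high)
}

#' Glucose management indicator
#'
#' Linear estimate of laboratory HbA1c from mean CGM glucose using the
#' consensus mapping `GMI(%) = 3.31 + 0.02392 * mean(mg/dL)`; the
#' coefficients are exposed so alternative calibrations can be swapped in.
#'
#' @inheritParams time_in_range
#' @param intercept,slope Calibration coefficients.
#' @return GMI in percent.
#' @export
gmi <- function(trace, days, intercept = 3.31, slope = 0.02392) {
  v <- trace$values[trace_window(trace, days)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no CGM data in the requested window")
  intercept + slope * mean(v)
}

#' Glycemic excursion events per day
#'
#' An event is a maximal run of at least `min_samples` consecutive
#' non-missing samples beyond the threshold; runs whose separating interval
#' is shorter than `merge_gap_min` minutes are merged before counting
#' (a single transient dip below threshold does not split an excursion).
#' The per-day rate is adjusted for CGM signal loss: events are divided by
#' `window days * (1 - lost-time fraction)`, so a half-sampled day with one
#' observed event reports two events per day.
#'
#' @inheritParams time_in_range
#' @param threshold Threshold in mg/dL.
#' @param direction `"above"` counts hyperglycemic excursions
#'   (`value > threshold`), `"below"` hypoglycemic ones
#'   (`value < threshold`).
#' @param min_samples Minimum consecutive beyond-threshold samples that
#'   constitute an event (default 2).
#' @param merge_gap_min Runs separated by less than this many minutes are
#'   merged (default 30).
#' @return Events per day, lost-time adjusted.
#' @export
count_events <- function(trace, days, threshold,
                         direction = c("above", "below"),
                         min_samples = 2, merge_gap_min = 30) {
  direction <- match.arg(direction)
  idx <- trace_window(trace, days)
  if (!length(idx)) stop("window does not overlap the trace")
  v <- trace$values[idx]
  lost <- mean(is.na(v))
  if (lost >= 1) stop("window has no CGM data (lost time = 1)")
  beyond <- !is.na(v) & if (direction == "above") v > threshold else
    v < threshold
  pos <- which(beyond)
  n_events <- 0L
  if (length(pos)) {
    # maximal runs of consecutive slots, then merge runs whose separating
    # interval (slots strictly between them) is shorter than merge_gap_min
    run_id <- cumsum(c(1L, diff(pos) > 1L))
    starts <- tapply(pos, run_id, min)
    ends <- tapply(pos, run_id, max)
    if (length(starts) > 1) {
      sep_min <- (starts[-1] - ends[-length(ends)] - 1) * trace$step_min
      grp <- cumsum(c(1L, sep_min >= merge_gap_min))
    } else {
      grp <- 1L
    }
    sizes <- tapply(ends - starts + 1, grp, sum)
    n_events <- sum(sizes >= min_samples)
  }
  n_events / (length(days) * (1 - lost))
}

#' Glycemic variability as coefficient of variation
#'
#' `100 * sample SD / mean` over the window's non-missing samples.
#'
#' @inheritParams time_in_range
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(trace, days) {
  v <- trace$values[trace_window(trace, days)]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 non-missing samples")
  100 * stats::sd(v) / mean(v)
}

#' Glycemic summary for one analysis window
#'
#' Assembles the CGM outcome metrics for one participant and window. Time
#' in range uses 70-180 mg/dL for T2D and 70-140 mg/dL otherwise; event
#' rates cover the standard thresholds (>140, >180, >250, <70 mg/dL) and
#' are lost-time adjusted; mean-based metrics (TIR, GMI, CV) use only
#' non-missing samples and need no such adjustment.
#'
#' @param record A [participant_record()].
#' @param days Integer vector of program days forming the window.
#' @param category Glycemic category; defaults to the record's own.
#' @return A one-row data frame of class `glycemic_summary` with `tir_pct`,
#'   `gmi_pct`, `mean_glucose`, `cv_pct`, `events_140`, `events_180`,
#'   `events_250`, `events_70`, and `lost_time_fraction`.
#' @export
summarize_glycemia <- function(record, days, category = record$category) {
  trace <- record$glucose
  rng <- if (identical(category, "T2D")) c(70, 180) else c(70, 140)
  v <- trace$values[trace_window(trace, days)]
  out <- data.frame(
    id = record$id, category = category,
    tir_pct = time_in_range(trace, days, rng[1], rng[2]),
    gmi_pct = gmi(trace, days),
    mean_glucose = mean(v, na.rm = TRUE),
    cv_pct = coefficient_of_variation(trace, days),
    events_140 = count_events(trace, days, 140, "above"),
    events_180 = count_events(trace, days, 180, "above"),
    events_250 = count_events(trace, days, 250, "above"),
    events_70 = count_events(trace, days, 70, "below"),
    lost_time_fraction = mean(is.na(v)))
  class(out) <- c("glycemic_summary", "data.frame")
  out
}

#' Baseline and end summaries for a cohort
#'
#' @param cohort List of [participant_record()]s.
#' @param windows An [analysis_windows()] pair.
#' @return Data frame with one row per participant per window (`window`
#'   column is `"baseline"` or `"end"`).
#' @export
cohort_glycemic_summaries <- function(cohort, windows = analysis_windows()) {
  do.call(rbind, lapply(cohort, function(r) {
    rbind(cbind(window = "baseline",
                summarize_glycemia(r, windows$baseline)),
          cbind(window = "end", summarize_glycemia(r, windows$end)))
  }))
}

metric_cols <- c("tir_pct", "gmi_pct", "mean_glucose", "cv_pct",
                 "events_140", "events_180", "events_250", "events_70")

#' Subgroup mean changes, baseline versus end
#'
#' Forms subgroups on baseline values only - all participants, suboptimal
#' control (`baseline TIR < 90%`), poor control (`baseline TIR < 70%`),
#' elevated GMI (`> 6%` and `> 7%`) - and reports the mean end-minus-
#' baseline change of every metric per subgroup, overall and per glycemic
#' category. Empty subgroups are reported as absent rows, not zeros.
#'
#' @param summaries Output of [cohort_glycemic_summaries()].
#' @return Data frame with columns `subgroup`, `category` (`"all"` plus
#'   each glycemic category), `n`, and `d_<metric>` mean deltas.
#' @export
subgroup_deltas <- function(summaries) {
  base <- summaries[summaries$window == "baseline", ]
  end <- summaries[summaries$window == "end", ]
  end <- end[match(base$id, end$id), ]
  defs <- list(
    all = rep(TRUE, nrow(base)),
    tir_lt90 = base$tir_pct < 90,
    tir_lt70 = base$tir_pct < 70,
    gmi_gt6 = base$gmi_pct > 6,
    gmi_gt7 = base$gmi_pct > 7)
  rows <- list()
  for (sg in names(defs)) {
    for (cat in c("all", "healthy", "prediabetes", "T2D")) {
      sel <- defs[[sg]] & (cat == "all" | base$category == cat)
      if (!any(sel)) next
      deltas <- end[sel, metric_cols] - base[sel, metric_cols]
      row <- data.frame(subgroup = sg, category = cat, n = sum(sel))
      row[paste0("d_", metric_cols)] <- colMeans(deltas)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
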