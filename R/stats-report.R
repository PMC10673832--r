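#' Paired baseline-versus-end comparison
#'
#' Classic paired t-test on per-participant deltas with a normality check
#' (Shapiro-Wilk on the deltas at alpha 0.05, reported as a flag only; a
#' log-transformation hook exists but is off by default, mirroring
#' analyses where no variable required transformation). Zero-variance
#' deltas are reported with an explicit `degenerate` flag instead of a
#' test statistic.
#'
#' @param baseline,end Equal-length numeric vectors paired by participant.
#' @param metric Optional metric label carried into the output.
#' @param log_transform Apply `log` to both vectors before testing.
#' @return One-row data frame: `metric`, `n`, `mean_baseline`, `mean_end`,
#'   `mean_delta`, `t`, `df`, `p`, `normality_p`, `normal`, `degenerate`.
#' @export
paired_t <- function(baseline, end, metric = "", log_transform = FALSE) {
  if (length(baseline) != length(end)) stop("vectors must be paired")
  keep <- !is.na(baseline) & !is.na(end)
  baseline <- baseline[keep]
  end <- end[keep]
  n <- length(baseline)
  if (n < 2) stop("need at least 2 pairs")
  if (log_transform) {
    baseline <- log(baseline)
    end <- log(end)
  }
  delta <- end - baseline
  norm_p <- if (n >= 3 && n <= 5000 && stats::sd(delta) > 0) {
    stats::shapiro.test(delta)$p.value
  } else NA_real_
  if (stats::sd(delta) == 0) {
    return(data.frame(metric = metric, n = n,
                      mean_baseline = mean(baseline), mean_end = mean(end),
                      mean_delta = mean(delta), t = NA_real_,
                      df = n - 1, p = NA_real_, normality_p = norm_p,
                      normal = NA, degenerate = TRUE))
  }
  tt <- stats::t.test(end, baseline, paired = TRUE)
  data.frame(metric = metric, n = n, mean_baseline = mean(baseline),
             mean_end = mean(end), mean_delta = mean(delta),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, normality_p = norm_p,
             normal = is.na(norm_p) || norm_p >= 0.05,
             degenerate = FALSE)
}

#' Cohort report bundle
#'
#' Assembles the program's outcome tables from the upstream modules:
#' paired glycemic comparisons per metric and glycemic category (plus
#' baseline-defined subgroups), the nutrient percent-change table over the
#' diet set, and weight/activity summaries. Significance threshold is
#' 0.05; p-values are uncorrected by default (an optional
#' Benjamini-Hochberg adjustment can be switched on).
#'
#' @param cohort List of [participant_record()]s.
#' @param qc A [select_analysis_sets()] report for the cohort.
#' @param windows An [analysis_windows()] pair.
#' @param thresholds A [qc_thresholds()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return List of class `cohort_report` with `glycemic` (paired tests),
#'   `subgroups` (mean deltas), `nutrient_changes` (percent change of the
#'   macronutrient ratios per category), `weight` (strata means), and
#'   `activity` (paired activity/HR comparisons).
#' @export
cohort_report <- function(cohort, qc = select_analysis_sets(cohort),
                          windows = analysis_windows(),
                          thresholds = qc_thresholds(),
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  ids <- vapply(cohort, function(r) r$id, 0L)
  glu_ids <- qc$id[qc$glucose_set]
  glu_cohort <- cohort[match(glu_ids, ids)]
  if (!length(glu_cohort)) stop("glucose analysis set is empty")
  summaries <- cohort_glycemic_summaries(glu_cohort, windows)
  base <- summaries[summaries$window == "baseline", ]
  end <- summaries[summaries$window == "end", ]
  end <- end[match(base$id, end$id), ]

  tests <- list()
  for (cat in c("all", "healthy", "prediabetes", "T2D")) {
    sel <- if (cat == "all") rep(TRUE, nrow(base)) else base$category == cat
    if (sum(sel) < 2) next
    for (m in metric_cols) {
      tests[[length(tests) + 1L]] <- cbind(
        group = cat, paired_t(base[[m]][sel], end[[m]][sel], metric = m))
    }
  }
  glycemic <- do.call(rbind, tests)
  if (p_adjust == "BH") glycemic$p <- stats::p.adjust(glycemic$p, "BH")
  glycemic$significant <- !is.na(glycemic$p) & glycemic$p < 0.05

  # nutrient percent-change table over the diet set
  diet_ids <- qc$id[qc$diet_set]
  diet_cohort <- cohort[match(diet_ids, ids)]
  nut_rows <- list()
  ratio_cols <- c("mean_daily_kcal", "carb_ratio", "sugar_ratio",
                  "protein_ratio", "fat_ratio", "satfat_ratio",
                  "fiber_per_kcal")
  if (length(diet_cohort)) {
    per <- lapply(diet_cohort, function(r) {
      b <- tryCatch(nutrient_summary(r$meals, 1:7, thresholds),
                    error = function(e) NULL)
      e <- tryCatch(nutrient_summary(r$meals, thresholds$end_window_days,
                                     thresholds),
                    error = function(e) NULL)
      if (is.null(b) || is.null(e)) return(NULL)
      data.frame(category = r$category, window = c("baseline", "end"),
                 rbind(b[ratio_cols], e[ratio_cols]))
    })
    per <- do.call(rbind, Filter(Negate(is.null), per))
    for (cat in c("all", "healthy", "prediabetes", "T2D")) {
      sel <- if (cat == "all") rep(TRUE, nrow(per)) else per$category == cat
      pb <- per[sel & per$window == "baseline", ratio_cols, drop = FALSE]
      pe <- per[sel & per$window == "end", ratio_cols, drop = FALSE]
      if (!nrow(pb)) next
      row <- data.frame(category = cat, n = nrow(pb))
      row[paste0("pct_change_", ratio_cols)] <-
        100 * (colMeans(pe) - colMeans(pb)) / colMeans(pb)
      nut_rows[[length(nut_rows) + 1L]] <- row
    }
  }
  nutrient_changes <- if (length(nut_rows)) do.call(rbind, nut_rows) else
    NULL

  weight_ids <- qc$id[qc$weight_set]
  weight <- if (length(weight_ids)) {
    tryCatch(weight_strata_report(cohort[match(weight_ids, ids)],
                                  last_days = thresholds$end_window_days),
             error = function(e) NULL)
  } else NULL

  # activity + HR comparisons over the glucose set (resting-HR-excluded
  # participants drop out of the HR rows only)
  beh <- do.call(rbind, lapply(glu_cohort, function(r) {
    excl <- qc$resting_hr_excluded[qc$id == r$id]
    tryCatch(behavior_summary(r, windows, hr_excluded = excl),
             error = function(e) NULL)
  }))
  activity <- NULL
  if (!is.null(beh) && nrow(beh) >= 2) {
    activity <- rbind(
      cbind(group = "all", paired_t(beh$activity_min_baseline,
                                    beh$activity_min_end,
                                    metric = "adjusted_activity_min")),
      if (sum(!is.na(beh$hr110_min_baseline)) >= 2) {
        cbind(group = "all", paired_t(beh$hr110_min_baseline,
                                      beh$hr110_min_end,
                                      metric = "hr110_min"))
      })
  }

  structure(
    list(glycemic = glycemic,
         subgroups = subgroup_deltas(summaries),
         nutrient_changes = nutrient_changes,
         weight = weight, activity = activity,
         n = list(cohort = length(cohort), glucose = length(glu_cohort),
                  weight = length(weight_ids), diet = length(diet_ids))),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf(
    "<cohort_report> n=%d (glucose %d, weight %d, diet %d)\n",
    x$n$cohort, x$n$glucose, x$n$weight, x$n$diet))
  sig <- x$glycemic[x$glycemic$group == "all" & x$glycemic$significant, ]
  if (nrow(sig)) {
    cat("significant overall changes:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %-14s delta %+.3f (p=%.2g)\n", sig$metric[i],
                  sig$mean_delta[i], sig$p[i]))
    }
  }
  invisible(x)
}
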