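#' Dietary summary over qualifying logging days
#'
#' Computes mean daily calories and macronutrient-to-calorie ratios over
#' the window's good logging days only (see [good_logging_day()]), so the
#' summary is robust to changes in logging frequency. Macronutrient
#' calories use 4 kcal/g for carbohydrate, sugar and protein and 9 kcal/g
#' for fat and saturated fat; ratios divide by the logged total calories
#' (not the macro-derived sum), and fiber is reported as grams per total
#' kcal.
#'
#' @param meals Data frame of meal logs (columns `day`, `time_min`, and the
#'   nutrient columns).
#' @param days Integer vector of program days forming the window.
#' @param thresholds A [qc_thresholds()] supplying the good-day rule.
#' @return One-row data frame: `n_good_days`, `mean_daily_kcal`,
#'   `carb_ratio`, `sugar_ratio`, `protein_ratio`, `fat_ratio`,
#'   `satfat_ratio` (macro kcal : total kcal), and `fiber_per_kcal`
#'   (g : total kcal).
#' @export
nutrient_summary <- function(meals, days, thresholds = qc_thresholds()) {
  in_window <- meals[meals$day %in% days, , drop = FALSE]
  good <- Filter(function(d) {
    good_logging_day(in_window[in_window$day == d, , drop = FALSE],
                     thresholds)
  }, unique(in_window$day))
  if (!length(good)) stop("no good logging days in the requested window")
  sel <- in_window[in_window$day %in% good, , drop = FALSE]
  total_kcal <- sum(sel$kcal)
  ratio <- function(col) {
    macro_kcal_multipliers[[col]] * sum(sel[[col]]) / total_kcal
  }
  data.frame(
    n_good_days = length(good),
    mean_daily_kcal = total_kcal / length(good),
    carb_ratio = ratio("carb_g"),
    sugar_ratio = ratio("sugar_g"),
    protein_ratio = ratio("protein_g"),
    fat_ratio = ratio("fat_g"),
    satfat_ratio = ratio("satfat_g"),
    fiber_per_kcal = sum(sel$fiber_g) / total_kcal)
}

# logging events per day in a window: every meal, activity or weight log
# counts as one app interaction
interactions_per_day <- function(record, days) {
  n <- sum(record$meals$day %in% days) +
    sum(record$activities$day %in% days) +
    sum(record$weights$day %in% days)
  n / length(days)
}

#' Logging-adjusted activity minutes per day
#'
#' Raw logged activity minutes per day are confounded by logging
#' frequency, which typically decays over a program. The adjustment
#' divides raw minutes/day by the ratio of the window's app-interaction
#' rate to the baseline window's rate, so the adjusted value equals the
#' raw value when logging behavior is unchanged, and is scaled up when
#' the participant logs less often.
#'
#' @param record A [participant_record()].
#' @param days Window to evaluate.
#' @param baseline_days Reference window for the interaction rate
#'   (default days 1-5, the activity/food-logging baseline).
#' @return Adjusted activity minutes per day.
#' @export
adjusted_activity_minutes <- function(record, days, baseline_days = 1:5) {
  acts <- record$activities[record$activities$day %in% days, , drop = FALSE]
  raw <- sum(acts$minutes) / length(days)
  if (raw == 0) return(0)
  rate <- interactions_per_day(record, days)
  ref <- interactions_per_day(record, baseline_days)
  if (rate <= 0) stop("no app interactions in the requested window")
  if (ref <= 0) stop("no app interactions in the baseline window")
  raw / (rate / ref)
}

#' Minutes per day with heart rate above a threshold
#'
#' Objective activity measure: minutes with HR above `threshold`
#' (strictly), divided by the number of window days with at least 20 h of
#' capture. Participants flagged as resting-HR-excluded must not use this
#' measure.
#'
#' @param record A [participant_record()].
#' @param days Window to evaluate.
#' @param threshold Heart-rate threshold in bpm (default 110).
#' @param excluded Set `TRUE` for participants whose resting HR exceeds
#'   the threshold; the function then signals an explicit exclusion error.
#' @param min_capture_hours Hours of capture a day needs to enter the
#'   denominator (default 20).
#' @return Minutes per day above the threshold.
#' @export
hr_above_threshold_minutes <- function(record, days, threshold = 110,
                                       excluded = FALSE,
                                       min_capture_hours = 20) {
  if (excluded) {
    stop("participant excluded from HR-based measures (resting HR above ",
         threshold, " bpm)")
  }
  hr <- record$heart_rate
  day_of <- floor((seq_along(hr) - 1) / 1440) + 1
  sel <- day_of %in% days
  capture <- tapply(!is.na(hr[sel]), day_of[sel], sum)
  full_days <- sum(capture >= min_capture_hours * 60)
  if (full_days == 0) stop("no window days with sufficient HR capture")
  sum(hr[sel] > threshold, na.rm = TRUE) / full_days
}

#' Body-weight change over the program
#'
#' Compares the first weight measurement of the first window with the last
#' measurement of the final window.
#'
#' @param weights Data frame with columns `day` and `lbs`.
#' @param first_days,last_days Measurement windows (defaults 1-7 and the
#'   last 14 days of a 28-day program).
#' @return One-row data frame: `weight_first`, `weight_last`,
#'   `weight_delta_lbs`, `weight_delta_pct` (percent of initial weight).
#' @export
weight_change <- function(weights, first_days = 1:7, last_days = 15:28) {
  first <- weights[weights$day %in% first_days, , drop = FALSE]
  last <- weights[weights$day %in% last_days, , drop = FALSE]
  if (!nrow(first) || !nrow(last)) {
    stop("need at least one weight in each of the first and last windows")
  }
  w_first <- first$lbs[which.min(first$day)]
  w_last <- last$lbs[which.max(last$day)]
  data.frame(weight_first = w_first, weight_last = w_last,
             weight_delta_lbs = w_last - w_first,
             weight_delta_pct = 100 * (w_last - w_first) / w_first)
}

weight_strata_breaks <- c(-Inf, 150, 200, 250, 300)
weight_strata_labels <- c("<150", "150-199", "200-249", "250-300")

#' Mean weight loss by baseline-weight stratum
#'
#' Strata are lower-inclusive: a baseline weight of exactly 250 lbs falls
#' in the 250-300 stratum. Twelve-week columns are reported only when the
#' program is long enough to contain the extended window (days 70-84);
#' otherwise the 4-week change is the only phase. Empty strata are absent
#' from the output.
#'
#' @param cohort List of [participant_record()]s (weight-set members).
#' @param first_days,last_days Four-week measurement windows passed to
#'   [weight_change()].
#' @return Data frame with `stratum`, `n`, `mean_loss_lbs`,
#'   `mean_loss_pct` (positive numbers denote loss), plus `mean_loss_lbs_12wk`
#'   and `mean_loss_pct_12wk` when the extended phase exists.
#' @export
weight_strata_report <- function(cohort, first_days = 1:7,
                                 last_days = 15:28) {
  per <- lapply(cohort, function(r) {
    wc <- tryCatch(weight_change(r$weights, first_days, last_days),
                   error = function(e) NULL)
    if (is.null(wc)) return(NULL)
    cbind(baseline_weight = r$baseline_weight, program_days = r$program_days,
          r = r$id, wc,
          wc12 = if (r$program_days >= 84) {
            tryCatch(weight_change(r$weights, first_days, 70:84)$
                       weight_delta_lbs, error = function(e) NA_real_)
          } else NA_real_)
  })
  per <- do.call(rbind, Filter(Negate(is.null), per))
  if (is.null(per) || !nrow(per)) stop("no participants with usable weights")
  per$stratum <- as.character(cut(per$baseline_weight, weight_strata_breaks,
                                  weight_strata_labels, right = FALSE))
  has12 <- any(!is.na(per$wc12))
  one <- function(sel, label) {
    if (!any(sel)) return(NULL)
    out <- data.frame(
      stratum = label, n = sum(sel),
      mean_loss_lbs = -mean(per$weight_delta_lbs[sel]),
      mean_loss_pct = -mean(per$weight_delta_pct[sel]))
    if (has12) out$mean_loss_lbs_12wk <- -mean(per$wc12[sel], na.rm = TRUE)
    out
  }
  rows <- c(lapply(weight_strata_labels,
                   function(s) one(per$stratum == s, s)),
            list(one(rep(TRUE, nrow(per)), "overall")))
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Behavior summary for one participant
#'
#' @param record A [participant_record()].
#' @param windows An [analysis_windows()] pair used for the glucose-aligned
#'   metrics; activity uses its own baseline (days 1-5).
#' @param hr_excluded Resting-HR exclusion flag from the QC report.
#' @return One-row data frame with adjusted activity minutes, HR>110
#'   minutes per day (baseline and end), and the weight fields.
#' @export
behavior_summary <- function(record, windows = analysis_windows(),
                             hr_excluded = FALSE) {
  act_base <- adjusted_activity_minutes(record, 1:5, baseline_days = 1:5)
  act_end <- adjusted_activity_minutes(record, windows$end,
                                       baseline_days = 1:5)
  hr_base <- if (hr_excluded) NA_real_ else
    hr_above_threshold_minutes(record, windows$baseline)
  hr_end <- if (hr_excluded) NA_real_ else
    hr_above_threshold_minutes(record, windows$end)
  wc <- tryCatch(weight_change(record$weights),
                 error = function(e) data.frame(
                   weight_first = NA_real_, weight_last = NA_real_,
                   weight_delta_lbs = NA_real_, weight_delta_pct = NA_real_))
  cbind(data.frame(id = record$id, category = record$category,
                   activity_min_baseline = act_base,
                   activity_min_end = act_end,
                   hr110_min_baseline = hr_base, hr110_min_end = hr_end),
        wc)
}
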