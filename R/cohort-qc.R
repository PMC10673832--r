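#' Quality-control thresholds for cohort inclusion
#'
#' Encodes the inclusion rules that select the analysis subsets: CGM
#' coverage, meal-logging consistency, body-weight tracking, and heart-rate
#' capture. All comparisons are inclusive (the rules are stated as "at
#' least"). Two window presets exist in the source methodology (a baseline
#' of days 3-7 in one place and days 1-5 excluding day 1 in another); the
#' default adopts days 2-7, aligned with the glycemic baseline window, and
#' both bounds are configurable.
#'
#' @param cgm_daily_coverage_min Minimum fraction of a day's CGM slots
#'   present for the day to count as covered (default 0.70).
#' @param cgm_days_fraction_min Minimum fraction of covered days required
#'   in each QC window (default 0.5).
#' @param baseline_window_days,end_window_days Day ranges of the two QC
#'   windows (defaults 2:7 and 15:28, i.e. the last 14 days).
#' @param hr_hours_min Minimum hours of heart-rate capture per day
#'   (default 20).
#' @param min_meal_logs_per_day Logging events per day that count as
#'   "active logging" (default 2).
#' @param good_day_kcal_min Calorie floor for a good logging day
#'   (default 1600).
#' @param good_day_span_hours All logs of a good day must fall within a
#'   window of this many hours (default 16).
#' @param good_day_min_span_hours First-to-last log span required so logs
#'   are "spread throughout waking hours" (default 4).
#' @param weight_first_days,weight_last_days Windows in which at least one
#'   body-weight measurement is required (defaults 1:7 and 15:28).
#' @param resting_hr_max Resting heart rate above which a participant is
#'   excluded from heart-rate-based activity measures (default 110 bpm).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cgm_daily_coverage_min = 0.70,
                          cgm_days_fraction_min = 0.5,
                          baseline_window_days = 2:7,
                          end_window_days = 15:28,
                          hr_hours_min = 20,
                          min_meal_logs_per_day = 2,
                          good_day_kcal_min = 1600,
                          good_day_span_hours = 16,
                          good_day_min_span_hours = 4,
                          weight_first_days = 1:7,
                          weight_last_days = 15:28,
                          resting_hr_max = 110) {
  stopifnot(cgm_daily_coverage_min > 0, cgm_daily_coverage_min <= 1,
            cgm_days_fraction_min > 0, cgm_days_fraction_min <= 1,
            hr_hours_min > 0, hr_hours_min <= 24,
            min_meal_logs_per_day >= 1, good_day_kcal_min >= 0,
            good_day_span_hours > 0, good_day_min_span_hours >= 0)
  structure(
    list(cgm_daily_coverage_min = cgm_daily_coverage_min,
         cgm_days_fraction_min = cgm_days_fraction_min,
         baseline_window_days = as.integer(baseline_window_days),
         end_window_days = as.integer(end_window_days),
         hr_hours_min = hr_hours_min,
         min_meal_logs_per_day = min_meal_logs_per_day,
         good_day_kcal_min = good_day_kcal_min,
         good_day_span_hours = good_day_span_hours,
         good_day_min_span_hours = good_day_min_span_hours,
         weight_first_days = as.integer(weight_first_days),
         weight_last_days = as.integer(weight_last_days),
         resting_hr_max = resting_hr_max),
    class = "qc_thresholds"
  )
}

#' Daily CGM coverage
#'
#' @param trace A [glucose_trace()].
#' @param day Program day (must lie within the trace span).
#' @return Fraction of the day's slots with a non-missing reading;
#'   slots per day = 1440 / step.
#' @export
daily_cgm_coverage <- function(trace, day) {
  idx <- trace_window(trace, day)
  if (!length(idx)) stop("day ", day, " lies outside the trace span")
  slots_per_day <- 1440 %/% trace$step_min
  sum(!is.na(trace$values[idx])) / slots_per_day
}

#' CGM coverage requirement
#'
#' True iff at least `cgm_days_fraction_min` of the days in *each* QC
#' window have coverage of at least `cgm_daily_coverage_min`.
#'
#' @param record A [participant_record()] (or anything with a `glucose`
#'   trace).
#' @param thresholds A [qc_thresholds()].
#' @return Logical flag; a missing trace yields `FALSE`.
#' @export
passes_cgm_requirement <- function(record, thresholds = qc_thresholds()) {
  trace <- record$glucose
  if (is.null(trace) || !length(trace$values)) return(FALSE)
  ok_window <- function(days) {
    days <- days[days <= max(trace_slot_days(trace))]
    if (!length(days)) return(FALSE)
    cov <- vapply(days, function(d) daily_cgm_coverage(trace, d), 0)
    mean(cov >= thresholds$cgm_daily_coverage_min) >=
      thresholds$cgm_days_fraction_min
  }
  ok_window(thresholds$baseline_window_days) &&
    ok_window(thresholds$end_window_days)
}

#' Good logging day
#'
#' A day qualifies for dietary analysis when it has at least
#' `min_meal_logs_per_day` logging events, all logs fall within a
#' `good_day_span_hours` window with a first-to-last span of at least
#' `good_day_min_span_hours` (the adopted reading of "spread throughout
#' waking hours spanning a 16 h range"), and the logged calories total at
#' least `good_day_kcal_min`.
#'
#' @param day_meals Data frame of one calendar day's meal logs (columns
#'   `time_min`, `kcal`).
#' @param thresholds A [qc_thresholds()].
#' @return Logical flag.
#' @export
good_logging_day <- function(day_meals, thresholds = qc_thresholds()) {
  if (is.null(day_meals) || nrow(day_meals) < thresholds$min_meal_logs_per_day)
    return(FALSE)
  span_min <- diff(range(day_meals$time_min))
  span_min <= thresholds$good_day_span_hours * 60 &&
    span_min >= thresholds$good_day_min_span_hours * 60 &&
    sum(day_meals$kcal) >= thresholds$good_day_kcal_min
}

#' Meal-logging requirement
#'
#' "Active logging of all meals" during both QC windows, operationalized as
#' at least `min_meal_logs_per_day` logging events on every day of the
#' first 7 days and the last 14 days.
#'
#' @inheritParams passes_cgm_requirement
#' @return Logical flag.
#' @export
passes_meal_logging <- function(record, thresholds = qc_thresholds()) {
  counts <- function(days) {
    vapply(days, function(d) sum(record$meals$day == d), 0L)
  }
  first7 <- 1:7
  last14 <- thresholds$end_window_days
  all(counts(first7) >= thresholds$min_meal_logs_per_day) &&
    all(counts(last14) >= thresholds$min_meal_logs_per_day)
}

#' Weight-tracking requirement
#'
#' At least one body-weight measurement in the first window and one in the
#' last window.
#'
#' @inheritParams passes_cgm_requirement
#' @return Logical flag.
#' @export
passes_weight_tracking <- function(record, thresholds = qc_thresholds()) {
  any(record$weights$day %in% thresholds$weight_first_days) &&
    any(record$weights$day %in% thresholds$weight_last_days)
}

#' Heart-rate capture requirement
#'
#' Capture of at least `hr_hours_min` hours per day on every program day.
#'
#' @inheritParams passes_cgm_requirement
#' @return Logical flag.
#' @export
passes_hr_capture <- function(record, thresholds = qc_thresholds()) {
  hr <- record$heart_rate
  if (is.null(hr) || !length(hr)) return(FALSE)
  days <- floor((seq_along(hr) - 1) / 1440) + 1
  per_day <- tapply(!is.na(hr), days, sum)
  length(per_day) >= record$program_days &&
    all(per_day >= thresholds$hr_hours_min * 60)
}

#' Resting heart rate
#'
#' Robust proxy: the 5th percentile of per-minute heart rate over the
#' program.
#'
#' @param record A [participant_record()].
#' @return Resting heart rate in bpm (`NA` when no capture).
#' @export
resting_heart_rate <- function(record) {
  hr <- record$heart_rate[!is.na(record$heart_rate)]
  if (!length(hr)) return(NA_real_)
  unname(stats::quantile(hr, 0.05))
}

# does the participant have at least one good logging day in each window?
has_good_days <- function(record, days, thresholds) {
  any(vapply(days, function(d) {
    good_logging_day(record$meals[record$meals$day == d, , drop = FALSE],
                     thresholds)
  }, FALSE))
}

#' Select analysis subsets for a cohort
#'
#' Evaluates every inclusion rule per participant and derives the analysis
#' set memberships: `glucose_set` (CGM + meal logging + HR capture),
#' `weight_set` (glucose set with weight tracking), and `diet_set`
#' (glucose set with at least one good logging day in both the baseline
#' and end windows). Participants whose resting heart rate exceeds
#' `resting_hr_max` are flagged for exclusion from heart-rate-based
#' activity measures but remain eligible for the glucose set.
#'
#' @param cohort List of [participant_record()]s.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame (class `qc_report`) with one row per participant:
#'   id, category, the rule booleans, and the set memberships.
#' @export
select_analysis_sets <- function(cohort, thresholds = qc_thresholds()) {
  if (!length(cohort)) stop("cohort must be nonempty")
  rows <- lapply(cohort, function(r) {
    cgm_ok <- passes_cgm_requirement(r, thresholds)
    meals_ok <- passes_meal_logging(r, thresholds)
    weight_ok <- passes_weight_tracking(r, thresholds)
    hr_ok <- passes_hr_capture(r, thresholds)
    rhr <- resting_heart_rate(r)
    rhr_excl <- !is.na(rhr) && rhr > thresholds$resting_hr_max
    glucose_set <- cgm_ok && meals_ok && hr_ok
    data.frame(
      id = r$id, category = r$category, cgm_ok = cgm_ok,
      meals_ok = meals_ok, weight_ok = weight_ok, hr_ok = hr_ok,
      resting_hr = rhr, resting_hr_excluded = rhr_excl,
      glucose_set = glucose_set,
      weight_set = glucose_set && weight_ok,
      diet_set = glucose_set &&
        has_good_days(r, 1:7, thresholds) &&
        has_good_days(r, thresholds$end_window_days, thresholds))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}
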