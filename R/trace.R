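#' CGM glucose trace
#'
#' A uniformly sampled continuous glucose monitor (CGM) series with explicit
#' missing slots. Time is kept as minutes since the start of the program
#' (day 1, 00:00 = minute 0); slot `i` covers
#' `[start_min + (i-1)*step_min, start_min + i*step_min)`.
#'
#' @param values Numeric vector of glucose readings in mg/dL; `NA` marks a
#'   slot lost to sensor dropout. Non-missing values must lie in (20, 600).
#' @param step_min Sampling step in minutes (default 15, the historic
#'   intermittent-scan cadence of factory-calibrated sensors).
#' @param start_min Time of the first slot in minutes since program start.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(values, step_min = 15, start_min = 0) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (step_min <= 0) stop("step_min must be positive")
  v <- values[!is.na(values)]
  if (length(v) && (any(v <= 20) || any(v >= 600))) {
    stop("glucose values must lie in (20, 600) mg/dL or be NA")
  }
  structure(
    list(values = as.numeric(values), step_min = step_min,
         start_min = start_min),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- length(x$values)
  miss <- mean(is.na(x$values))
  cat(sprintf(
    "<glucose_trace> %d slots @ %g min (%.1f days), %.1f%% missing\n",
    n, x$step_min, n * x$step_min / 1440, 100 * miss))
  invisible(x)
}

# minute-of-program at which each slot starts
trace_slot_times <- function(trace) {
  trace$start_min + (seq_along(trace$values) - 1) * trace$step_min
}

# calendar day index (1-based, midnight boundaries) of each slot
trace_slot_days <- function(trace) {
  floor(trace_slot_times(trace) / 1440) + 1
}

#' Slot indices of a trace falling on given program days
#'
#' @param trace A [glucose_trace()].
#' @param days Integer vector of day indices (day 1 = first program day).
#' @return Integer vector of slot indices.
#' @export
trace_window <- function(trace, days) {
  which(trace_slot_days(trace) %in% days)
}

#' Fraction of window slots lost to CGM signal dropout
#'
#' @inheritParams trace_window
#' @return Fraction of slots in the window whose reading is missing.
#' @export
window_lost_time <- function(trace, days) {
  idx <- trace_window(trace, days)
  if (!length(idx)) stop("window does not overlap the trace")
  mean(is.na(trace$values[idx]))
}

#' Analysis window pair
#'
#' Day ranges used for baseline-versus-end comparisons. Day 1 is excluded
#' from the default baseline because first-day CGM readings are known to be
#' less accurate.
#'
#' @param baseline Integer days forming the baseline window (default 2:7).
#' @param end Integer days forming the end-of-program window (default 14:28).
#' @return List with elements `baseline` and `end`.
#' @export
analysis_windows <- function(baseline = 2:7, end = 14:28) {
  stopifnot(length(baseline) >= 1, length(end) >= 1)
  if (length(intersect(baseline, end))) {
    stop("baseline and end windows must be disjoint")
  }
  list(baseline = as.integer(baseline), end = as.integer(end))
}

#' Participant record
#'
#' Bundles every stream captured for one program participant: CGM trace,
#' per-minute heart rate, meal logs with nutrient breakdown, activity logs,
#' body-weight logs, plus glycemic category and demographics.
#'
#' @param id Integer participant id.
#' @param category One of `"healthy"`, `"prediabetes"`, `"T2D"`.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param baseline_weight Starting body weight in lbs.
#' @param glucose A [glucose_trace()].
#' @param heart_rate Per-minute heart-rate vector (bpm), length
#'   `program_days * 1440`; `NA` marks lost capture.
#' @param meals Data frame with columns `day`, `time_min`, `food`, `kcal`,
#'   `carb_g`, `sugar_g`, `protein_g`, `fat_g`, `satfat_g`, `fiber_g`.
#' @param activities Data frame with columns `day`, `time_min`, `minutes`.
#' @param weights Data frame with columns `day`, `lbs`.
#' @param program_days Program length in days.
#' @param ground_truth Optional list of generator parameters used, kept for
#'   oracle recomputation in tests.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(id, category, age, sex, baseline_weight,
                               glucose, heart_rate, meals, activities,
                               weights, program_days = 28,
                               ground_truth = NULL) {
  category <- match.arg(category, c("healthy", "prediabetes", "T2D"))
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(inherits(glucose, "glucose_trace"), is.data.frame(meals),
            is.data.frame(activities), is.data.frame(weights))
  if (nrow(weights) && any(weights$lbs <= 0)) stop("weights must be positive")
  horizon <- program_days * 1440
  for (d in list(meals$time_min, activities$time_min)) {
    if (length(d) && (any(d < 0) || any(d >= horizon))) {
      stop("stream timestamps must fall within the program")
    }
  }
  structure(
    list(id = id, category = category, age = age, sex = sex,
         baseline_weight = baseline_weight, glucose = glucose,
         heart_rate = heart_rate, meals = meals, activities = activities,
         weights = weights, program_days = program_days,
         ground_truth = ground_truth),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf(
    "<participant_record> id %s, %s, %s, age %d, %.0f lbs; %d meals, %d activity logs, %d weights\n",
    x$id, x$category, x$sex, as.integer(x$age), x$baseline_weight,
    nrow(x$meals), nrow(x$activities), nrow(x$weights)))
  invisible(x)
}

empty_meals <- function() {
  data.frame(day = integer(), time_min = numeric(), food = character(),
             kcal = numeric(), carb_g = numeric(), sugar_g = numeric(),
             protein_g = numeric(), fat_g = numeric(), satfat_g = numeric(),
             fiber_g = numeric(), stringsAsFactors = FALSE)
}

empty_activities <- function() {
  data.frame(day = integer(), time_min = numeric(), minutes = numeric())
}

empty_weights <- function() {
  data.frame(day = integer(), lbs = numeric())
}
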