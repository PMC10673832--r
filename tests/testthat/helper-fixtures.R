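# Constructed participant records exercising each inclusion-rule boundary.

std_meal_row <- function(day, tod, kcal = 700, food = "meal") {
  data.frame(day = day, time_min = (day - 1) * 1440 + tod, food = food,
             kcal = kcal, carb_g = 60, sugar_g = 20, protein_g = 30,
             fat_g = 20, satfat_g = 8, fiber_g = 5,
             stringsAsFactors = FALSE)
}

# meals on every program day at the given times-of-day and calories
std_meals <- function(program_days = 28, tods = c(480, 780, 1140),
                      kcals = rep(700, length(tods))) {
  do.call(rbind, lapply(seq_len(program_days), function(d) {
    do.call(rbind, Map(function(tt, kk) std_meal_row(d, tt, kk),
                       tods, kcals))
  }))
}

make_fixture_record <- function(id = 1L, category = "healthy",
                                program_days = 28, step = 15,
                                glucose_level = 100,
                                missing_slots_by_day = list(),
                                meals = std_meals(program_days),
                                hr_level = 70,
                                hr_minutes_by_day = NULL,
                                weights = data.frame(day = c(2L, 20L),
                                                     lbs = c(180, 178))) {
  per_day <- 1440 %/% step
  n <- program_days * per_day
  g <- rep(glucose_level, n)
  for (nm in names(missing_slots_by_day)) {
    d <- as.integer(nm)
    k <- missing_slots_by_day[[nm]]
    g[(d - 1) * per_day + seq_len(k)] <- NA
  }
  hr <- rep(hr_level, program_days * 1440)
  if (!is.null(hr_minutes_by_day)) {
    for (d in seq_len(program_days)) {
      cap <- hr_minutes_by_day[d]
      if (cap < 1440) {
        hr[(d - 1) * 1440 + (cap + 1):1440] <- NA
      }
    }
  }
  participant_record(
    id = id, category = category, age = 50, sex = "female",
    baseline_weight = 180, glucose = glucose_trace(g, step),
    heart_rate = hr, meals = meals,
    activities = data.frame(day = integer(), time_min = numeric(),
                            minutes = numeric()),
    weights = weights, program_days = program_days)
}

# the boundary suite: each element is list(name, record, expect), where
# expect covers the QC booleans and derived set memberships
qc_boundary_fixtures <- function() {
  exp_all <- list(cgm_ok = TRUE, meals_ok = TRUE, weight_ok = TRUE,
                  hr_ok = TRUE, resting_hr_excluded = FALSE,
                  glucose_set = TRUE, weight_set = TRUE, diet_set = TRUE)
  modify <- function(base, ...) utils::modifyList(base, list(...))
  fx <- list()
  add <- function(name, record, expect) {
    fx[[length(fx) + 1L]] <<- list(name = name, record = record,
                                   expect = expect)
  }

  add("all rules satisfied", make_fixture_record(), exp_all)

  # exact 70% daily coverage is representable with a 9-min step (160
  # slots/day, 112 = 70%); boundary is inclusive
  miss_end_half <- setNames(as.list(rep(160 - 112, 7)), as.character(15:21))
  add("half of end days at exactly 70% coverage",
      make_fixture_record(step = 9, missing_slots_by_day = miss_end_half),
      exp_all)
  miss_end_most <- setNames(as.list(rep(160 - 111, 8)), as.character(15:22))
  add("most end days just under 70% coverage",
      make_fixture_record(step = 9, missing_slots_by_day = miss_end_most),
      modify(exp_all, cgm_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))
  miss_end_all <- setNames(as.list(rep(48, 14)), as.character(15:28))
  add("end window all at 50% coverage",
      make_fixture_record(missing_slots_by_day = miss_end_all),
      modify(exp_all, cgm_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))
  add("exactly half the baseline days covered",
      make_fixture_record(missing_slots_by_day =
                            setNames(as.list(rep(48, 3)),
                                     as.character(2:4))),
      exp_all)
  add("under half the baseline days covered",
      make_fixture_record(missing_slots_by_day =
                            setNames(as.list(rep(48, 4)),
                                     as.character(2:5))),
      modify(exp_all, cgm_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))
  add("all days at 68 of 96 slots (just above 70%)",
      make_fixture_record(missing_slots_by_day =
                            setNames(as.list(rep(96 - 68, 28)),
                                     as.character(1:28))),
      exp_all)
  add("all days at 67 of 96 slots (just below 70%)",
      make_fixture_record(missing_slots_by_day =
                            setNames(as.list(rep(96 - 67, 28)),
                                     as.character(1:28))),
      modify(exp_all, cgm_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))

  one_log_on <- function(d) {
    m <- std_meals()
    m <- m[!(m$day == d & m$time_min %% 1440 != 480), ]
    m
  }
  add("single meal log on one end-window day",
      make_fixture_record(meals = one_log_on(20L)),
      modify(exp_all, meals_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))
  add("single meal log on a mid-program day only",
      make_fixture_record(meals = one_log_on(10L)),
      exp_all)

  # good-logging-day boundaries: two logs per day everywhere
  two_logs <- function(tods, kcals) std_meals(tods = tods, kcals = kcals)
  add("two logs, 1700 kcal, 15-h span",
      make_fixture_record(meals = two_logs(c(420, 1320), c(900, 800))),
      exp_all)
  add("two logs totalling exactly 1600 kcal",
      make_fixture_record(meals = two_logs(c(420, 1320), c(800, 800))),
      exp_all)
  add("two logs totalling 1500 kcal",
      make_fixture_record(meals = two_logs(c(420, 1320), c(700, 800))),
      modify(exp_all, diet_set = FALSE))
  add("logs spanning exactly 16 h",
      make_fixture_record(meals = two_logs(c(420, 1380), c(900, 800))),
      exp_all)
  add("logs spanning 17 h",
      make_fixture_record(meals = two_logs(c(360, 1380), c(900, 800))),
      modify(exp_all, diet_set = FALSE))
  add("logs spanning exactly 4 h",
      make_fixture_record(meals = two_logs(c(420, 660), c(900, 800))),
      exp_all)
  add("logs spanning only 3 h",
      make_fixture_record(meals = two_logs(c(420, 600), c(900, 800))),
      modify(exp_all, diet_set = FALSE))

  add("heart rate captured exactly 20 h every day",
      make_fixture_record(hr_minutes_by_day = rep(1200L, 28)),
      exp_all)
  add("heart rate 19.9 h on one day",
      make_fixture_record(hr_minutes_by_day = c(rep(1440L, 27), 1194L)),
      modify(exp_all, hr_ok = FALSE, glucose_set = FALSE,
             weight_set = FALSE, diet_set = FALSE))

  add("weight logged in first window only",
      make_fixture_record(weights = data.frame(day = 2L, lbs = 180)),
      modify(exp_all, weight_ok = FALSE, weight_set = FALSE))
  add("weight logged in last window only",
      make_fixture_record(weights = data.frame(day = 20L, lbs = 180)),
      modify(exp_all, weight_ok = FALSE, weight_set = FALSE))

  add("resting heart rate above 110 bpm",
      make_fixture_record(hr_level = 115),
      modify(exp_all, resting_hr_excluded = TRUE))
  fx
}

# brute-force re-evaluation of every QC predicate from the raw streams
brute_qc <- function(record, thr = qc_thresholds()) {
  step <- record$glucose$step_min
  per_day <- 1440 %/% step
  day_cov <- function(d) {
    v <- record$glucose$values[(d - 1) * per_day + seq_len(per_day)]
    sum(!is.na(v)) / per_day
  }
  win_ok <- function(days) {
    covered <- 0L
    for (d in days) if (day_cov(d) >= thr$cgm_daily_coverage_min) {
      covered <- covered + 1L
    }
    covered / length(days) >= thr$cgm_days_fraction_min
  }
  cgm_ok <- win_ok(thr$baseline_window_days) && win_ok(thr$end_window_days)
  counts_ok <- function(days) {
    for (d in days) {
      if (sum(record$meals$day == d) < thr$min_meal_logs_per_day) {
        return(FALSE)
      }
    }
    TRUE
  }
  meals_ok <- counts_ok(1:7) && counts_ok(thr$end_window_days)
  weight_ok <- any(record$weights$day %in% thr$weight_first_days) &&
    any(record$weights$day %in% thr$weight_last_days)
  hr_ok <- TRUE
  for (d in seq_len(record$program_days)) {
    cap <- sum(!is.na(record$heart_rate[(d - 1) * 1440 + 1:1440]))
    if (cap < thr$hr_hours_min * 60) hr_ok <- FALSE
  }
  list(cgm_ok = cgm_ok, meals_ok = meals_ok, weight_ok = weight_ok,
       hr_ok = hr_ok)
}
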