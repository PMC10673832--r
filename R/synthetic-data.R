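#' Generator configuration for synthetic program cohorts
#'
#' Defines the statistical structure of a simulated 28-day metabolic-health
#' program: meal-driven glucose excursions on top of a category-specific
#' basal level and a low-amplitude circadian term, diurnal heart rate with
#' exercise bouts, meal logging whose adherence decays linearly over the
#' program (81% early, 43% late, matching typical observed logging use),
#' contiguous CGM signal-loss gaps, and an optional injected behavior-change
#' effect (end-window carbohydrate reduction and activity increase) whose
#' ground truth is recorded for recovery tests.
#'
#' @param n_participants Number of participants to generate.
#' @param category_mix Named proportions over `healthy`, `prediabetes`,
#'   `T2D`; must sum to 1. Defaults to the 746:206:94 split typical of
#'   self-selected CGM program cohorts.
#' @param program_days Program length in days (default 28).
#' @param cgm_step CGM sampling step in minutes (default 15).
#' @param basal_glucose Named basal glucose (mg/dL) per category.
#' @param meal_params List with `amplitude` (mg/dL per carb gram),
#'   `fiber_atten` (fractional peak attenuation per fiber gram), `rise_min`
#'   and `decay_min` (kernel time constants, minutes).
#' @param meal_nutrients List of per-unit-size meal composition means:
#'   `kcal`, `carb_g`, `protein_g`, `fat_g`, `fiber_g`. Composition
#'   fluctuations are mean-one lognormals independent of meal size, so
#'   macronutrient-to-calorie ratios have closed-form expectations (see
#'   [expected_carb_ratio_change()]).
#' @param circadian_amp Amplitude (mg/dL) of the sinusoidal circadian
#'   glucose term peaking near dawn; kept at or below 10 so time of day is a
#'   real but secondary driver relative to meals.
#' @param noise_sd CGM sensor noise SD in mg/dL.
#' @param adherence_start,adherence_end Probability that a consumed meal is
#'   logged on day 1 and on the last day; interpolated linearly in between.
#' @param engaged_frac Fraction of participants who are consistently
#'   engaged loggers; their per-meal adherence never drops below
#'   `engaged_adherence`. Logging adherence in program cohorts is strongly
#'   participant-correlated - roughly half of enrollees keep logging while
#'   the rest taper off - and without this mixture no generated participant
#'   could satisfy the log-every-day inclusion rule.
#' @param engaged_adherence Adherence floor for engaged participants.
#' @param signal_loss_fraction Fraction of CGM slots lost to sensor
#'   dropout, placed as contiguous 1-8 h gaps.
#' @param effect List with `carb_reduction` (fractional carbohydrate cut in
#'   the end window), `activity_increase` (fractional increase in exercise
#'   duration), and `start_day` (first day the effect applies, default 15).
#' @param activity_prob Probability of an exercise bout on any given day.
#' @param seed Integer seed; together with the participant id it fully
#'   determines each record.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 100,
                             category_mix = c(healthy = 746, prediabetes = 206,
                                              T2D = 94) / 1046,
                             program_days = 28,
                             cgm_step = 15,
                             basal_glucose = c(healthy = 90, prediabetes = 105,
                                               T2D = 140),
                             meal_params = list(amplitude = 1.2,
                                                fiber_atten = 0.02,
                                                rise_min = 30, decay_min = 30),
                             meal_nutrients = list(kcal = 700, carb_g = 70,
                                                   protein_g = 30, fat_g = 25,
                                                   fiber_g = 6),
                             circadian_amp = 5,
                             noise_sd = 5,
                             adherence_start = 0.81,
                             adherence_end = 0.43,
                             engaged_frac = 0.45,
                             engaged_adherence = 0.98,
                             signal_loss_fraction = 0.10,
                             effect = list(carb_reduction = 0,
                                           activity_increase = 0,
                                           start_day = 15),
                             activity_prob = 0.5,
                             seed = 1L) {
  cats <- c("healthy", "prediabetes", "T2D")
  if (!all(cats %in% names(category_mix))) {
    stop("category_mix must name healthy, prediabetes and T2D")
  }
  category_mix <- category_mix[cats]
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  if (n_participants <= 0) stop("n_participants must be positive")
  with(meal_params, stopifnot(rise_min > 0, decay_min > 0, amplitude >= 0,
                              fiber_atten >= 0))
  if (adherence_start < 0 || adherence_start > 1 ||
      adherence_end < 0 || adherence_end > 1 ||
      engaged_adherence < 0 || engaged_adherence > 1 ||
      engaged_frac < 0 || engaged_frac > 1) {
    stop("adherence probabilities must lie in [0, 1]")
  }
  if (signal_loss_fraction < 0 || signal_loss_fraction >= 1) {
    stop("signal_loss_fraction must lie in [0, 1)")
  }
  if (circadian_amp < 0 || circadian_amp > 10) {
    stop("circadian_amp must lie in [0, 10] mg/dL")
  }
  if (is.null(effect$start_day)) effect$start_day <- 15
  stopifnot(program_days >= 1, cgm_step > 0, 1440 %% cgm_step == 0,
            effect$carb_reduction >= 0, effect$carb_reduction < 1,
            effect$activity_increase >= 0)
  structure(
    list(n_participants = as.integer(n_participants),
         category_mix = category_mix, program_days = as.integer(program_days),
         cgm_step = cgm_step, basal_glucose = basal_glucose,
         meal_params = meal_params, meal_nutrients = meal_nutrients,
         circadian_amp = circadian_amp, noise_sd = noise_sd,
         adherence_start = adherence_start, adherence_end = adherence_end,
         engaged_frac = engaged_frac, engaged_adherence = engaged_adherence,
         signal_loss_fraction = signal_loss_fraction, effect = effect,
         activity_prob = activity_prob, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Logging adherence on a given program day
#'
#' Linear interpolation between the start and end adherence probabilities.
#'
#' @param cfg A [generator_config()].
#' @param day Program day (1-based).
#' @return Probability that a consumed meal is logged that day.
#' @export
adherence_on_day <- function(cfg, day) {
  if (cfg$program_days == 1) return(cfg$adherence_start)
  f <- (day - 1) / (cfg$program_days - 1)
  cfg$adherence_start + (cfg$adherence_end - cfg$adherence_start) * f
}

# gamma-like unit-peak kernel: rises over ~rise_min, decays with decay_min,
# peak value exactly 1 at t = rise_min
meal_kernel <- function(t, rise_min, decay_min) {
  p <- rise_min / decay_min
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / rise_min)^p * exp((rise_min - t[pos]) / decay_min)
  out
}

#' Incremental glucose response to one meal
#'
#' Mechanistic kernel that makes logged nutrients the dominant glucose
#' driver: the incremental curve is a gamma-like rise/decay whose peak
#' scales linearly with carbohydrate grams and is attenuated by fiber,
#' `peak = amplitude * carb_g * max(0, 1 - fiber_atten * fiber_g)`.
#'
#' @param nutrients A [nutrient_vector()] (or list with `carb_g`,
#'   `fiber_g`).
#' @param params Kernel parameters: `amplitude`, `fiber_atten`, `rise_min`,
#'   `decay_min` (see [generator_config()]).
#' @param step_min Grid step in minutes.
#' @param horizon_min Curve length in minutes (default 4 h).
#' @return Numeric incremental glucose curve (mg/dL) on
#'   `seq(0, horizon_min, by = step_min)`; starts at 0 and is non-negative.
#' @export
meal_response <- function(nutrients, params = generator_config()$meal_params,
                          step_min = 15, horizon_min = 240) {
  carb <- nutrients$carb_g
  fiber <- nutrients$fiber_g
  if (is.null(carb) || is.null(fiber) || carb < 0 || fiber < 0) {
    stop("nutrients must supply non-negative carb_g and fiber_g")
  }
  peak <- params$amplitude * carb * max(0, 1 - params$fiber_atten * fiber)
  t <- seq(0, horizon_min, by = step_min)
  peak * meal_kernel(t, params$rise_min, params$decay_min)
}

# mean-one lognormal fluctuation
rlnorm1 <- function(n, sdlog) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

participant_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(id) * 104729) %% 2147483629)
}

# Daily meal schedule: three main meals plus an occasional snack. Sizes are
# relative to meal_nutrients (breakfast 0.9x, lunch 1x, dinner 1.1x,
# snack 0.35x).
meal_types <- data.frame(
  food = c("breakfast", "lunch", "dinner", "snack"),
  mean_min = c(450, 760, 1140, 960),
  sd_min = c(30, 40, 40, 60),
  scale = c(0.9, 1.0, 1.1, 0.35),
  prob = c(1, 1, 1, 0.35),
  stringsAsFactors = FALSE
)

#' Generate one synthetic participant
#'
#' Glucose equals basal + the meal-response kernel summed over the
#' participant's logged meals + a circadian term + Gaussian sensor noise,
#' then masked by contiguous signal-loss gaps. Meals are drawn per day and
#' logged with probability [adherence_on_day()]; from `effect$start_day`
#' onward carbohydrates (and proportionally sugar and calories) are reduced
#' by `effect$carb_reduction` and exercise duration increased by
#' `effect$activity_increase`. Body weight drifts by one pound per 3500 kcal
#' of cumulative deficit attributable to the injected effect. The record is
#' fully determined by `(cfg$seed, id)`.
#'
#' @param cfg A [generator_config()].
#' @param category Glycemic category of the participant.
#' @param id Integer participant id.
#' @return A [participant_record()] with `ground_truth` bookkeeping.
#' @export
generate_participant <- function(cfg, category = "healthy", id = 1L) {
  category <- match.arg(category, c("healthy", "prediabetes", "T2D"))
  set.seed(participant_seed(cfg$seed, id))
  D <- cfg$program_days
  step <- cfg$cgm_step
  n_slots <- D * 1440 %/% step
  mp <- cfg$meal_params
  mn <- cfg$meal_nutrients
  eff <- cfg$effect

  age <- round(min(80, max(18, stats::rnorm(1, 49, 11.5))))
  sex <- if (stats::runif(1) < 0.49) "male" else "female"
  w0 <- round(min(320, max(110, stats::rnorm(1, 185, 35))), 1)
  engaged <- stats::runif(1) < cfg$engaged_frac
  adh_day <- function(day) {
    s <- adherence_on_day(cfg, day)
    if (engaged) max(s, cfg$engaged_adherence) else s
  }

  adherence_vec <- vapply(seq_len(D), adh_day, 0)
  n_types <- nrow(meal_types)
  cap <- D * n_types
  m_day <- integer(cap); m_tod <- numeric(cap); m_food <- character(cap)
  m_kcal <- numeric(cap); m_carb <- numeric(cap); m_sugar <- numeric(cap)
  m_prot <- numeric(cap); m_fat <- numeric(cap); m_satfat <- numeric(cap)
  m_fiber <- numeric(cap)
  n_m <- 0L
  daily <- data.frame(day = seq_len(D), adherence = adherence_vec,
                      n_meals = 0L, carb_raw = 0, carb_cut_kcal = 0,
                      activity_min = 0, deficit_kcal = 0)
  for (day in seq_len(D)) {
    adh <- adherence_vec[day]
    on_effect <- day >= eff$start_day
    for (k in seq_len(n_types)) {
      if (stats::runif(1) > meal_types$prob[k]) next
      logged <- stats::runif(1) < adh
      tod <- min(1435, max(5, stats::rnorm(1, meal_types$mean_min[k],
                                           meal_types$sd_min[k])))
      size <- meal_types$scale[k] * rlnorm1(1, 0.25)
      carb_raw <- mn$carb_g * size * rlnorm1(1, 0.20)
      protein <- mn$protein_g * size * rlnorm1(1, 0.25)
      fat <- mn$fat_g * size * rlnorm1(1, 0.30)
      fiber <- mn$fiber_g * size * rlnorm1(1, 0.35)
      kcal_raw <- mn$kcal * size * stats::runif(1, 0.925, 1.075)
      sugar_frac <- stats::runif(1, 0.15, 0.45)
      satfat_frac <- stats::runif(1, 0.25, 0.45)
      if (!logged) next
      if (on_effect) {
        carb <- carb_raw * (1 - eff$carb_reduction)
        kcal <- kcal_raw - 4 * eff$carb_reduction * carb_raw
        daily$carb_cut_kcal[day] <- daily$carb_cut_kcal[day] +
          4 * eff$carb_reduction * carb_raw
      } else {
        carb <- carb_raw
        kcal <- kcal_raw
      }
      daily$n_meals[day] <- daily$n_meals[day] + 1L
      daily$carb_raw[day] <- daily$carb_raw[day] + carb_raw
      n_m <- n_m + 1L
      m_day[n_m] <- day
      m_tod[n_m] <- (day - 1) * 1440 + tod
      m_food[n_m] <- meal_types$food[k]
      m_kcal[n_m] <- kcal; m_carb[n_m] <- carb
      m_sugar[n_m] <- carb * sugar_frac; m_prot[n_m] <- protein
      m_fat[n_m] <- fat; m_satfat[n_m] <- fat * satfat_frac
      m_fiber[n_m] <- fiber
    }
  }
  meals <- if (n_m) {
    sel <- seq_len(n_m)
    data.frame(day = m_day[sel], time_min = m_tod[sel], food = m_food[sel],
               kcal = m_kcal[sel], carb_g = m_carb[sel],
               sugar_g = m_sugar[sel], protein_g = m_prot[sel],
               fat_g = m_fat[sel], satfat_g = m_satfat[sel],
               fiber_g = m_fiber[sel], stringsAsFactors = FALSE)
  } else empty_meals()

  # exercise bouts: occur physiologically every ~other day; logged subject
  # to the same adherence as meals
  a_day <- integer(D); a_start <- numeric(D); a_dur <- numeric(D)
  a_logged <- logical(D)
  n_b <- 0L
  for (day in seq_len(D)) {
    if (stats::runif(1) > cfg$activity_prob) next
    start <- min(1380, max(300, stats::rnorm(1, 1080, 90)))
    dur <- 30 * rlnorm1(1, 0.40)
    extra <- 0
    if (day >= eff$start_day && eff$activity_increase > 0) {
      extra <- dur * eff$activity_increase
      dur <- dur + extra
    }
    n_b <- n_b + 1L
    a_day[n_b] <- day; a_start[n_b] <- start; a_dur[n_b] <- dur
    a_logged[n_b] <- stats::runif(1) < adherence_vec[day]
    daily$activity_min[day] <- dur
    daily$deficit_kcal[day] <- daily$deficit_kcal[day] + 6 * extra
  }
  bsel <- seq_len(n_b)
  activities <- if (any(a_logged[bsel])) {
    lsel <- bsel[a_logged[bsel]]
    data.frame(day = a_day[lsel],
               time_min = (a_day[lsel] - 1) * 1440 + a_start[lsel],
               minutes = round(a_dur[lsel], 1))
  } else empty_activities()

  # glucose: basal + circadian (dawn peak ~07:00) + meal kernels + noise
  slot_t <- (seq_len(n_slots) - 1) * step
  tod <- slot_t %% 1440
  gl <- cfg$basal_glucose[[category]] +
    cfg$circadian_amp * cos(2 * pi * (tod - 420) / 1440) +
    stats::rnorm(n_slots, 0, cfg$noise_sd)
  if (nrow(meals)) {
    for (i in seq_len(nrow(meals))) {
      off <- slot_t - meals$time_min[i]
      idx <- which(off > 0 & off <= 240)
      if (!length(idx)) next
      peak <- mp$amplitude * meals$carb_g[i] *
        max(0, 1 - mp$fiber_atten * meals$fiber_g[i])
      gl[idx] <- gl[idx] + peak * meal_kernel(off[idx], mp$rise_min,
                                              mp$decay_min)
    }
  }
  gl <- pmin(pmax(gl, 25), 550)

  # contiguous sensor dropouts of 1-8 h until the target count is reached;
  # the last gap is trimmed so the realized fraction matches the target
  miss <- logical(n_slots)
  target <- round(cfg$signal_loss_fraction * n_slots)
  guard <- 0L
  while (sum(miss) < target && guard < 10000L) {
    guard <- guard + 1L
    len <- sample(seq(60 %/% step * 1, 480 %/% step), 1)
    start <- sample(seq_len(n_slots - len + 1), 1)
    new <- setdiff(seq(start, start + len - 1), which(miss))
    need <- target - sum(miss)
    if (length(new) > need) new <- new[seq_len(need)]
    miss[new] <- TRUE
  }
  gl[miss] <- NA_real_

  # per-minute heart rate: diurnal sinusoid + noise, raised during bouts
  n_min <- D * 1440
  tod_min <- (seq_len(n_min) - 1) %% 1440
  hr <- 65 - 8 * cos(2 * pi * tod_min / 1440) + stats::rnorm(n_min, 0, 3)
  for (b in bsel) {
    i0 <- (a_day[b] - 1) * 1440 + floor(a_start[b]) + 1
    idx <- seq(i0, min(n_min, i0 + max(1, round(a_dur[b])) - 1))
    hr[idx] <- hr[idx] + 45
  }
  hr <- pmin(pmax(hr, 35), 210)

  # weight: one pound per 3500 kcal of cumulative deficit; the carb-cut
  # deficit is scaled by 1/adherence to estimate unlogged meals
  daily$deficit_kcal <- daily$deficit_kcal +
    daily$carb_cut_kcal / pmax(daily$adherence, 0.05)
  true_w <- w0 - cumsum(daily$deficit_kcal) / 3500
  wdays <- c(if (stats::runif(1) < 0.9) 1L,
             Filter(function(d) d <= D && stats::runif(1) < 0.35,
                    c(7L, 14L, 21L, 28L)))
  weights <- if (length(wdays)) {
    data.frame(day = as.integer(wdays),
               lbs = round(true_w[as.integer(wdays)] +
                             stats::rnorm(length(wdays), 0, 0.4), 1))
  } else empty_weights()

  participant_record(
    id = as.integer(id), category = category, age = age, sex = sex,
    baseline_weight = w0,
    glucose = glucose_trace(gl, step_min = step),
    heart_rate = hr, meals = meals, activities = activities,
    weights = weights, program_days = D,
    ground_truth = list(
      participant_seed = participant_seed(cfg$seed, id),
      engaged = engaged,
      basal = cfg$basal_glucose[[category]],
      circadian_amp = cfg$circadian_amp,
      effect = eff, meal_params = mp, meal_nutrients = mn,
      daily = daily, true_weight = true_w)
  )
}

#' Generate a synthetic cohort
#'
#' @param cfg A [generator_config()].
#' @return List of [participant_record()]s; category counts follow
#'   `cfg$category_mix` by largest remainder, ids run 1..n.
#' @export
generate_cohort <- function(cfg) {
  n <- cfg$n_participants
  if (n <= 0) stop("n_participants must be positive")
  raw <- cfg$category_mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  cats <- rep(names(counts), counts)
  lapply(seq_len(n), function(i) generate_participant(cfg, cats[i], i))
}

#' Closed-form expected carbohydrate-to-calorie ratios under the generator
#'
#' Because meal composition fluctuations are mean-one and independent of
#' meal size, the pooled carbohydrate-calorie share over many meals
#' converges to `4*carb / kcal` at baseline and to
#' `4*carb*(1-d) / (kcal - 4*d*carb)` in the effect window, where `d` is the
#' injected carbohydrate reduction. Used as the analytic oracle in
#' effect-recovery checks.
#'
#' @param cfg A [generator_config()].
#' @return List with `baseline`, `end`, and `delta` (end minus baseline).
#' @export
expected_carb_ratio_change <- function(cfg) {
  C <- cfg$meal_nutrients$carb_g
  K <- cfg$meal_nutrients$kcal
  d <- cfg$effect$carb_reduction
  base <- 4 * C / K
  end <- 4 * C * (1 - d) / (K - 4 * d * C)
  list(baseline = base, end = end, delta = end - base)
}

#' Write a cohort to a directory of delimited text files
#'
#' Produces `participants.csv`, `glucose.csv`, `hr.csv`, `meals.csv`,
#' `activity.csv`, `weights.csv` (long format keyed by id and minute of
#' program) and `ground_truth.json`.
#'
#' @param cohort List of [participant_record()]s.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grab <- function(f) do.call(rbind, lapply(cohort, f))
  utils::write.csv(grab(function(r) data.frame(
    id = r$id, category = r$category, age = r$age, sex = r$sex,
    baseline_weight = r$baseline_weight, program_days = r$program_days,
    cgm_step = r$glucose$step_min)),
    file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(grab(function(r) data.frame(
    id = r$id, time_min = trace_slot_times(r$glucose),
    glucose = r$glucose$values)),
    file.path(dir, "glucose.csv"), row.names = FALSE)
  utils::write.csv(grab(function(r) data.frame(
    id = r$id, time_min = seq_along(r$heart_rate) - 1, bpm = r$heart_rate)),
    file.path(dir, "hr.csv"), row.names = FALSE)
  utils::write.csv(grab(function(r) if (nrow(r$meals))
    cbind(id = r$id, r$meals) else NULL),
    file.path(dir, "meals.csv"), row.names = FALSE)
  utils::write.csv(grab(function(r) if (nrow(r$activities))
    cbind(id = r$id, r$activities) else NULL),
    file.path(dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(grab(function(r) if (nrow(r$weights))
    cbind(id = r$id, r$weights) else NULL),
    file.path(dir, "weights.csv"), row.names = FALSE)
  gt <- lapply(cohort, function(r) r$ground_truth)
  names(gt) <- vapply(cohort, function(r) as.character(r$id), "")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return List of [participant_record()]s (ground truth restored from
#'   JSON; data-frame fields come back as data frames).
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  parts <- rd("participants.csv")
  glu <- rd("glucose.csv")
  hr <- rd("hr.csv")
  meals <- rd("meals.csv")
  acts <- rd("activity.csv")
  wts <- rd("weights.csv")
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else NULL
  lapply(seq_len(nrow(parts)), function(i) {
    p <- parts[i, ]
    sub <- function(df) df[df$id == p$id, setdiff(names(df), "id"),
                           drop = FALSE]
    m <- sub(meals)
    if (!nrow(m)) m <- empty_meals()
    a <- sub(acts)
    if (!nrow(a)) a <- empty_activities()
    w <- sub(wts)
    if (!nrow(w)) w <- empty_weights()
    participant_record(
      id = p$id, category = p$category, age = p$age, sex = p$sex,
      baseline_weight = p$baseline_weight,
      glucose = glucose_trace(sub(glu)$glucose, step_min = p$cgm_step),
      heart_rate = sub(hr)$bpm, meals = m, activities = a, weights = w,
      program_days = p$program_days,
      ground_truth = if (!is.null(gt)) gt[[as.character(p$id)]] else NULL)
  })
}
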