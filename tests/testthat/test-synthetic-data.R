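test_that("meal response kernel scales with carbs, is attenuated by fiber, and matches direct evaluation", {
  params <- generator_config()$meal_params

  expect_equal(meal_response(nutrient_vector(carb_g = 0), params),
               rep(0, 17))

  one <- meal_response(nutrient_vector(carb_g = 30), params)
  two <- meal_response(nutrient_vector(carb_g = 60), params)
  expect_equal(max(two) / max(one), 2)

  # independent hand evaluation of the kernel on the grid
  amp <- 1.2
  curve <- meal_response(nutrient_vector(carb_g = 50),
                         list(amplitude = amp, fiber_atten = 0.02,
                              rise_min = 30, decay_min = 30))
  t <- seq(0, 240, by = 15)
  p <- 30 / 30
  expected <- amp * 50 * ifelse(t > 0, (t / 30)^p * exp((30 - t) / 30), 0)
  expect_equal(curve, expected, tolerance = 1e-12)
  expect_equal(max(curve), 60)

  expect_equal(curve[1], 0)
  expect_true(all(curve >= 0))
  expect_lt(curve[length(curve)], 1)

  # fiber attenuates the peak linearly down to a floor of zero
  fib <- meal_response(nutrient_vector(carb_g = 50, fiber_g = 10), params)
  expect_equal(max(fib), 60 * (1 - 0.02 * 10))

  expect_error(meal_response(list(carb_g = -5, fiber_g = 0), params),
               "non-negative")
})

test_that("participant glucose decomposes into basal + circadian + logged-meal kernels", {
  cfg <- generator_config(noise_sd = 0, signal_loss_fraction = 0,
                          adherence_start = 1, adherence_end = 1,
                          engaged_frac = 0, seed = 21)
  r <- generate_participant(cfg, "prediabetes", 3)
  tr <- r$glucose
  slot_t <- (seq_along(tr$values) - 1) * tr$step_min
  tod <- slot_t %% 1440
  expected <- 105 + cfg$circadian_amp * cos(2 * pi * (tod - 420) / 1440)
  mp <- cfg$meal_params
  for (i in seq_len(nrow(r$meals))) {
    off <- slot_t - r$meals$time_min[i]
    sel <- off > 0 & off <= 240
    peak <- mp$amplitude * r$meals$carb_g[i] *
      max(0, 1 - mp$fiber_atten * r$meals$fiber_g[i])
    expected[sel] <- expected[sel] + peak *
      (off[sel] / mp$rise_min)^(mp$rise_min / mp$decay_min) *
      exp((mp$rise_min - off[sel]) / mp$decay_min)
  }
  expect_equal(tr$values, pmin(pmax(expected, 25), 550), tolerance = 1e-10)

  # with no meals logged the trace is exactly basal + circadian
  cfg0 <- generator_config(noise_sd = 0, signal_loss_fraction = 0,
                           adherence_start = 0, adherence_end = 0,
                           engaged_frac = 0, seed = 21)
  r0 <- generate_participant(cfg0, "healthy", 1)
  expect_equal(nrow(r0$meals), 0)
  tod0 <- ((seq_along(r0$glucose$values) - 1) * 15) %% 1440
  expect_equal(r0$glucose$values,
               90 + cfg0$circadian_amp * cos(2 * pi * (tod0 - 420) / 1440),
               tolerance = 1e-10)
})

test_that("full adherence yields at least two logged meals every day", {
  cfg <- generator_config(adherence_start = 1, adherence_end = 1, seed = 4)
  r <- generate_participant(cfg, "healthy", 2)
  per_day <- table(factor(r$meals$day, levels = 1:28))
  expect_true(all(per_day >= 2))
})

test_that("records are deterministic in (seed, id) and differ across seeds", {
  cfg <- generator_config(seed = 17)
  a <- generate_participant(cfg, "T2D", 5)
  b <- generate_participant(cfg, "T2D", 5)
  expect_identical(a, b)

  cfg2 <- generator_config(seed = 18)
  c2 <- generate_participant(cfg2, "T2D", 5)
  expect_false(identical(a$meals$time_min, c2$meals$time_min))
  expect_identical(names(a), names(c2))
  expect_identical(names(a$meals), names(c2$meals))
})

test_that("cohort category counts follow the mix", {
  cfg <- generator_config(n_participants = 10,
                          category_mix = c(healthy = 1, prediabetes = 0,
                                           T2D = 0),
                          seed = 1)
  coh <- generate_cohort(cfg)
  expect_length(coh, 10)
  expect_true(all(vapply(coh, function(r) r$category, "") == "healthy"))

  # the default mix reproduces a 746/206/94 split at n = 1046
  cfg2 <- generator_config(n_participants = 1046, seed = 1)
  counts <- floor(cfg2$category_mix * 1046)
  rem <- 1046 - sum(counts)
  extra <- order(cfg2$category_mix * 1046 - counts,
                 decreasing = TRUE)[seq_len(rem)]
  counts[extra] <- counts[extra] + 1
  expect_equal(unname(counts), c(746, 206, 94))

  expect_error(generate_cohort(generator_config(n_participants = 1)), NA)
  expect_error(generator_config(n_participants = 0), "positive")
})

test_that("signal loss hits the target fraction with contiguous gaps", {
  for (f in c(0.05, 0.10, 0.25)) {
    cfg <- generator_config(signal_loss_fraction = f, seed = 9)
    r <- generate_participant(cfg, "healthy", 1)
    n <- length(r$glucose$values)
    realized <- mean(is.na(r$glucose$values))
    expect_lt(abs(realized - f), 3 * sqrt(f * (1 - f) / n) + 1 / n)
  }
})

test_that("injected carb reduction lowers end-window glucose for every participant", {
  cfg <- generator_config(noise_sd = 0, signal_loss_fraction = 0,
                          adherence_start = 1, adherence_end = 1,
                          effect = list(carb_reduction = 0.3,
                                        activity_increase = 0,
                                        start_day = 15),
                          seed = 6)
  for (i in 1:5) {
    r <- generate_participant(cfg, "healthy", i)
    tr <- r$glucose
    base <- mean(tr$values[trace_window(tr, 2:7)])
    end <- mean(tr$values[trace_window(tr, 15:28)])
    expect_lt(end, base)
    # weight drifts downward under the injected deficit
    if (nrow(r$weights)) {
      expect_lt(r$weights$lbs[which.max(r$weights$day)],
                r$baseline_weight + 1)
    }
  }
})

test_that("cohort CSV round trip preserves all streams", {
  cfg <- generator_config(n_participants = 2, program_days = 7, seed = 3)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "participants.csv", "glucose.csv", "hr.csv", "meals.csv",
    "activity.csv", "weights.csv", "ground_truth.json")))))
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$glucose$values, coh[[1]]$glucose$values)
  expect_equal(back[[2]]$meals$carb_g, coh[[2]]$meals$carb_g)
  expect_equal(back[[1]]$category, coh[[1]]$category)
  expect_equal(back[[2]]$weights$lbs, coh[[2]]$weights$lbs)
})

test_that("closed-form carb-ratio expectation follows the injected cut", {
  cfg <- generator_config()
  e0 <- expected_carb_ratio_change(cfg)
  expect_equal(e0$delta, 0)
  cfg2 <- generator_config(effect = list(carb_reduction = 0.3,
                                         activity_increase = 0,
                                         start_day = 15))
  e <- expected_carb_ratio_change(cfg2)
  expect_equal(e$baseline, 4 * 70 / 700)
  expect_equal(e$end, 4 * 70 * 0.7 / (700 - 4 * 0.3 * 70))
  expect_lt(e$delta, 0)
})
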