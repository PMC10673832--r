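# small training configuration used throughout; desk-scale on purpose
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(lstm_units = 12, dense_units = 24, epochs = 10, seed = 2),
    list(...))
  do.call(cgp_config, args)
}

# noiseless, fully adherent participant whose glucose is exactly the meal
# kernel on top of basal + circadian: the learnable benchmark
kernel_record <- function(days = 10, noise = 3, seed = 5) {
  cfg <- generator_config(n_participants = 1, noise_sd = noise,
                          signal_loss_fraction = 0, adherence_start = 1,
                          adherence_end = 1, program_days = days,
                          seed = seed)
  generate_participant(cfg, "healthy", 1)
}

test_that("sequence construction slides windows within complete days", {
  rec <- make_fixture_record(program_days = 1, meals = std_meals(1),
                             weights = data.frame(day = 1L, lbs = 180))
  cfg <- small_cfg()
  seqs <- build_sequences(rec, cfg, min_complete_days = 1)
  expect_equal(seqs$n, 96 - cfg$sequence_length)
  expect_equal(dim(seqs$x), c(80, 16, 12))
  expect_equal(seqs$y, rep(100, 80))

  # fewer than five complete days is an error under the default rule
  expect_error(build_sequences(rec, cfg), "insufficient data")

  # a day without HR capture contributes no sequences
  rec2 <- make_fixture_record(program_days = 2, meals = std_meals(2),
                              hr_minutes_by_day = c(1440L, 600L),
                              weights = data.frame(day = 1L, lbs = 180))
  seqs2 <- build_sequences(rec2, cfg, min_complete_days = 1)
  expect_equal(seqs2$n, 80)
  expect_true(all(seqs2$day == 1))
})

test_that("evaluation metrics match closed forms and keep the shift bound", {
  ev <- cgp_evaluate(c(100, 120, 140), c(100, 120, 140))
  expect_equal(ev$rmse_point_by_point, 0)
  expect_equal(ev$rmse_peak, 0)
  expect_equal(ev$percent_error, 0)

  ev2 <- cgp_evaluate(c(105, 125, 145, 165), c(100, 120, 140, 160))
  expect_equal(ev2$rmse_point_by_point, 5)
  expect_equal(ev2$correlation, 1)

  ev3 <- cgp_evaluate(c(100, 120, 140), c(110, 120, 130))
  expect_equal(ev3$rmse_point_by_point, sqrt(200 / 3), tolerance = 1e-9)

  # a lagged copy is recovered by the shifted metric
  actual <- 100 + 40 * sin(seq(0, 4 * pi, length.out = 48))
  lagged <- c(actual[-(1:2)], actual[47:48])
  ev4 <- cgp_evaluate(lagged, actual)
  expect_lte(ev4$rmse_shifted, ev4$rmse_point_by_point)
  expect_lt(ev4$rmse_shifted, 1e-6)

  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(32, 80, 200)
    a <- runif(32, 80, 200)
    ev5 <- cgp_evaluate(p, a)
    expect_lte(ev5$rmse_shifted, ev5$rmse_point_by_point + 1e-12)
  }
  expect_error(cgp_evaluate(1:5, 1:4), "length mismatch")
})

test_that("training learns kernel dynamics, emits valid distributions, and is seed-deterministic", {
  rec <- kernel_record()
  cfg <- small_cfg()
  sp <- glucowear:::split_days(rec, 0.25)
  tr <- build_sequences(rec, cfg, days = sp$train, min_complete_days = 1)
  te <- build_sequences(rec, cfg, days = sp$test, min_complete_days = 1)
  model <- cgp_train(tr, cfg)

  # loss decreases on average across epochs
  half <- length(model$losses) %/% 2
  expect_lt(mean(model$losses[(half + 1):length(model$losses)]),
            mean(model$losses[1:half]))

  pred <- glucowear:::cgp_predict_sequences(model, te)
  rmse <- sqrt(mean((pred - te$y)^2))
  mean_rmse <- sqrt(mean((mean(tr$y) - te$y)^2))
  pers_rmse <- sqrt(mean((te$x[, dim(te$x)[2], 1] * 60 + 120 - te$y)^2))
  expect_lt(rmse, mean_rmse)
  expect_lt(rmse, pers_rmse)

  # identical seed reproduces the run exactly
  model2 <- cgp_train(tr, cfg)
  expect_identical(model$losses, model2$losses)
  expect_identical(model$par, model2$par)

  # post-meal forecast: distributions are valid at every step
  ctx <- build_frames(rec, sp$test[1])[5:28, ]
  meal <- nutrient_vector(kcal = 700, carb_g = 70, sugar_g = 20,
                          protein_g = 30, fat_g = 25, satfat_g = 9,
                          fiber_g = 6)
  pp <- predict_postprandial(model, ctx, meal)
  expect_equal(nrow(pp$probs), 8)
  expect_equal(rowSums(pp$probs), rep(1, 8), tolerance = 1e-6)
  expect_true(all(pp$probs >= 0))
  expect_true(all(pp$p10 <= pp$p25 & pp$p25 <= pp$p75 & pp$p75 <= pp$p90))

  # a zero-nutrient "meal" on a flat stretch predicts no excursion
  flat_ctx <- glucowear:::blank_frame(
    8 * 1440 + seq(0, by = 15, length.out = 24), glucose = 92, hr = 65)
  pp0 <- predict_postprandial(model, flat_ctx, nutrient_vector())
  expect_true(all(pp0$mean - 92 < 10))

  # doubling the carbs never lowers the predicted 2-h peak (on average)
  peaks <- vapply(seq(30, 90, by = 10), function(cg) {
    single <- predict_postprandial(
      model, ctx, nutrient_vector(kcal = 10 * cg, carb_g = cg))
    double <- predict_postprandial(
      model, ctx, nutrient_vector(kcal = 20 * cg, carb_g = 2 * cg))
    max(double$mean) - max(single$mean)
  }, 0)
  expect_gt(mean(peaks), 0)
})

test_that("virtual CGM rollout stays autoregressive with nested bands", {
  rec <- kernel_record()
  cfg <- small_cfg()
  sp <- glucowear:::split_days(rec, 0.25)
  tr <- build_sequences(rec, cfg, days = sp$train, min_complete_days = 1)
  model <- cgp_train(tr, cfg)

  day <- sp$test[length(sp$test)]
  fr <- build_frames(rec, day)
  roll <- vcgm_rollout(model, fr, init_glucose = fr$glucose[1])
  expect_equal(nrow(roll$probs), nrow(fr))
  expect_true(all(roll$p10 <= roll$p25 & roll$p25 <= roll$p75 &
                    roll$p75 <= roll$p90))
  ev <- cgp_evaluate(roll, fr$glucose)
  expect_lt(ev$rmse_point_by_point, 25)
  expect_gt(ev$correlation, 0.5)

  # a meal-free day stays near basal
  quiet <- fr
  for (nm in c("kcal", "carb_g", "sugar_g", "protein_g", "fat_g",
               "satfat_g", "fiber_g")) quiet[[nm]] <- 0
  roll0 <- vcgm_rollout(model, quiet, init_glucose = 92)
  band <- max(roll0$p90 - roll0$p10)
  expect_lt(max(abs(roll0$mean - 92)), 15 + band)
})

test_that("ablating the dominant driver degrades accuracy most", {
  rec <- kernel_record(days = 10)
  cfg <- small_cfg()
  ab <- cgp_ablation(rec, cfg, mode = "remove_most_important",
                     max_steps = 1)
  expect_equal(ab$ranking[1], "nutrients")
  expect_gt(ab$ladder$rmse[1], ab$rmse_full)

  abr <- cgp_ablation(rec, cfg, mode = "reverse", max_steps = 1)
  # the first group added to a glucose-only model is the most informative
  expect_equal(abr$ladder$group[1], "nutrients")
  expect_lte(abr$ladder$rmse[1], abr$rmse_glucose_only + 0.5)
})

test_that("per-user tuning respects the budget contract and the seed", {
  rec <- kernel_record(days = 8)
  base <- small_cfg(epochs = 5)
  t0 <- per_user_tune(rec, base, budget = 0)
  expect_identical(t0$cfg, base)

  t1 <- per_user_tune(rec, base, budget = 2, seed = 7)
  t2 <- per_user_tune(rec, base, budget = 2, seed = 7)
  expect_identical(t1$cfg, t2$cfg)
  expect_equal(t1$val_nll, t2$val_nll)
  expect_lte(t1$val_nll, t1$base_nll)
})
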