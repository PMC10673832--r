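test_that("nutrient summary applies the 4/9 multipliers over good days only", {
  meals <- rbind(
    std_meal_row(2, 420, kcal = 900),
    std_meal_row(2, 1140, kcal = 700))
  meals$carb_g <- c(30, 20)
  meals$sugar_g <- c(10, 5)
  meals$protein_g <- c(15, 10)
  meals$fat_g <- c(6, 4)
  meals$satfat_g <- c(3, 2)
  meals$fiber_g <- c(4, 4)
  s <- nutrient_summary(meals, 1:7)
  expect_equal(s$n_good_days, 1)
  expect_equal(s$mean_daily_kcal, 1600)
  expect_equal(s$carb_ratio, 4 * 50 / 1600)
  expect_equal(s$protein_ratio, 4 * 25 / 1600)
  expect_equal(s$fat_ratio, 9 * 10 / 1600)
  expect_equal(s$satfat_ratio, 9 * 5 / 1600)
  expect_equal(s$sugar_ratio, 4 * 15 / 1600)
  expect_equal(s$fiber_per_kcal, 8 / 1600)

  # a day below the calorie floor contributes nothing
  low <- meals
  low$kcal <- c(700, 700)
  expect_error(nutrient_summary(low, 1:7), "no good logging days")

  # duplicating every good day's logs leaves all ratios unchanged
  dup <- rbind(meals, transform(meals, day = 3,
                                time_min = time_min + 1440))
  s2 <- nutrient_summary(dup, 1:7)
  for (col in c("carb_ratio", "sugar_ratio", "protein_ratio", "fat_ratio",
                "satfat_ratio", "fiber_per_kcal", "mean_daily_kcal")) {
    expect_equal(s2[[col]], s[[col]], label = col)
  }

  # all-zero macros with logged calories give zero ratios
  zero <- meals
  for (col in c("carb_g", "sugar_g", "protein_g", "fat_g", "satfat_g",
                "fiber_g")) zero[[col]] <- 0
  s3 <- nutrient_summary(zero, 1:7)
  expect_equal(s3$carb_ratio + s3$fat_ratio + s3$fiber_per_kcal, 0)
})

test_that("nutrient summary matches the naive oracle on random logs", {
  for (seed in 1:25) {
    meals <- random_meal_log(seed)
    if (is.null(meals)) next
    expected <- oracle_nutrient_ratios(meals, 1:7)
    if (is.null(expected)) {
      expect_error(nutrient_summary(meals, 1:7), "no good logging days")
    } else {
      got <- nutrient_summary(meals, 1:7)
      for (nm in names(expected)) {
        expect_equal(got[[nm]], expected[[nm]], tolerance = 1e-12,
                     label = paste("seed", seed, nm))
      }
    }
  }
})

test_that("activity minutes are rescaled by the app-interaction ratio", {
  rec <- make_fixture_record()
  rec$activities <- data.frame(
    day = c(1:5, 20:26), time_min = c(1:5, 20:26) * 1440 - 400,
    minutes = 30)
  # equal interaction rates: 3 meal logs/day everywhere, one activity each
  # window day plus identical weight patterns -> adjusted equals raw in
  # the baseline window by construction
  expect_equal(adjusted_activity_minutes(rec, 1:5, baseline_days = 1:5),
               30)

  # halving the end-window interaction rate doubles adjusted minutes
  rec2 <- rec
  rec2$meals <- rec2$meals[!(rec2$meals$day >= 15 &
                               rec2$meals$time_min %% 1440 != 480), ]
  rec2$activities <- rec2$activities[rec2$activities$day <= 5, ]
  rec2$weights <- data.frame(day = 2L, lbs = 180)
  raw_end <- 0
  expect_equal(adjusted_activity_minutes(rec2, 15:28,
                                         baseline_days = 1:5), 0)

  # a window with half the baseline interaction rate scales 30 -> 60
  rec3 <- make_fixture_record()
  rec3$weights <- rec3$weights[0, ]
  rec3$meals <- rbind(
    do.call(rbind, lapply(1:5, function(d) {
      rbind(std_meal_row(d, 480), std_meal_row(d, 780),
            std_meal_row(d, 900), std_meal_row(d, 1140))
    })),
    do.call(rbind, lapply(15:28, function(d) {
      rbind(std_meal_row(d, 480), std_meal_row(d, 1140))
    })))
  rec3$activities <- data.frame(day = 15:28, time_min = (15:28) * 1440 - 300,
                                minutes = 30)
  # baseline: 4 logs/day; end: 2 meal + 1 activity = 3 logs/day
  adj <- adjusted_activity_minutes(rec3, 15:28, baseline_days = 1:5)
  expect_equal(adj, 30 / (3 / 4))
})

test_that("HR-above-threshold minutes count strict exceedances per captured day", {
  rec <- make_fixture_record(program_days = 2, hr_level = 100,
                             meals = std_meals(2),
                             weights = data.frame(day = 1L, lbs = 180))
  expect_equal(hr_above_threshold_minutes(rec, 1:2), 0)

  rec$heart_rate[100:129] <- 120  # 30 contiguous minutes on day 1
  expect_equal(hr_above_threshold_minutes(rec, 1:2), 15)
  expect_equal(hr_above_threshold_minutes(rec, 1), 30)

  # boundary: exactly 110 bpm does not count
  rec$heart_rate[200] <- 110
  expect_equal(hr_above_threshold_minutes(rec, 1), 30)

  # a mixed minute series counts exactly the strict exceedances
  set.seed(1)
  hr <- sample(c(rep(120, 47), rep(90, 1440 - 47)))
  rec2 <- make_fixture_record(program_days = 1, meals = std_meals(1),
                              weights = data.frame(day = 1L, lbs = 180))
  rec2$heart_rate <- hr
  expect_equal(hr_above_threshold_minutes(rec2, 1), 47)

  expect_error(hr_above_threshold_minutes(rec2, 1, excluded = TRUE),
               "excluded")
})

test_that("weight change picks first-in-first-window and last-in-last-window", {
  w <- data.frame(day = c(2, 5, 20, 27), lbs = c(250, 249, 242, 240))
  wc <- weight_change(w)
  expect_equal(wc$weight_delta_lbs, -10)
  expect_equal(wc$weight_delta_pct, -4)

  wc2 <- weight_change(data.frame(day = c(3, 20), lbs = c(200, 195)))
  expect_equal(wc2$weight_delta_lbs, -5)
  expect_equal(wc2$weight_delta_pct, -2.5)

  wc3 <- weight_change(data.frame(day = c(1, 28), lbs = c(180, 180)))
  expect_equal(wc3$weight_delta_lbs, 0)

  expect_error(weight_change(data.frame(day = 2, lbs = 200)),
               "each of the first and last")
})

test_that("weight strata are lower-inclusive and means match a group-by oracle", {
  mk_rec <- function(id, w0, w_end) {
    r <- make_fixture_record(id = id,
                             weights = data.frame(day = c(2L, 27L),
                                                  lbs = c(w0, w_end)))
    r$baseline_weight <- w0
    r$id <- id
    r
  }
  cohort <- list(mk_rec(1, 145, 140), mk_rec(2, 175, 170),
                 mk_rec(3, 250.0, 241), mk_rec(4, 260, 250),
                 mk_rec(5, 220, 218))
  rep <- weight_strata_report(cohort)
  expect_equal(rep$n[rep$stratum == "250-300"], 2)  # 250.0 is inclusive
  expect_equal(rep$mean_loss_lbs[rep$stratum == "250-300"],
               mean(c(250 - 241, 260 - 250)))
  expect_equal(rep$mean_loss_lbs[rep$stratum == "<150"], 5)
  expect_equal(rep$mean_loss_lbs[rep$stratum == "overall"],
               mean(c(5, 5, 9, 10, 2)))
  expect_false("mean_loss_lbs_12wk" %in% names(rep))
  expect_false("300+" %in% rep$stratum)
})
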