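mk <- function(v, step = 15) glucose_trace(v, step)

test_that("time in range counts inclusive bounds over non-missing samples", {
  expect_equal(time_in_range(mk(rep(100, 96)), 1, 70, 140), 100)
  expect_equal(time_in_range(mk(c(rep(120, 48), rep(200, 48))), 1, 70, 180),
               50)
  listed <- c(65, 80, 95, 120, 141, 150, 139, 70, 140, 300)
  expect_equal(time_in_range(mk(listed), 1, 70, 140), 60)
  # missing samples drop from the denominator
  v <- c(listed, rep(NA_real_, 10))
  expect_equal(time_in_range(mk(v), 1, 70, 140), 60)
  expect_error(time_in_range(mk(rep(NA_real_, 96)), 1, 70, 140), "no CGM")
})

test_that("GMI is the consensus linear map of mean glucose", {
  expect_equal(gmi(mk(rep(100, 10)), 1), 5.702)
  expect_equal(gmi(mk(rep(200, 10)), 1), 8.094)
  # strictly increasing in mean glucose
  g <- vapply(seq(80, 240, by = 20),
              function(m) gmi(mk(rep(m, 10)), 1), 0)
  expect_true(all(diff(g) > 0))
})

test_that("event counting uses 2-sample runs, short-gap merging, and lost-time adjustment", {
  expect_equal(count_events(mk(rep(100, 96)), 1, 180, "above"), 0)

  # one 45-min excursion in a fully sampled day
  v <- rep(100, 96)
  v[40:42] <- 200
  expect_equal(count_events(mk(v), 1, 180, "above"), 1)

  # same excursion with half the day missing doubles the rate
  v2 <- v
  v2[seq(2, 96, by = 2)] <- NA
  v2[40:42] <- 200
  lost <- mean(is.na(v2))
  expect_equal(count_events(mk(v2), 1, 180, "above"), 1 / (1 - lost))

  # a single-sample spike is not an event
  v3 <- rep(100, 96)
  v3[50] <- 200
  expect_equal(count_events(mk(v3), 1, 180, "above"), 0)

  # two runs separated by one in-range slot (15 min) merge into one event
  v4 <- rep(100, 96)
  v4[c(40, 41, 43, 44)] <- 200
  expect_equal(count_events(mk(v4), 1, 180, "above"), 1)
  # separated by two slots (30 min) they stay distinct
  v5 <- rep(100, 96)
  v5[c(40, 41, 44, 45)] <- 200
  expect_equal(count_events(mk(v5), 1, 180, "above"), 2)

  # hypoglycemic direction
  v6 <- rep(100, 96)
  v6[10:12] <- 60
  expect_equal(count_events(mk(v6), 1, 70, "below"), 1)

  expect_error(count_events(mk(rep(NA_real_, 96)), 1, 180, "above"),
               "lost time")
})

test_that("coefficient of variation is scale-invariant sample SD over mean", {
  expect_equal(coefficient_of_variation(mk(rep(100, 10)), 1), 0)
  expect_equal(coefficient_of_variation(mk(c(90, 110)), 1),
               100 * sd(c(90, 110)) / 100)
  v <- runif(50, 80, 200)
  expect_equal(coefficient_of_variation(mk(v), 1),
               coefficient_of_variation(mk(2 * v), 1))
})

test_that("metrics match naive per-sample oracles on random traces", {
  for (seed in 1:40) {
    tt <- random_small_trace(seed)
    tr <- tt$trace
    days <- seq_len(tt$n_days)
    v <- tr$values
    expect_equal(time_in_range(tr, days, 70, 140), oracle_tir(v, 70, 140),
                 tolerance = 1e-12)
    expect_equal(gmi(tr, days), oracle_gmi(v), tolerance = 1e-12)
    if (sum(!is.na(v)) >= 2) {
      expect_equal(coefficient_of_variation(tr, days), oracle_cv(v),
                   tolerance = 1e-9)
    }
    for (thr in c(140, 180)) {
      expect_equal(count_events(tr, days, thr, "above"),
                   oracle_events(v, 15, tt$n_days, thr, "above"),
                   tolerance = 1e-12)
    }
    expect_equal(count_events(tr, days, 70, "below"),
                 oracle_events(v, 15, tt$n_days, 70, "below"),
                 tolerance = 1e-12)
  }
})

test_that("range nesting and permutation invariance hold on arbitrary traces", {
  for (seed in 41:55) {
    tt <- random_small_trace(seed)
    tr <- tt$trace
    days <- seq_len(tt$n_days)
    expect_lte(time_in_range(tr, days, 70, 140),
               time_in_range(tr, days, 70, 180))
    # TIR ignores sample order within the window
    perm <- glucose_trace(sample(tr$values), 15)
    expect_equal(time_in_range(perm, days, 70, 140),
                 time_in_range(tr, days, 70, 140))
  }
})

test_that("event rates order by threshold on excursion-shaped CGM traces", {
  # threshold nesting is a property of meal-excursion data (each excursion
  # crossing a higher threshold also crosses the lower ones), not of
  # arbitrary noise; check it on generated participants
  for (seed in 1:6) {
    cfg <- generator_config(n_participants = 1, seed = 300 + seed)
    r <- generate_participant(cfg, sample(c("healthy", "prediabetes",
                                            "T2D"), 1), 1)
    days <- 2:28
    e140 <- count_events(r$glucose, days, 140, "above")
    e180 <- count_events(r$glucose, days, 180, "above")
    e250 <- count_events(r$glucose, days, 250, "above")
    expect_lte(e250, e180 + 1e-12)
    expect_lte(e180, e140 + 1e-12)
  }
})

test_that("glycemic summary picks the category band and degenerates correctly", {
  flat <- make_fixture_record(glucose_level = 95)
  s <- summarize_glycemia(flat, 2:7)
  expect_equal(s$tir_pct, 100)
  expect_equal(s$cv_pct, 0)
  expect_equal(s$events_140 + s$events_180 + s$events_250 + s$events_70, 0)

  t2d <- make_fixture_record(category = "T2D", glucose_level = 170)
  s2 <- summarize_glycemia(t2d, 2:7)
  expect_equal(s2$tir_pct, 100)  # 70-180 band
  s3 <- summarize_glycemia(t2d, 2:7, category = "healthy")
  expect_equal(s3$tir_pct, 0)    # 70-140 band
})

test_that("subgroup deltas form baseline-defined groups and match brute force", {
  cfg <- generator_config(n_participants = 30,
                          effect = list(carb_reduction = 0.3,
                                        activity_increase = 0,
                                        start_day = 15),
                          seed = 23)
  coh <- generate_cohort(cfg)
  sums <- cohort_glycemic_summaries(coh)
  sg <- subgroup_deltas(sums)

  base <- sums[sums$window == "baseline", ]
  end <- sums[sums$window == "end", ]
  end <- end[match(base$id, end$id), ]

  # brute-force the suboptimal-control subgroup mean delta
  sel <- base$tir_pct < 90
  row <- sg[sg$subgroup == "tir_lt90" & sg$category == "all", ]
  if (any(sel)) {
    expect_equal(row$n, sum(sel))
    expect_equal(row$d_tir_pct,
                 mean(end$tir_pct[sel] - base$tir_pct[sel]))
    expect_gt(row$d_tir_pct, 0)
  } else {
    expect_equal(nrow(row), 0)
  }

  # a participant with baseline TIR 85 belongs to <90 but not <70
  expect_true(all(sg$subgroup != "tir_lt70" |
                    sg$n <= sg$n[sg$subgroup == "tir_lt90" &
                                   sg$category == "all"][1]))

  # identical baseline and end leaves all deltas at zero
  same <- rbind(cbind(window = "baseline",
                      summarize_glycemia(make_fixture_record(), 2:7)),
                cbind(window = "end",
                      summarize_glycemia(make_fixture_record(), 2:7)))
  sg0 <- subgroup_deltas(same)
  dcols <- grep("^d_", names(sg0), value = TRUE)
  expect_true(all(abs(as.matrix(sg0[, dcols])) < 1e-12))
})
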