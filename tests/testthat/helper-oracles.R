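# Naive per-sample re-implementations of every metric, kept deliberately
# loop-based and independent of the package's vectorized code paths.

oracle_tir <- function(values, low, high) {
  n_in <- 0L
  n_tot <- 0L
  for (v in values) {
    if (is.na(v)) next
    n_tot <- n_tot + 1L
    if (v >= low && v <= high) n_in <- n_in + 1L
  }
  100 * n_in / n_tot
}

oracle_gmi <- function(values) {
  s <- 0
  n <- 0L
  for (v in values) {
    if (!is.na(v)) {
      s <- s + v
      n <- n + 1L
    }
  }
  3.31 + 0.02392 * (s / n)
}

oracle_cv <- function(values) {
  v <- c()
  for (x in values) if (!is.na(x)) v <- c(v, x)
  m <- sum(v) / length(v)
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  100 * sqrt(ss / (length(v) - 1)) / m
}

oracle_coverage <- function(values, slots_per_day) {
  sum(!is.na(values)) / slots_per_day
}

oracle_events <- function(values, step, n_days, threshold, direction,
                          min_samples = 2, merge_gap_min = 30) {
  beyond <- function(v) {
    !is.na(v) && if (direction == "above") v > threshold else v < threshold
  }
  runs <- list()
  cur_start <- NA
  for (i in seq_along(values)) {
    if (beyond(values[i])) {
      if (is.na(cur_start)) cur_start <- i
    } else if (!is.na(cur_start)) {
      runs[[length(runs) + 1L]] <- c(cur_start, i - 1L)
      cur_start <- NA
    }
  }
  if (!is.na(cur_start)) {
    runs[[length(runs) + 1L]] <- c(cur_start, length(values))
  }
  # merge runs separated by an interval shorter than merge_gap_min
  merged <- list()
  for (r in runs) {
    if (length(merged) &&
        (r[1] - merged[[length(merged)]][2] - 1) * step < merge_gap_min) {
      prev <- merged[[length(merged)]]
      merged[[length(merged)]] <- c(prev[1], r[2], prev[3] + r[2] - r[1] + 1)
    } else {
      merged[[length(merged) + 1L]] <- c(r[1], r[2], r[2] - r[1] + 1)
    }
  }
  n_ev <- 0L
  for (m in merged) if (m[3] >= min_samples) n_ev <- n_ev + 1L
  lost <- mean(is.na(values))
  n_ev / (n_days * (1 - lost))
}

oracle_good_day <- function(tods, kcals, kcal_min = 1600, span_max_h = 16,
                            span_min_h = 4, min_logs = 2) {
  if (length(tods) < min_logs) return(FALSE)
  span <- max(tods) - min(tods)
  span <= span_max_h * 60 && span >= span_min_h * 60 &&
    sum(kcals) >= kcal_min
}

oracle_nutrient_ratios <- function(meals, days) {
  tot <- c(kcal = 0, carb = 0, sugar = 0, protein = 0, fat = 0, satfat = 0,
           fiber = 0)
  n_good <- 0L
  for (d in days) {
    m <- meals[meals$day == d, , drop = FALSE]
    if (!nrow(m)) next
    if (!oracle_good_day(m$time_min, m$kcal)) next
    n_good <- n_good + 1L
    tot <- tot + c(sum(m$kcal), sum(m$carb_g), sum(m$sugar_g),
                   sum(m$protein_g), sum(m$fat_g), sum(m$satfat_g),
                   sum(m$fiber_g))
  }
  if (n_good == 0L) return(NULL)
  list(n_good_days = n_good,
       mean_daily_kcal = tot[["kcal"]] / n_good,
       carb_ratio = 4 * tot[["carb"]] / tot[["kcal"]],
       sugar_ratio = 4 * tot[["sugar"]] / tot[["kcal"]],
       protein_ratio = 4 * tot[["protein"]] / tot[["kcal"]],
       fat_ratio = 9 * tot[["fat"]] / tot[["kcal"]],
       satfat_ratio = 9 * tot[["satfat"]] / tot[["kcal"]],
       fiber_per_kcal = tot[["fiber"]] / tot[["kcal"]])
}

# random small traces used for oracle-equivalence sweeps
random_small_trace <- function(seed) {
  set.seed(seed)
  n_days <- sample(2:4, 1)
  n <- n_days * 96
  v <- runif(n, 55, 320)
  miss <- runif(1, 0, 0.3)
  v[runif(n) < miss] <- NA
  if (sum(!is.na(v)) < 4) v[1:4] <- runif(4, 80, 150)
  list(trace = glucose_trace(v, 15), n_days = n_days)
}

random_meal_log <- function(seed, days = 1:7) {
  set.seed(seed)
  rows <- list()
  for (d in days) {
    k <- sample(0:4, 1)
    if (k == 0) next
    tod <- sort(sample(300:1380, k))
    for (j in seq_len(k)) {
      carb <- runif(1, 10, 120)
      fat <- runif(1, 5, 50)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, time_min = (d - 1) * 1440 + tod[j], food = "x",
        kcal = runif(1, 200, 1400), carb_g = carb,
        sugar_g = carb * runif(1, 0, 1), protein_g = runif(1, 5, 60),
        fat_g = fat, satfat_g = fat * runif(1, 0, 1),
        fiber_g = runif(1, 0, 15))
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
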