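#' Food item
#'
#' @param id Unique identifier.
#' @param name Human-readable name (nonempty).
#' @param nutrients A [nutrient_vector()] for one serving.
#' @param category Category tag (e.g. "grain", "fruit") used by the
#'   similarity blend.
#' @return A list of class `food_item`.
#' @export
food_item <- function(id, name, nutrients, category = "other") {
  if (!nzchar(name)) stop("name must be nonempty")
  structure(list(id = id, name = name, nutrients = nutrients,
                 category = category),
            class = "food_item")
}

# per-100-kcal nutrient densities (excluding kcal itself)
nutrient_density <- function(item) {
  nv <- item$nutrients
  if (nv$kcal <= 0) stop("zero-kcal item has undefined nutrient density")
  unlist(nv[setdiff(nutrient_cols, "kcal")]) / (nv$kcal / 100)
}

#' Similarity between two foods
#'
#' Cosine similarity of per-100-kcal nutrient density vectors, blended
#' with a category-match indicator:
#' `w_nutrient * cosine + w_category * 1[same category]`. Both weights are
#' configurable and sum to 1 by default, keeping the score in \[0, 1\].
#'
#' @param query,candidate [food_item()]s.
#' @param w_nutrient,w_category Blend weights.
#' @return Similarity score in \[0, 1\].
#' @export
food_similarity <- function(query, candidate, w_nutrient = 0.8,
                            w_category = 0.2) {
  a <- nutrient_density(query)
  b <- nutrient_density(candidate)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  cosine <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  w_nutrient * cosine +
    w_category * as.numeric(identical(query$category, candidate$category))
}

#' Healthiness score of a food
#'
#' A carbohydrate/fiber composition scale: fiber density is rewarded and
#' net (non-fiber) carbohydrate density penalized, per 100 kcal:
#' `w_fiber * fiber - w_carb * (carb - fiber)`. Higher is healthier.
#'
#' @param item A [food_item()].
#' @param w_fiber,w_carb Weights (defaults 2 and 1).
#' @return Numeric score (unbounded).
#' @export
healthiness_score <- function(item, w_fiber = 2, w_carb = 1) {
  d <- nutrient_density(item)
  w_fiber * d[["fiber_g"]] -
    w_carb * (d[["carb_g"]] - d[["fiber_g"]])
}

#' Recommend similar but healthier foods
#'
#' Four fixed stages: (1) similarity matching - candidates with
#' similarity to the query of at least `tau`; (2) blacklist removal;
#' (3) healthiness ranking (descending, ties broken by similarity then
#' id); (4) cleanup - items with missing nutrients or healthiness not
#' strictly above the query's are dropped; the list is truncated to `k`.
#'
#' @param query A [food_item()] the user wants to eat.
#' @param database List of [food_item()]s.
#' @param blacklist Character/numeric vector of food ids to exclude
#'   (allergies, sensitivities).
#' @param k Maximum number of recommendations.
#' @param tau Minimum similarity in \[0, 1\].
#' @param ... Passed to [food_similarity()] and [healthiness_score()].
#' @return List of recommended [food_item()]s, healthiest first.
#' @export
recommend_foods <- function(query, database, blacklist = character(),
                            k = 5, tau = 0.5, ...) {
  if (!length(database)) stop("database must be nonempty")
  if (k < 1 || tau < 0 || tau > 1) stop("need k >= 1 and tau in [0, 1]")
  dots <- list(...)
  sim_args <- dots[intersect(names(dots), c("w_nutrient", "w_category"))]
  h_args <- dots[intersect(names(dots), c("w_fiber", "w_carb"))]
  q_health <- do.call(healthiness_score, c(list(query), h_args))
  cand <- Filter(function(it) !identical(it$id, query$id), database)
  sims <- vapply(cand, function(it) {
    do.call(food_similarity, c(list(query, it), sim_args))
  }, 0)
  cand <- cand[sims >= tau]
  cand <- Filter(function(it) !(it$id %in% blacklist), cand)
  if (!length(cand)) return(list())
  ok <- vapply(cand, function(it) {
    !anyNA(unlist(it$nutrients)) &&
      do.call(healthiness_score, c(list(it), h_args)) > q_health
  }, FALSE)
  cand <- cand[ok]
  if (!length(cand)) return(list())
  health <- vapply(cand, function(it) {
    do.call(healthiness_score, c(list(it), h_args))
  }, 0)
  sims2 <- vapply(cand, function(it) {
    do.call(food_similarity, c(list(query, it), sim_args))
  }, 0)
  ids <- vapply(cand, function(it) as.character(it$id), "")
  ord <- order(-health, -sims2, ids)
  utils::head(cand[ord], k)
}

#' Rank foods by observed glucose impact
#'
#' For every food in the meal history, computes the mean incremental area
#' under the post-meal glucose curve (2-h window, trapezoidal,
#' baseline-subtracted; the baseline is the median of readings in the 15
#' minutes before the log). Meals falling in CGM gaps (no baseline sample
#' or fewer than two post-meal samples) contribute nothing; foods with
#' fewer than two usable exposures are flagged low-confidence.
#'
#' @param meals Data frame of meal logs with `food`, `time_min` columns.
#' @param trace The participant's [glucose_trace()].
#' @param post_min Post-meal window in minutes (default 120).
#' @param baseline_min Pre-meal baseline window in minutes (default 15).
#' @return Data frame sorted by descending mean incremental AUC:
#'   `food`, `n`, `mean_iauc` (mg/dL.min), `mean_peak` (mg/dL),
#'   `low_confidence`.
#' @export
identify_spiking_foods <- function(meals, trace, post_min = 120,
                                   baseline_min = 15) {
  if (!nrow(meals)) stop("no meal history")
  times <- trace_slot_times(trace)
  per_meal <- lapply(seq_len(nrow(meals)), function(i) {
    t0 <- meals$time_min[i]
    base_idx <- which(times >= t0 - baseline_min & times < t0 &
                        !is.na(trace$values))
    post_idx <- which(times > t0 & times <= t0 + post_min &
                        !is.na(trace$values))
    if (!length(base_idx) || length(post_idx) < 2) return(NULL)
    baseline <- stats::median(trace$values[base_idx])
    tt <- times[post_idx]
    dv <- trace$values[post_idx] - baseline
    iauc <- sum(diff(tt) * (utils::head(dv, -1) + utils::tail(dv, -1)) / 2)
    data.frame(food = meals$food[i], iauc = iauc, peak = max(dv))
  })
  per_meal <- do.call(rbind, Filter(Negate(is.null), per_meal))
  if (is.null(per_meal) || !nrow(per_meal)) {
    stop("no meals with paired CGM data")
  }
  agg <- do.call(rbind, lapply(split(per_meal, per_meal$food), function(g) {
    data.frame(food = g$food[1], n = nrow(g), mean_iauc = mean(g$iauc),
               mean_peak = mean(g$peak), low_confidence = nrow(g) < 2)
  }))
  agg[order(-agg$mean_iauc), , drop = FALSE]
}

#' Longest daily meal-free interval
#'
#' For each program day, the longest interval without a meal log that
#' starts on that day (bounded by the next day's first meal), i.e. the
#' achieved overnight/daytime fast.
#'
#' @param meals Data frame of meal logs with `time_min`.
#' @param program_days Number of program days.
#' @return Numeric vector of hours per day (`NA` where undefined).
#' @export
longest_daily_fast <- function(meals, program_days) {
  tt <- sort(meals$time_min)
  out <- rep(NA_real_, program_days)
  if (length(tt) < 2) return(out)
  gaps <- data.frame(start = utils::head(tt, -1), len = diff(tt))
  gaps$day <- floor(gaps$start / 1440) + 1
  for (d in unique(gaps$day)) {
    out[d] <- max(gaps$len[gaps$day == d]) / 60
  }
  out
}

#' Mifflin-St Jeor resting energy expenditure
#'
#' @param sex `"male"` or `"female"`.
#' @param age Years.
#' @param weight_kg Body weight in kg.
#' @param height_cm Height in cm.
#' @return Resting energy expenditure in kcal/day.
#' @export
mifflin_st_jeor <- function(sex, age, weight_kg, height_cm) {
  base <- 10 * weight_kg + 6.25 * height_cm - 5 * age
  base + if (identical(sex, "male")) 5 else -161
}

#' Personalized intervention plan (the five levers)
#'
#' Assembles the program's five intervention targets: (1) the user's
#' spiking foods ranked by observed glucose impact; (2) a daily calorie
#' target below the maintenance requirement (Mifflin-St Jeor resting rate
#' times an activity factor, minus a fixed deficit, floored at 1200
#' kcal/day); (3) a fiber goal band by sex (21-25 g/day for females,
#' 30-35 g/day for males); (4) an activity suggestion emphasizing
#' post-meal timing; (5) a 16-h fasting target with the achieved fast
#' computed as the mean longest daily meal-free interval.
#'
#' @param profile List with `sex`, `age`, `weight_kg`, `height_cm`,
#'   `activity_factor` (e.g. 1.2 sedentary to 1.7 very active).
#' @param meals Meal-log history (for spiking foods and fasting).
#' @param trace CGM history paired with the meals.
#' @param program_days Program length (for the fasting computation).
#' @param deficit_kcal Daily deficit below maintenance (default 500).
#' @param activity_min Suggested activity minutes per day (default 30).
#' @param fasting_target_h Fasting target in hours (default 16).
#' @return A list of class `lever_plan`.
#' @export
lever_plan <- function(profile, meals = NULL, trace = NULL,
                       program_days = 28, deficit_kcal = 500,
                       activity_min = 30, fasting_target_h = 16) {
  need <- c("sex", "age", "weight_kg", "height_cm", "activity_factor")
  missing_f <- setdiff(need, names(profile))
  if (length(missing_f)) {
    stop("profile missing fields: ", paste(missing_f, collapse = ", "))
  }
  maintenance <- mifflin_st_jeor(profile$sex, profile$age,
                                 profile$weight_kg, profile$height_cm) *
    profile$activity_factor
  spiking <- if (!is.null(meals) && !is.null(trace) && nrow(meals)) {
    tryCatch(identify_spiking_foods(meals, trace),
             error = function(e) NULL)
  } else NULL
  fasts <- if (!is.null(meals) && nrow(meals) >= 2) {
    longest_daily_fast(meals, program_days)
  } else NA_real_
  structure(
    list(spiking_foods = spiking,
         maintenance_kcal = maintenance,
         calorie_target = max(1200, maintenance - deficit_kcal),
         fiber_goal_g = if (identical(profile$sex, "female")) c(21, 25)
           else c(30, 35),
         activity_suggestion = list(
           minutes_per_day = activity_min,
           note = "prefer post-meal activity to blunt glucose spikes"),
         fasting_target_h = fasting_target_h,
         achieved_fast_h = mean(fasts, na.rm = TRUE),
         fasting_met = mean(fasts, na.rm = TRUE) >= fasting_target_h),
    class = "lever_plan"
  )
}

#' Read a food database from CSV
#'
#' Expected columns: `id`, `name`, `category`, `kcal`, `carb_g`,
#' `sugar_g`, `protein_g`, `fat_g`, `satfat_g`, `fiber_g`.
#'
#' @param path CSV path.
#' @return List of [food_item()]s.
#' @export
read_food_database <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    food_item(df$id[i], df$name[i],
              nutrient_vector(kcal = df$kcal[i], carb_g = df$carb_g[i],
                              sugar_g = df$sugar_g[i],
                              protein_g = df$protein_g[i],
                              fat_g = df$fat_g[i], satfat_g = df$satfat_g[i],
                              fiber_g = df$fiber_g[i]),
              category = df$category[i])
  })
}
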