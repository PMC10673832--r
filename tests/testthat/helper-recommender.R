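# independent brute-force enumeration of all four recommendation stages
brute_recommend <- function(query, db, blacklist = character(), k = 5,
                            tau = 0.5) {
  dens <- function(it) {
    unlist(it$nutrients[c("carb_g", "sugar_g", "protein_g", "fat_g",
                          "satfat_g", "fiber_g")]) /
      (it$nutrients$kcal / 100)
  }
  sim <- function(a, b) {
    x <- dens(a); y <- dens(b)
    cosv <- if (sum(x^2) == 0 || sum(y^2) == 0) 0 else
      sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    0.8 * cosv + 0.2 * (a$category == b$category)
  }
  health <- function(it) {
    d <- dens(it)
    2 * d[["fiber_g"]] - (d[["carb_g"]] - d[["fiber_g"]])
  }
  qh <- health(query)
  keep <- list()
  for (it in db) {
    if (identical(it$id, query$id)) next
    if (sim(query, it) < tau) next
    if (it$id %in% blacklist) next
    if (anyNA(unlist(it$nutrients))) next
    if (health(it) <= qh) next
    keep[[length(keep) + 1L]] <- it
  }
  if (!length(keep)) return(character())
  h <- vapply(keep, health, 0)
  s <- vapply(keep, function(it) sim(query, it), 0)
  ids <- vapply(keep, function(it) as.character(it$id), "")
  utils::head(ids[order(-h, -s, ids)], k)
}

fi <- function(id, kcal, carb, fiber, protein = 10, fat = 5, sugar = 0,
               satfat = 0, category = "grain") {
  food_item(id, paste0("food-", id),
            nutrient_vector(kcal = kcal, carb_g = carb, sugar_g = sugar,
                            protein_g = protein, fat_g = fat,
                            satfat_g = satfat, fiber_g = fiber),
            category = category)
}

random_db <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  lapply(seq_len(n), function(i) {
    carb <- runif(1, 0, 80)
    fat <- runif(1, 0, 30)
    fi(i, kcal = runif(1, 50, 600), carb = carb,
       fiber = runif(1, 0, min(15, carb)),
       protein = runif(1, 0, 40), fat = fat,
       sugar = carb * runif(1), satfat = fat * runif(1),
       category = sample(c("grain", "fruit", "snack"), 1))
  })
}
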