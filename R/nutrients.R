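#' Nutrient vector for one meal or food serving
#'
#' @param kcal Logged total calories. May disagree slightly with the
#'   macro-derived calorie sum, as real food logs do.
#' @param carb_g,sugar_g,protein_g,fat_g,satfat_g,fiber_g Grams of each
#'   nutrient; sugar is a subset of carbohydrate and saturated fat a subset
#'   of total fat.
#' @return A named list of class `nutrient_vector`.
#' @export
nutrient_vector <- function(kcal = 0, carb_g = 0, sugar_g = 0, protein_g = 0,
                            fat_g = 0, satfat_g = 0, fiber_g = 0) {
  x <- list(kcal = kcal, carb_g = carb_g, sugar_g = sugar_g,
            protein_g = protein_g, fat_g = fat_g, satfat_g = satfat_g,
            fiber_g = fiber_g)
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("nutrient values must be finite and non-negative")
  }
  if (sugar_g > carb_g) stop("sugar_g cannot exceed carb_g")
  if (satfat_g > fat_g) stop("satfat_g cannot exceed fat_g")
  structure(x, class = "nutrient_vector")
}

nutrient_cols <- c("kcal", "carb_g", "sugar_g", "protein_g", "fat_g",
                   "satfat_g", "fiber_g")

# energy content of the macro components, 4 kcal/g for carbohydrate, sugar
# and protein; 9 kcal/g for fat and saturated fat
macro_kcal_multipliers <- c(carb_g = 4, sugar_g = 4, protein_g = 4,
                            fat_g = 9, satfat_g = 9)
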