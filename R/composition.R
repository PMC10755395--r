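#' Percentage of total energy from a macronutrient
#'
#' Converts grams of a macronutrient to its contribution to total energy,
#' using kcal/g factors of 4 (protein), 9 (fat and saturated fat) and 3.9
#' (sugars), then expresses it as a percentage.
#'
#' @param nutrient_g Grams per day (non-negative, vectorised).
#' @param energy_kcal Total energy per day, kcal (> 0, vectorised).
#' @param nutrient One of `"sugars_g"`, `"protein_g"`, `"fat_g"`,
#'   `"satfat_g"` (or the short forms without `_g`).
#' @return Percentage of total energy.
#' @examples
#' percent_energy(50, 2000, "protein_g")  # 10
#' percent_energy(100, 2000, "sugars_g")  # 19.5
#' @export
percent_energy <- function(nutrient_g, energy_kcal, nutrient) {
  nutrient <- match.arg(sub("_g$", "", nutrient),
                        c("sugars", "protein", "fat", "satfat"))
  fac <- energy_factors()[[paste0(nutrient, "_g")]]
  if (any(is.na(energy_kcal)) || any(energy_kcal <= 0)) {
    stop_domain("percent_energy is undefined when energy_kcal <= 0")
  }
  if (any(nutrient_g < 0)) stop_domain("nutrient grams must be >= 0")
  100 * fac * nutrient_g / energy_kcal
}

#' Sodium density (mg per kcal)
#'
#' @param sodium_mg Sodium, mg/day (vectorised).
#' @param energy_kcal Total energy, kcal/day (> 0).
#' @return mg sodium per kcal.
#' @examples
#' sodium_density(2120, 2000)  # 1.06
#' @export
sodium_density <- function(sodium_mg, energy_kcal) {
  if (any(is.na(energy_kcal)) || any(energy_kcal <= 0)) {
    stop_domain("sodium_density is undefined when energy_kcal <= 0")
  }
  if (any(sodium_mg < 0)) stop_domain("sodium_mg must be >= 0")
  sodium_mg / energy_kcal
}

#' Relative (energy-adjusted) nutrient profile
#'
#' Expresses a daily nutrient vector as percentages of total energy
#' (sugars, protein, fat, saturated fat) and sodium density in mg/kcal.
#' Relative profiles are invariant to scaling the whole vector, hence
#' identical before and after household-to-individual allocation.
#' Percentages are not renormalised to sum to 100: unmodelled energy
#' sources (e.g. non-sugar carbohydrate, alcohol) account for the rest.
#'
#' @param v Named nutrient vector (see [nutrient_vector()]) with
#'   `energy_kcal > 0`.
#' @return Named numeric vector with components `sugars_pctE`,
#'   `protein_pctE`, `fat_pctE`, `satfat_pctE`, `sodium_mg_kcal`.
#' @examples
#' v <- nutrient_vector(2000, 100, 50, 80, 30, 2120)
#' relative_profile(v)
#' relative_profile(v * 0.36)  # identical
#' @export
relative_profile <- function(v) {
  validate_nutrient_vector(v)
  e <- v[["energy_kcal"]]
  if (e <= 0) stop_domain("relative_profile is undefined when energy_kcal <= 0")
  c(
    sugars_pctE = percent_energy(v[["sugars_g"]], e, "sugars"),
    protein_pctE = percent_energy(v[["protein_g"]], e, "protein"),
    fat_pctE = percent_energy(v[["fat_g"]], e, "fat"),
    satfat_pctE = percent_energy(v[["satfat_g"]], e, "satfat"),
    sodium_mg_kcal = sodium_density(v[["sodium_mg"]], e)
  )
}

#' Names of the five relative measures
#' @return Character vector.
#' @export
relative_cols <- function() {
  c("sugars_pctE", "protein_pctE", "fat_pctE", "satfat_pctE", "sodium_mg_kcal")
}

# Internal: add prefixed relative-measure columns to a frame that carries
# prefixed nutrient columns. Rows with zero/NA energy get NA (pipeline
# exclusions guarantee positive energy in the analysis set).
add_relative_cols <- function(df, prefix_in, prefix_out) {
  e <- df[[paste0(prefix_in, "energy_kcal")]]
  ok <- !is.na(e) & e > 0
  safe_e <- ifelse(ok, e, NA_real_)
  fac <- energy_factors()
  for (nut in names(fac)) {
    out <- paste0(prefix_out, sub("_g$", "_pctE", nut))
    df[[out]] <- 100 * fac[[nut]] * df[[paste0(prefix_in, nut)]] / safe_e
  }
  df[[paste0(prefix_out, "sodium_mg_kcal")]] <-
    df[[paste0(prefix_in, "sodium_mg")]] / safe_e
  df
}
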