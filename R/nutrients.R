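#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' The six analytes carried through every pipeline stage
#'
#' Column-name conventions used everywhere in the package: energy in kcal,
#' sugars/protein/fat/saturated fat in grams, sodium in mg — all per day
#' once a daily estimate has been formed.
#'
#' @return Character vector of the six nutrient column names.
#' @export
nutrient_cols <- function() {
  c("energy_kcal", "sugars_g", "protein_g", "fat_g", "satfat_g", "sodium_mg")
}

#' Energy conversion factors (kcal per gram)
#'
#' Factors used to express macronutrients as a percentage of total energy.
#' Note sugars uses 3.9 kcal/g (not the conventional 4), matching the
#' back-of-pack convention adopted throughout.
#'
#' @return Named numeric vector with elements `sugars_g`, `protein_g`,
#'   `fat_g`, `satfat_g`.
#' @export
energy_factors <- function() {
  c(sugars_g = 3.9, protein_g = 4, fat_g = 9, satfat_g = 9)
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector over the six analytes. All
#' components must be non-negative and saturated fat cannot exceed total
#' fat.
#'
#' @param energy_kcal,sugars_g,protein_g,fat_g,satfat_g,sodium_mg
#'   Non-negative scalars.
#' @return Named numeric vector of length 6.
#' @examples
#' nutrient_vector(energy_kcal = 2000, sugars_g = 95, protein_g = 70,
#'                 fat_g = 80, satfat_g = 30, sodium_mg = 2100)
#' @export
nutrient_vector <- function(energy_kcal = 0, sugars_g = 0, protein_g = 0,
                            fat_g = 0, satfat_g = 0, sodium_mg = 0) {
  v <- c(energy_kcal = energy_kcal, sugars_g = sugars_g,
         protein_g = protein_g, fat_g = fat_g, satfat_g = satfat_g,
         sodium_mg = sodium_mg)
  validate_nutrient_vector(v)
  v
}

validate_nutrient_vector <- function(v, where = "nutrient vector") {
  if (!is.numeric(v) || !all(nutrient_cols() %in% names(v))) {
    abort(paste0(where, " must be numeric with components ",
                 paste(nutrient_cols(), collapse = ", ")),
          class = "basketdiet_error_data")
  }
  if (anyNA(v[nutrient_cols()]) || any(v[nutrient_cols()] < 0)) {
    abort(paste0(where, ": all components must be non-negative and non-missing"),
          class = "basketdiet_error_data")
  }
  if (v[["satfat_g"]] > v[["fat_g"]] + 1e-9) {
    abort(paste0(where, ": satfat_g exceeds fat_g"),
          class = "basketdiet_error_data")
  }
  invisible(v)
}

# Internal: assert a data frame carries the six (possibly prefixed) nutrient
# columns, e.g. prefix = "hh_" for household-level daily estimates.
check_nutrient_frame <- function(df, prefix = "", where = "data") {
  need <- paste0(prefix, nutrient_cols())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(where, " is missing columns: ", paste(missing, collapse = ", ")),
          class = "basketdiet_error_data")
  }
  invisible(df)
}

stop_config <- function(msg) abort(msg, class = "basketdiet_error_config")
stop_data <- function(msg) abort(msg, class = "basketdiet_error_data")
stop_lookup <- function(msg) abort(msg, class = "basketdiet_error_lookup")
stop_domain <- function(msg) abort(msg, class = "basketdiet_error_domain")
stop_insufficient <- function(msg) abort(msg, class = "basketdiet_error_insufficient_data")
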