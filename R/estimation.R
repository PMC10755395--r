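#' Define a comparison period
#'
#' A closed date interval; `n_days` counts both endpoints.
#'
#' @param start Start date (Date or ISO-8601 string).
#' @param n_days Number of calendar days in the period (>= 1).
#' @return List with `start`, `end`, `n_days`.
#' @examples
#' comparison_period("2021-01-01", 91)
#' @export
comparison_period <- function(start, n_days) {
  start <- as.Date(start)
  if (is.na(start)) stop_data("invalid start date")
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1) stop_config("n_days must be >= 1")
  list(start = start, end = start + (n_days - 1L), n_days = n_days)
}

# Internal: per-product grams for one purchase unit, from pack fields.
unit_grams <- function(catalogue) {
  g <- ifelse(catalogue$pack_unit %in% c("g", "ml"),
              catalogue$pack_amount, catalogue$unit_net_weight_g)
  if (any(catalogue$pack_unit == "each" &
          (is.na(catalogue$unit_net_weight_g) | catalogue$unit_net_weight_g <= 0))) {
    stop_data("pack_unit = 'each' requires a positive unit_net_weight_g")
  }
  g
}

# Internal: TRUE where a per-100 profile is usable; blank (all-NA) or
# all-zero profiles count as missing and are imputed.
has_profile <- function(catalogue) {
  per100 <- as.matrix(catalogue[paste0("per100_", nutrient_cols())])
  apply(per100, 1, function(r) !all(is.na(r)) && any(r > 0))
}

#' Resolve transaction lines to total nutrients
#'
#' Links each line to the product catalogue by `product_id` and computes
#' the line's total nutrients: per-100 profile times total grams / 100,
#' where total grams is quantity x pack_amount for pack units of g or ml
#' (1 ml is treated as 1 g) and quantity x unit_net_weight_g for unit
#' packs. Products with an absent or blank per-100 profile fall back to
#' the generic entry for their food category; provenance records which
#' route was used.
#'
#' @param lines Tibble of transaction lines: `customer_id`,
#'   `transaction_id`, `date`, `product_id`, `quantity`, `cost`.
#' @param catalogue Product catalogue with `product_id`, `category`,
#'   `pack_amount`, `pack_unit`, `unit_net_weight_g` and
#'   `per100_<nutrient>` columns (NA when missing).
#' @param generics Generic food-composition table with `category` and
#'   `per100_<nutrient>` columns, one row per category 1-15.
#' @return `lines` with added `provenance` (`"retailer"`/`"generic"`) and
#'   the six total-nutrient columns.
#' @export
resolve_lines <- function(lines, catalogue, generics) {
  check_nutrient_frame(catalogue, "per100_", "catalogue")
  check_nutrient_frame(generics, "per100_", "generic table")
  if (anyDuplicated(catalogue$product_id)) {
    stop_data("duplicate product_id in catalogue")
  }
  unknown <- setdiff(unique(lines$product_id), catalogue$product_id)
  if (length(unknown) > 0) {
    stop_lookup(paste0("unknown product_id(s): ",
                       paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (any(is.na(lines$quantity)) || any(lines$quantity <= 0)) {
    stop_data("all quantities must be > 0")
  }
  cat2 <- catalogue
  cat2$grams_per_unit <- unit_grams(cat2)
  cat2$retailer_profiled <- has_profile(cat2)
  per100 <- as.matrix(cat2[paste0("per100_", nutrient_cols())])
  gen <- generics[order(generics$category), ]
  gen100 <- as.matrix(gen[paste0("per100_", nutrient_cols())])
  gidx <- match(cat2$category, gen$category)
  use_gen <- !cat2$retailer_profiled
  if (any(use_gen & is.na(gidx))) {
    stop_lookup("generic table does not cover every category with unprofiled products")
  }
  eff100 <- per100
  eff100[use_gen, ] <- gen100[gidx[use_gen], , drop = FALSE]

  li <- match(lines$product_id, cat2$product_id)
  grams <- lines$quantity * cat2$grams_per_unit[li]
  nut <- eff100[li, , drop = FALSE] * (grams / 100)
  colnames(nut) <- nutrient_cols()
  out <- as_tibble(lines)
  out$provenance <- ifelse(cat2$retailer_profiled[li], "retailer", "generic")
  dplyr::bind_cols(out, as_tibble(nut))
}

#' Resolve a single transaction line
#'
#' Convenience single-line wrapper around [resolve_lines()].
#'
#' @inheritParams resolve_lines
#' @param line One-row tibble or named list with the transaction-line
#'   fields.
#' @return Named list: `nutrients` (named vector) and `provenance`.
#' @export
resolve_line <- function(line, catalogue, generics) {
  res <- resolve_lines(as_tibble(line), catalogue, generics)
  list(nutrients = unlist(res[1, nutrient_cols()]),
       provenance = res$provenance[1])
}

#' Product match rate before and after generic imputation
#'
#' Pre-imputation: the fraction of distinct purchased products carrying a
#' usable retailer per-100 profile. Post-imputation: 1 whenever the
#' generic table covers all 15 categories (every line can be resolved).
#'
#' @inheritParams resolve_lines
#' @return Named list `pre_imputation_rate`, `post_imputation_rate`.
#' @export
match_rate <- function(lines, catalogue, generics) {
  if (nrow(lines) == 0) stop_insufficient("match rate is undefined for empty lines")
  prods <- unique(lines$product_id)
  li <- match(prods, catalogue$product_id)
  if (anyNA(li)) stop_lookup("lines reference products not in the catalogue")
  profiled <- has_profile(catalogue)[li]
  covered <- all(1:15 %in% generics$category)
  list(pre_imputation_rate = mean(profiled),
       post_imputation_rate = if (covered) 1.0 else
         mean(profiled | catalogue$category[li] %in% generics$category))
}

#' Mean daily household nutrient estimate over a comparison period
#'
#' Sums resolved line nutrients dated inside the (closed) period and
#' divides by the number of days in the period. Lines outside the period
#' are ignored. With no in-period lines the zero vector is returned with
#' attribute `no_purchases = TRUE`.
#'
#' @param resolved Output of [resolve_lines()] (must carry `date` and the
#'   six nutrient columns).
#' @param period A [comparison_period()].
#' @return Named daily nutrient vector with attribute `no_purchases`.
#' @export
daily_household_estimate <- function(resolved, period) {
  check_nutrient_frame(resolved, where = "resolved lines")
  dates <- as.Date(resolved$date)
  inper <- dates >= period$start & dates <= period$end
  tot <- colSums(resolved[inper, nutrient_cols(), drop = FALSE])
  out <- tot / period$n_days
  attr(out, "no_purchases") <- !any(inper)
  out
}

#' Per-participant mean daily household purchase estimates
#'
#' Vectorised pipeline stage: resolves all lines and computes each
#' participant's mean daily household nutrient vector over their own
#' primary comparison period.
#'
#' @param lines Transaction lines for all participants (`customer_id`
#'   matches `participant_id`).
#' @inheritParams resolve_lines
#' @param periods Tibble with `participant_id`, `period_start`,
#'   `period_days`.
#' @return Tibble with `participant_id`, `no_purchases`, and `hh_<nutrient>`
#'   daily columns (zero when no in-period purchase).
#' @export
estimate_daily_purchases <- function(lines, catalogue, generics, periods) {
  resolved <- resolve_lines(lines, catalogue, generics)
  resolved$date <- as.Date(resolved$date)
  per <- dplyr::transmute(
    periods,
    participant_id = .data$participant_id,
    period_start = as.Date(.data$period_start),
    period_end = .data$period_start + (as.integer(.data$period_days) - 1L),
    period_days = as.integer(.data$period_days)
  )
  joined <- dplyr::inner_join(resolved, per,
                              by = c(customer_id = "participant_id")) %>%
    dplyr::filter(.data$date >= .data$period_start, .data$date <= .data$period_end)
  sums <- joined %>%
    dplyr::group_by(participant_id = .data$customer_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrient_cols()), sum),
                     .groups = "drop")
  out <- per %>%
    dplyr::left_join(sums, by = "participant_id") %>%
    dplyr::mutate(
      no_purchases = is.na(.data$energy_kcal),
      dplyr::across(dplyr::all_of(nutrient_cols()),
                    ~ dplyr::coalesce(.x, 0) / .data$period_days)
    ) %>%
    dplyr::select("participant_id", "no_purchases",
                  dplyr::all_of(nutrient_cols()))
  dplyr::rename_with(out, ~ paste0("hh_", .x), dplyr::all_of(nutrient_cols()))
}
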