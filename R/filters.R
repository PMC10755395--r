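#' Apply the study inclusion/exclusion rules
#'
#' Exclusions are applied in the order reported by the recruitment funnel:
#' (1) no completed FFQ record; (2) no purchase with the retailer inside
#' the primary comparison period; (3) FFQ daily energy >= 8000 kcal (four
#' times an adult woman's recommended intake; the boundary itself is
#' excluded). Each rule's count goes into an auditable exclusion ledger.
#'
#' @param participants Tibble with one row per candidate, keyed by
#'   `participant_id`.
#' @param ffq Tibble of completed FFQ records: `participant_id` plus
#'   `ffq_<nutrient>` daily intake columns.
#' @param purchases Tibble from [estimate_daily_purchases()]:
#'   `participant_id`, `no_purchases`, `hh_<nutrient>` columns.
#' @return List with `analysis_set` (participants joined to their FFQ and
#'   purchase estimates) and `ledger` (tibble: `rule`, `n_excluded`, plus
#'   attribute rows for initial and final n).
#' @export
apply_exclusions <- function(participants, ffq, purchases) {
  if (anyDuplicated(participants$participant_id)) {
    stop_data("duplicate participant_id in participants")
  }
  if (anyDuplicated(ffq$participant_id)) {
    stop_data("duplicate participant_id in ffq records")
  }
  n0 <- nrow(participants)
  cur <- dplyr::left_join(participants, ffq, by = "participant_id")
  no_ffq <- is.na(cur$ffq_energy_kcal)
  n_no_ffq <- sum(no_ffq)
  cur <- cur[!no_ffq, , drop = FALSE]

  cur <- dplyr::left_join(cur, purchases, by = "participant_id")
  no_purch <- is.na(cur$hh_energy_kcal) | cur$no_purchases
  n_no_purch <- sum(no_purch)
  cur <- cur[!no_purch, , drop = FALSE]

  outlier <- cur$ffq_energy_kcal >= 8000
  n_outlier <- sum(outlier)
  cur <- cur[!outlier, , drop = FALSE]

  ledger <- tibble(
    rule = c("no completed FFQ", "no in-period purchase",
             "FFQ energy >= 8000 kcal/d"),
    n_excluded = c(n_no_ffq, n_no_purch, n_outlier)
  )
  attr(ledger, "n_initial") <- n0
  attr(ledger, "n_final") <- nrow(cur)
  stopifnot(n0 - sum(ledger$n_excluded) == nrow(cur))
  list(analysis_set = as_tibble(cur), ledger = ledger)
}

#' Sensitivity filter on low purchased energy
#'
#' Removes participants whose mean daily purchased energy is strictly
#' below the threshold (default 500 kcal/d, a quarter of an adult woman's
#' recommended intake); exactly 500 kcal/d is retained. Very low
#' purchasing is taken to indicate food sourced elsewhere rather than low
#' intake. The energy level tested is household-level by default,
#' switchable to the individual allocation.
#'
#' @param analysis_set Tibble carrying `hh_energy_kcal` (and
#'   `ind_energy_kcal` if `level = "individual"`).
#' @param threshold_kcal Threshold in kcal/day (> 0).
#' @param level `"household"` (default) or `"individual"`.
#' @return List with `subset` and `n_excluded`.
#' @export
sensitivity_filter <- function(analysis_set, threshold_kcal = 500,
                               level = c("household", "individual")) {
  level <- match.arg(level)
  if (is.na(threshold_kcal) || threshold_kcal <= 0) {
    stop_config("sensitivity threshold must be > 0")
  }
  col <- if (level == "household") "hh_energy_kcal" else "ind_energy_kcal"
  if (!col %in% names(analysis_set)) {
    stop_data(paste0("column '", col, "' not present in analysis set"))
  }
  keep <- analysis_set[[col]] >= threshold_kcal
  list(subset = analysis_set[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Assign household-size and loyalty subgroups
#'
#' Household sizes of three or more are combined ("3+"); the three lowest
#' self-reported loyalty bands (0-20 %, 21-40 %, 41-60 % of food shopping
#' with the retailer) are combined into a low-medium group, with 61-80 %
#' as high and 81-100 % as very high loyalty.
#'
#' @param data Tibble with `household_size` (integer >= 1) and
#'   `loyalty_band` (one of `"0-20%"`, `"21-40%"`, `"41-60%"`, `"61-80%"`,
#'   `"81-100%"`).
#' @return `data` with added `household_size_group` and `loyalty_group`.
#' @export
assign_subgroups <- function(data) {
  if (any(is.na(data$household_size)) || any(data$household_size < 1)) {
    stop_data("household_size must be >= 1")
  }
  bands <- loyalty_bands()
  bad <- setdiff(unique(data$loyalty_band), bands)
  if (length(bad) > 0) {
    stop_data(paste0("unrecognized loyalty band(s): ", paste(bad, collapse = ", ")))
  }
  data$household_size_group <- dplyr::case_when(
    data$household_size == 1 ~ "1",
    data$household_size == 2 ~ "2",
    TRUE ~ "3+"
  )
  data$loyalty_group <- dplyr::case_when(
    data$loyalty_band %in% bands[1:3] ~ "low-medium (0-60%)",
    data$loyalty_band == bands[4] ~ "high (61-80%)",
    TRUE ~ "very high (81-100%)"
  )
  data
}

#' The five self-reported loyalty bands
#' @return Character vector of band labels.
#' @export
loyalty_bands <- function() {
  c("0-20%", "21-40%", "41-60%", "61-80%", "81-100%")
}

#' Recruitment eligibility screen on a year of purchase history
#'
#' A customer is screened in as a likely primary shopper when, over one
#' calendar year, they shopped in at least `min_categories` of the 15 food
#' categories on at least `min_occasions` distinct shopping occasions, and
#' (optionally) their annual spend lies within bounds derived from a
#' reference distribution: at most Q3 + 1.5 x IQR, and at least a
#' configured lower bound excluding an equal proportion from the lower
#' tail.
#'
#' @param history Tibble of one customer's transaction lines over a year,
#'   with `transaction_id`, `cost` and a product `category` column (join
#'   the catalogue first if needed).
#' @param min_categories Minimum distinct food categories (default 7).
#' @param min_occasions Minimum distinct shopping occasions (default 10).
#' @param spend_rule Optional list with reference quartiles `q1`, `q3` and
#'   `lower` (the lower spend bound); `NULL` (default) disables the spend
#'   rule, as in synthetic runs where no external reference exists.
#' @return Logical: eligible or not.
#' @export
eligibility_screen <- function(history, min_categories = 7, min_occasions = 10,
                               spend_rule = NULL) {
  if (!"category" %in% names(history)) {
    stop_data("history must carry a product 'category' column")
  }
  ok <- dplyr::n_distinct(history$category) >= min_categories &&
    dplyr::n_distinct(history$transaction_id) >= min_occasions
  if (!is.null(spend_rule)) {
    if (is.null(spend_rule$q1) || is.null(spend_rule$q3)) {
      stop_config("spend_rule requires reference quartiles q1 and q3")
    }
    iqr <- spend_rule$q3 - spend_rule$q1
    upper <- spend_rule$q3 + 1.5 * iqr
    lower <- if (is.null(spend_rule$lower)) -Inf else spend_rule$lower
    spend <- sum(history$cost)
    ok <- ok && spend <= upper && spend >= lower
  }
  ok
}
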