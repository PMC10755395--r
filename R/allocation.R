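#' Default age/gender recommended daily energy intake table
#'
#' Recommended daily energy intakes (kcal) by age band and gender, used to
#' allocate household purchased nutrients to individuals. The defaults are
#' plausible UK reference values constrained so that three verifiable
#' anchors hold exactly: a 30-year-old woman has 1928 kcal, the
#' female/male average at age 30 is 2230 kcal, and the average at age 3 is
#' 1197.5 kcal. Users validating against official recommendations should
#' supply their own table via [load_energy_table()].
#'
#' @return A tibble with columns `age_min`, `age_max`, `female_kcal`,
#'   `male_kcal`; bands are contiguous, non-overlapping and cover ages
#'   0-120 inclusive.
#' @examples
#' default_energy_table()
#' @export
default_energy_table <- function() {
  tbl <- tibble::tribble(
    ~age_min, ~age_max, ~female_kcal, ~male_kcal,
    0L,   1L,   650,  720,
    2L,   3L,  1132, 1263,
    4L,   6L,  1380, 1520,
    7L,  10L,  1700, 1880,
    11L, 14L,  1900, 2200,
    15L, 17L,  2000, 2500,
    18L, 59L,  1928, 2532,
    60L, 74L,  1850, 2300,
    75L, 120L, 1750, 2100
  )
  validate_energy_table(tbl)
}

validate_energy_table <- function(tbl) {
  need <- c("age_min", "age_max", "female_kcal", "male_kcal")
  if (!all(need %in% names(tbl))) {
    stop_config(paste("energy table must have columns",
                      paste(need, collapse = ", ")))
  }
  tbl <- dplyr::arrange(as_tibble(tbl), .data$age_min)
  if (any(tbl$female_kcal <= 0) || any(tbl$male_kcal <= 0)) {
    stop_config("energy table: all kcal values must be > 0")
  }
  if (any(tbl$age_max < tbl$age_min)) {
    stop_config("energy table: age_max < age_min in some band")
  }
  if (tbl$age_min[1] != 0 || tbl$age_max[nrow(tbl)] < 120) {
    stop_config("energy table must cover ages 0-120")
  }
  if (nrow(tbl) > 1 &&
      any(tbl$age_min[-1] != tbl$age_max[-nrow(tbl)] + 1L)) {
    stop_config("energy table bands must be contiguous and non-overlapping")
  }
  tbl
}

#' Read a recommended-energy table from CSV
#'
#' The CSV must have columns `age_min`, `age_max`, `female_kcal`,
#' `male_kcal` with contiguous, non-overlapping age bands covering 0-120.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble (see [default_energy_table()]).
#' @export
load_energy_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_energy_table(tbl)
}

#' Recommended daily energy intake for one person
#'
#' Looks up the age band and returns the gender-specific recommendation;
#' for `gender = "unknown"` (non-participant household members, whose
#' genders are not collected) the arithmetic mean of the female and male
#' values is used.
#'
#' @param age Age in whole years (vectorised).
#' @param gender One of `"female"`, `"male"`, `"unknown"` (vectorised,
#'   recycled against `age`).
#' @param table Recommendation table, by default [default_energy_table()].
#' @return Numeric vector of kcal/day.
#' @examples
#' recommended_energy(30, "female")   # 1928
#' recommended_energy(30, "unknown")  # 2230
#' recommended_energy(3, "unknown")   # 1197.5
#' @export
recommended_energy <- function(age, gender, table = default_energy_table()) {
  table <- validate_energy_table(table)
  n <- max(length(age), length(gender))
  age <- rep_len(age, n)
  gender <- rep_len(gender, n)
  if (!all(gender %in% c("female", "male", "unknown"))) {
    stop_data("gender must be one of 'female', 'male', 'unknown'")
  }
  idx <- findInterval(age, table$age_min)
  bad <- is.na(age) | age < 0 | idx < 1 | age > table$age_max[pmax(idx, 1)]
  if (any(bad)) {
    stop_domain(paste0("age(s) outside energy-table coverage: ",
                       paste(unique(age[bad]), collapse = ", ")))
  }
  f <- table$female_kcal[idx]
  m <- table$male_kcal[idx]
  dplyr::case_when(
    gender == "female" ~ f,
    gender == "male" ~ m,
    TRUE ~ (f + m) / 2
  )
}

#' Energy-proportional allocation share for a study participant
#'
#' The share of household purchased nutrients attributed to the
#' participant: their recommended energy intake divided by the sum over
#' all household members. The participant's own gender is known; other
#' members use the unknown-gender (female/male average) rule.
#'
#' @param age Participant age in years.
#' @param gender Participant gender, `"female"` or `"male"`.
#' @param member_ages Integer vector of the other household members' ages
#'   (length 0 for a single-person household).
#' @param table Recommendation table.
#' @return Share in (0, 1].
#' @examples
#' # 30-year-old woman, 30-year-old partner, 3-year-old child: 36%
#' allocation_share(30, "female", c(30, 3))
#' @export
allocation_share <- function(age, gender, member_ages = integer(0),
                             table = default_energy_table()) {
  if (length(age) != 1 || length(gender) != 1) {
    stop_data("allocation_share() takes one participant at a time")
  }
  if (!gender %in% c("female", "male")) {
    stop_data("a participant's own gender must be 'female' or 'male'")
  }
  w <- household_weights(age, gender, member_ages, table)
  w[1] / sum(w)
}

#' Recommended-energy weights for every household member
#'
#' First element is the participant (own gender); remaining elements are
#' the other members under the unknown-gender rule. Shares derived from a
#' single weight vector sum to exactly 1, so allocation conserves the
#' household total.
#'
#' @inheritParams allocation_share
#' @return Numeric vector of kcal weights, participant first.
#' @export
household_weights <- function(age, gender, member_ages = integer(0),
                              table = default_energy_table()) {
  self <- recommended_energy(age, gender, table)
  if (length(member_ages) == 0) return(self)
  others <- recommended_energy(member_ages, "unknown", table)
  c(self, others)
}

#' Scale a household daily estimate to an individual
#'
#' Multiplies every nutrient component by the same allocation share.
#' Because one share scales all six analytes, relative (energy-adjusted)
#' measures are unchanged by allocation.
#'
#' @param household Named nutrient vector (see [nutrient_vector()]) or a
#'   data frame carrying the six nutrient columns.
#' @param share Allocation share in (0, 1].
#' @return Same shape as `household`, scaled.
#' @export
individualize <- function(household, share) {
  if (any(is.na(share)) || any(share <= 0) || any(share > 1)) {
    stop_domain("share must lie in (0, 1]")
  }
  if (is.data.frame(household)) {
    check_nutrient_frame(household, where = "household estimate")
    household[nutrient_cols()] <- household[nutrient_cols()] * share
    return(household)
  }
  validate_nutrient_vector(household, "household estimate")
  household * share
}

# Internal vectorised share computation for a participants table with a
# household_members table (columns participant_id, age).
participant_shares <- function(participants, members,
                               table = default_energy_table()) {
  self_kcal <- recommended_energy(participants$age, participants$gender, table)
  if (nrow(members) > 0) {
    other <- tibble(participant_id = members$participant_id,
                    kcal = recommended_energy(members$age, "unknown", table)) %>%
      dplyr::group_by(.data$participant_id) %>%
      dplyr::summarise(other_kcal = sum(.data$kcal), .groups = "drop")
  } else {
    other <- tibble(participant_id = character(0), other_kcal = numeric(0))
  }
  participants %>%
    dplyr::mutate(self_kcal = self_kcal) %>%
    dplyr::left_join(other, by = "participant_id") %>%
    dplyr::mutate(
      other_kcal = dplyr::coalesce(.data$other_kcal, 0),
      share = .data$self_kcal / (.data$self_kcal + .data$other_kcal)
    ) %>%
    dplyr::select("participant_id", "share")
}
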