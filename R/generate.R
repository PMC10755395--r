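#' Default recruitment-wave scheme
#'
#' Five waves (a pilot plus four seasonal waves) spanning a year. Each wave
#' has a 1-year study period preceded by a 1-year baseline period of
#' transactions; the primary comparison period (matching the FFQ recall
#' window) starts at the study-period start.
#'
#' @return Tibble with `wave`, `study_start`, `comparison_start`.
#' @export
default_wave_scheme <- function() {
  tibble(
    wave = c("pilot", "wave1", "wave2", "wave3", "wave4"),
    study_start = as.Date(c("2020-06-01", "2020-09-01", "2020-12-01",
                            "2021-03-01", "2021-06-01")),
    comparison_start = as.Date(c("2020-06-01", "2020-09-01", "2020-12-01",
                                 "2021-03-01", "2021-06-01"))
  )
}

#' Configuration for the synthetic study generator
#'
#' Defines the stated world the generator emulates: cohort size 686 (the
#' analysis sample), ~28 % of catalogue products without back-of-pack
#' profiles before imputation, household sizes 1-5 averaging 2.2 persons,
#' five self-reported loyalty bands (82 % above 40 %, 64 % above 60 %), a
#' ~91-day primary comparison period inside a study year plus a baseline
#' year, ~10 % food waste and ~10 % intake under-reporting, and a
#' heteroskedastic log-scale purchase:intake ratio structure
#' ln(P) - ln(I) = b0 + b1 m + N(0, sigma) imposed on the individual-level
#' allocated purchase estimate (m is the mean of the two log values).
#'
#' Default (b0, b1, sigma) reproduce the printed individual-level energy
#' agreement: ratio 0.86 at A = 2000 kcal with LoA 22-343 %, i.e.
#' sigma = ln(3.43/0.86)/1.96 and b0 = ln(0.86) - b1 ln(2000) with slope
#' b1 = 0.6 (under-estimation at low magnitudes, several-fold
#' over-estimation at high).
#'
#' @param seed Integer RNG seed. One fixed stream per output family
#'   (catalogue, cohort, observations), so changing `n_participants` does
#'   not perturb the catalogue.
#' @param n_participants Cohort size.
#' @param wave_scheme Tibble with `wave`, `study_start`, `comparison_start`.
#' @param comparison_days Days in the primary comparison period.
#' @param catalogue_size Number of products (>= 15; includes 6 staple
#'   products used for exact basket construction).
#' @param missing_profile_rate Fraction of products with absent per-100
#'   profiles before imputation.
#' @param household_size_distribution Named probabilities over sizes 1-5.
#' @param loyalty_band_distribution Named probabilities over the 5 bands.
#' @param ratio_intercept,ratio_slope,ratio_noise_sd The (b0, b1, sigma)
#'   of the imposed log-scale ratio structure.
#' @param waste_fraction Fraction of purchases wasted (ground-truth
#'   bookkeeping; see the methods vignette).
#' @param underreport_fraction FFQ under-reporting: FFQ = true x (1 - u).
#' @param log_energy_mean,log_energy_sd Distribution of the mean-of-logs
#'   magnitude for daily energy (defaults: ln(2000), 0.30).
#' @param ratio_noise_cor Correlation of the ratio noise across the six
#'   analytes within a participant (shared + idiosyncratic decomposition).
#'   The default 0.93 makes the relative (energy-adjusted) log-ratio
#'   spread sigma * sqrt(2 (1 - cor)) match the printed relative-sugar
#'   limits of agreement (0.59-1.67, i.e. ln(1.67)/1.96 = 0.26).
#' @param trips_per_week Mean shopping-trip rate (Poisson).
#' @param lines_per_trip Mean basket lines per trip.
#' @param energy_table Recommendation table used for allocation shares.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 686L,
                             wave_scheme = default_wave_scheme(),
                             comparison_days = 91L,
                             catalogue_size = 150L,
                             missing_profile_rate = 0.28,
                             household_size_distribution =
                               c("1" = 0.30, "2" = 0.40, "3" = 0.15,
                                 "4" = 0.10, "5" = 0.05),
                             loyalty_band_distribution =
                               stats::setNames(c(0.08, 0.10, 0.18, 0.28, 0.36),
                                               loyalty_bands()),
                             ratio_intercept = log(0.86) - 0.6 * log(2000),
                             ratio_slope = 0.6,
                             ratio_noise_sd = log(3.43 / 0.86) / 1.96,
                             waste_fraction = 0.10,
                             underreport_fraction = 0.10,
                             log_energy_mean = log(2000),
                             log_energy_sd = 0.30,
                             ratio_noise_cor = 0.93,
                             trips_per_week = 1.2,
                             lines_per_trip = 6,
                             energy_table = default_energy_table()) {
  cfg <- list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    wave_scheme = as_tibble(wave_scheme),
    comparison_days = as.integer(comparison_days),
    catalogue_size = as.integer(catalogue_size),
    missing_profile_rate = missing_profile_rate,
    household_size_distribution = household_size_distribution,
    loyalty_band_distribution = loyalty_band_distribution,
    ratio_intercept = ratio_intercept, ratio_slope = ratio_slope,
    ratio_noise_sd = ratio_noise_sd,
    waste_fraction = waste_fraction,
    underreport_fraction = underreport_fraction,
    log_energy_mean = log_energy_mean, log_energy_sd = log_energy_sd,
    ratio_noise_cor = ratio_noise_cor,
    trips_per_week = trips_per_week, lines_per_trip = lines_per_trip,
    energy_table = validate_energy_table(energy_table)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop_config(paste0("invalid generator config field '", field, "': ", why))
  }
  chk(!is.na(cfg$seed), "seed", "must be an integer")
  chk(cfg$n_participants >= 1, "n_participants", "must be >= 1")
  chk(nrow(cfg$wave_scheme) >= 1, "wave_scheme", "must have at least one wave")
  chk(all(c("wave", "study_start", "comparison_start") %in% names(cfg$wave_scheme)),
      "wave_scheme", "needs columns wave, study_start, comparison_start")
  chk(cfg$comparison_days >= 1, "comparison_days", "must be >= 1")
  chk(cfg$catalogue_size >= 15, "catalogue_size",
      "must be >= 15 (one product per category)")
  chk(cfg$missing_profile_rate >= 0 && cfg$missing_profile_rate <= 1,
      "missing_profile_rate", "must be in [0, 1]")
  chk(round(cfg$missing_profile_rate * cfg$catalogue_size) <=
        cfg$catalogue_size - 6,
      "missing_profile_rate",
      "the 6 staple products must keep retailer profiles")
  hs <- cfg$household_size_distribution
  chk(length(hs) == 5 && all(hs >= 0) && abs(sum(hs) - 1) < 1e-9,
      "household_size_distribution", "5 probabilities summing to 1")
  lb <- cfg$loyalty_band_distribution
  chk(length(lb) == 5 && all(lb >= 0) && abs(sum(lb) - 1) < 1e-9,
      "loyalty_band_distribution", "5 probabilities summing to 1")
  chk(cfg$ratio_noise_sd >= 0, "ratio_noise_sd", "must be >= 0")
  chk(cfg$waste_fraction >= 0 && cfg$waste_fraction < 1,
      "waste_fraction", "must be in [0, 1)")
  chk(cfg$underreport_fraction >= 0 && cfg$underreport_fraction < 1,
      "underreport_fraction", "must be in [0, 1)")
  chk(cfg$ratio_noise_cor >= 0 && cfg$ratio_noise_cor <= 1,
      "ratio_noise_cor", "must be in [0, 1]")
  chk(cfg$trips_per_week > 0, "trips_per_week", "must be > 0")
  chk(cfg$lines_per_trip >= 1, "lines_per_trip", "must be >= 1")
  structure(cfg, class = "generator_config")
}

#' Read a generator configuration from a JSON file
#'
#' Any subset of [generator_config()] fields may be given; the rest take
#' their defaults. `wave_scheme` is an array of objects with `wave`,
#' `study_start`, `comparison_start` (ISO-8601 dates).
#'
#' @param path Path to a JSON file.
#' @return A validated `generator_config`.
#' @export
generator_config_from_file <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$wave_scheme)) {
    raw$wave_scheme <- as_tibble(raw$wave_scheme)
    raw$wave_scheme$study_start <- as.Date(raw$wave_scheme$study_start)
    raw$wave_scheme$comparison_start <- as.Date(raw$wave_scheme$comparison_start)
  }
  if (!is.null(raw$household_size_distribution)) {
    raw$household_size_distribution <- unlist(raw$household_size_distribution)
  }
  if (!is.null(raw$loyalty_band_distribution)) {
    raw$loyalty_band_distribution <- unlist(raw$loyalty_band_distribution)
  }
  if (!is.null(raw$energy_table)) raw$energy_table <- as_tibble(raw$energy_table)
  do.call(generator_config, raw)
}

# Independent RNG stream per output family.
family_seed <- function(cfg, k) set.seed(cfg$seed * 7L + k * 1000003L)

# The six staple products that let in-period baskets be decomposed exactly
# onto any non-negative nutrient target (macro-pure foods plus an
# energy-only spirit, echoing label-free alcohol).
staple_products <- function() {
  tibble(
    product_id = sprintf("P%05d", 1:6),
    description = c("granulated sugar", "protein powder", "vegetable oil",
                    "coconut oil", "table salt", "vodka"),
    category = 1:6,
    pack_amount = c(1000, 500, 1000, 500, 750, 700),
    pack_unit = c("g", "g", "ml", "g", "g", "ml"),
    unit_net_weight_g = NA_real_,
    price = c(1.10, 12.00, 2.20, 3.50, 0.65, 16.00),
    staple = TRUE,
    per100_energy_kcal = c(390, 400, 900, 900, 0, 231),
    per100_sugars_g = c(100, 0, 0, 0, 0, 0),
    per100_protein_g = c(0, 100, 0, 0, 0, 0),
    per100_fat_g = c(0, 0, 100, 100, 0, 0),
    per100_satfat_g = c(0, 0, 0, 100, 0, 0),
    per100_sodium_mg = c(0, 0, 0, 0, 39000, 0)
  )
}

# Random per-100 profiles: energy first, then macro energy shares summing
# to <= 0.95 so residual energy (non-sugar carbohydrate etc.) is positive
# -- every real label satisfies energy >= 3.9 sugars + 4 protein + 9 fat.
random_profiles <- function(n) {
  energy <- pmin(pmax(stats::rlnorm(n, log(180), 0.7), 15), 900)
  g <- matrix(stats::rgamma(3 * n, shape = 1.2), ncol = 3)
  share <- g / rowSums(g) * stats::runif(n, 0.45, 0.95)
  fat <- energy * share[, 3] / 9
  tibble(
    per100_energy_kcal = energy,
    per100_sugars_g = energy * share[, 1] / 3.9,
    per100_protein_g = energy * share[, 2] / 4,
    per100_fat_g = fat,
    per100_satfat_g = fat * stats::runif(n, 0.05, 0.9),
    per100_sodium_mg = energy * stats::runif(n, 0.1, 2.5)
  )
}

#' Generate the product catalogue and generic food-composition table
#'
#' Products carry back-of-pack per-100 g/ml profiles except for exactly
#' `round(missing_profile_rate * catalogue_size)` of them (their profiles
#' are absent, to be imputed from the generic table). Every one of the 15
#' food categories has a generic entry. Six staple products always keep
#' retailer profiles. For products with absent profiles the category
#' generic is, by construction, the product's true composition (the
#' synthetic world has no imputation error; see the vignette).
#'
#' @param config A [generator_config()].
#' @return List with `catalogue` and `generics` tibbles.
#' @export
generate_catalogue <- function(config) {
  config <- validate_generator_config(config)
  family_seed(config, 1L)
  n <- config$catalogue_size
  staples <- staple_products()
  n_other <- n - 6L
  others <- tibble(
    product_id = sprintf("P%05d", 7:n),
    description = sprintf("product %d", 7:n),
    category = rep_len(1:15, n_other),
    pack_unit = sample(c("g", "ml", "each"), n_other, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    pack_amount = sample(c(100, 200, 250, 330, 400, 500, 750, 1000),
                         n_other, replace = TRUE),
    unit_net_weight_g = sample(c(50, 80, 100, 150, 200, 300, 400),
                               n_other, replace = TRUE),
    price = round(stats::runif(n_other, 0.5, 8), 2),
    staple = FALSE
  )
  others$unit_net_weight_g[others$pack_unit != "each"] <- NA_real_
  others <- dplyr::bind_cols(others, random_profiles(n_other))
  n_missing <- round(config$missing_profile_rate * n)
  if (n_missing > 0) {
    drop <- sample(others$product_id, n_missing)
    others[others$product_id %in% drop,
           paste0("per100_", nutrient_cols())] <- NA_real_
  }
  catalogue <- dplyr::bind_rows(staples, others)
  generics <- dplyr::bind_cols(tibble(category = 1:15), random_profiles(15))
  list(catalogue = catalogue, generics = generics)
}

# Truncated-normal helper (simple clamp; the tails carry no meaning here).
rnorm_clamp <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Generate the participant cohort and its ground truth
#'
#' Draws demographics (ages around 56 +/- 13, 72 % female), household
#' compositions (other members have unknown gender: the first is an adult
#' partner, further members are children), loyalty bands, wave
#' assignments, and the latent agreement structure: the energy mean-of-logs
#' m is drawn first, then per analyte the log difference
#' d = b0 + b1 m + noise, giving the individual-level purchase target
#' exp(m_k + d_k/2) and FFQ intake exp(m_k - d_k/2) where m_k positions
#' each analyte at its composition-implied magnitude. Noise is correlated
#' across analytes within a participant (a household's retailer-sourcing
#' behaviour drives all analytes together). True intake is
#' FFQ / (1 - underreport).
#'
#' @param config A [generator_config()].
#' @return List with `participants`, `members` and `truth` (ground-truth
#'   object: generating parameters plus per-participant targets; consumed
#'   only by tests, never by pipeline stages).
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  if (nrow(config$wave_scheme) == 0) stop_config("wave_scheme is empty")
  family_seed(config, 2L)
  n <- config$n_participants
  ids <- sprintf("ID%05d", seq_len(n))
  age <- pmin(pmax(round(stats::rnorm(n, 56, 13)), 18), 90)
  gender <- ifelse(stats::runif(n) < 0.72, "female", "male")
  hsize <- as.integer(sample(names(config$household_size_distribution), n,
                             replace = TRUE,
                             prob = config$household_size_distribution))
  band <- sample(names(config$loyalty_band_distribution), n, replace = TRUE,
                 prob = config$loyalty_band_distribution)
  band_idx <- match(band, loyalty_bands())
  true_share <- stats::runif(n, pmax((band_idx - 1) * 0.2, 0.001), band_idx * 0.2)
  wv <- config$wave_scheme[sample.int(nrow(config$wave_scheme), n, replace = TRUE), ]

  participants <- tibble(
    participant_id = ids, age = age, gender = gender,
    household_size = hsize, loyalty_band = band, wave = wv$wave,
    study_start = as.Date(wv$study_start),
    baseline_start = as.Date(wv$study_start) - 365L,
    period_start = as.Date(wv$comparison_start),
    period_days = config$comparison_days
  )

  # household members: first a partner (adult), then children
  n_other <- pmax(hsize - 1L, 0L)
  pid_rep <- rep(ids, n_other)
  idx <- sequence(n_other)
  partner_age <- pmin(pmax(rep(age, n_other) + round(stats::rnorm(length(pid_rep), 0, 4)),
                           18), 90)
  child_age <- sample(0:17, length(pid_rep), replace = TRUE)
  members <- tibble(
    participant_id = pid_rep, member_index = idx,
    age = ifelse(idx == 1, partner_age, child_age),
    gender = "unknown"
  )

  # latent agreement structure, per analyte
  b0 <- config$ratio_intercept; b1 <- config$ratio_slope
  sigma <- config$ratio_noise_sd; rho <- config$ratio_noise_cor
  m_E <- stats::rnorm(n, config$log_energy_mean, config$log_energy_sd)
  c_S <- rnorm_clamp(n, 19, 3, 5, 40)
  c_P <- rnorm_clamp(n, 14, 2, 8, 25)
  c_F <- rnorm_clamp(n, 36, 5, 15, 55)
  tot <- c_S + c_P + c_F
  scl <- ifelse(tot > 90, 90 / tot, 1)
  c_S <- c_S * scl; c_P <- c_P * scl; c_F <- c_F * scl
  c_SF <- c_F * rnorm_clamp(n, 0.39, 0.06, 0.1, 0.8)
  na_dens <- rnorm_clamp(n, 1.06, 0.25, 0.3, 2.5)

  m <- cbind(
    energy_kcal = m_E,
    sugars_g = m_E + log(c_S / 100 / 3.9),
    protein_g = m_E + log(c_P / 100 / 4),
    fat_g = m_E + log(c_F / 100 / 9),
    satfat_g = m_E + log(c_SF / 100 / 9),
    sodium_mg = m_E + log(na_dens)
  )
  eps0 <- stats::rnorm(n)
  eps <- sigma * (rho * eps0 +
                    sqrt(1 - rho^2) * matrix(stats::rnorm(6 * n), ncol = 6))
  # the purchase:intake ratio is a household-level sourcing behaviour: one
  # magnitude regressor (the energy mean-of-logs) drives all six analytes,
  # with correlated per-analyte noise
  d <- b0 + b1 * m_E + eps
  P <- exp(m + d / 2)   # individual-level daily purchase target
  I <- exp(m - d / 2)   # FFQ daily intake
  n_clamped <- sum(P[, "satfat_g"] > P[, "fat_g"]) + sum(I[, "satfat_g"] > I[, "fat_g"])
  P[, "satfat_g"] <- pmin(P[, "satfat_g"], P[, "fat_g"])
  I[, "satfat_g"] <- pmin(I[, "satfat_g"], I[, "fat_g"])
  # label realizability: any basket of real products has
  # energy >= 3.9 sugars + 4 protein + 9 fat; rescale macro grams of the
  # rare draws where analyte noise pushes past 97% of energy
  guard <- function(X) {
    macroE <- 3.9 * X[, "sugars_g"] + 4 * X[, "protein_g"] + 9 * X[, "fat_g"]
    f <- pmin(0.97 * X[, "energy_kcal"] / macroE, 1)
    X[, c("sugars_g", "protein_g", "fat_g", "satfat_g")] <-
      X[, c("sugars_g", "protein_g", "fat_g", "satfat_g")] * f
    list(X = X, n = sum(f < 1))
  }
  gP <- guard(P); gI <- guard(I)
  P <- gP$X; I <- gI$X
  n_rescaled <- gP$n + gI$n

  shares <- participant_shares(participants, members, config$energy_table)
  share <- shares$share[match(ids, shares$participant_id)]
  H <- P / share  # household-level daily target

  truth_tbl <- dplyr::bind_cols(
    tibble(participant_id = ids, retailer_share = true_share,
           allocation_share = share),
    stats::setNames(as_tibble(I), paste0("ffq_", nutrient_cols())),
    stats::setNames(as_tibble(I / (1 - config$underreport_fraction)),
                    paste0("true_", nutrient_cols())),
    stats::setNames(as_tibble(P), paste0("target_ind_", nutrient_cols())),
    stats::setNames(as_tibble(H), paste0("target_hh_", nutrient_cols()))
  )
  truth <- list(
    params = list(b0 = b0, b1 = b1, sigma = sigma,
                  waste_fraction = config$waste_fraction,
                  underreport_fraction = config$underreport_fraction,
                  satfat_clamped = n_clamped,
                  macro_rescaled = n_rescaled),
    participants = truth_tbl
  )
  list(participants = participants, members = members, truth = truth)
}

#' Generate transaction lines and FFQ records
#'
#' Shopping trips arrive as a Poisson stream across the participant's
#' baseline and study years with random baskets drawn from the catalogue.
#' Lines inside the primary comparison period are then rescaled and
#' completed with staple-product lines so that the household's in-period
#' totals equal the ground-truth household target exactly: running the
#' estimation and allocation stages downstream reproduces the imposed
#' ratio structure to machine precision. FFQ records are emitted directly
#' as daily nutrient vectors.
#'
#' @param config A [generator_config()].
#' @param cohort Output of [generate_cohort()].
#' @param cat Output of [generate_catalogue()].
#' @return List with `transactions` and `ffq` tibbles.
#' @export
generate_observations <- function(config, cohort, cat) {
  config <- validate_generator_config(config)
  if (nrow(cat$catalogue) == 0) stop_data("catalogue is empty")
  family_seed(config, 3L)
  pp <- cohort$participants
  n <- nrow(pp)
  truth <- cohort$truth$participants

  ffq <- dplyr::select(truth, "participant_id",
                       dplyr::all_of(paste0("ffq_", nutrient_cols())))

  # random trips across baseline + study years
  n_trips <- stats::rpois(n, config$trips_per_week * 730 / 7)
  pid <- rep(pp$participant_id, n_trips)
  t_start <- rep(pp$baseline_start, n_trips)
  offs <- floor(stats::runif(length(pid)) * 730)
  trips <- tibble(
    customer_id = pid,
    transaction_id = paste0(pid, "-T", sequence(n_trips)),
    date = t_start + offs
  )
  n_lines <- 1L + stats::rpois(nrow(trips), max(config$lines_per_trip - 1, 0))
  lines <- trips[rep(seq_len(nrow(trips)), n_lines), ]
  kat <- cat$catalogue
  li <- sample.int(nrow(kat), nrow(lines), replace = TRUE)
  grams <- stats::rlnorm(nrow(lines), log(400), 0.7)
  gpu <- unit_grams(kat)
  lines$product_id <- kat$product_id[li]
  lines$quantity <- grams / gpu[li]
  lines$price <- kat$price[li]

  # resolve with the same code path the pipeline uses (label-consistent)
  res <- resolve_lines(
    dplyr::select(lines, "customer_id", "transaction_id", "date",
                  "product_id", "quantity"),
    kat, cat$generics)
  per <- tibble(customer_id = pp$participant_id,
                p_start = pp$period_start,
                p_end = pp$period_start + (pp$period_days - 1L))
  res <- dplyr::left_join(res, per, by = "customer_id")
  res$in_period <- res$date >= res$p_start & res$date <= res$p_end

  # per-household in-period raw totals R and target T
  nutm <- as.matrix(res[nutrient_cols()])
  gfun <- function(x) {
    x[, "energy_kcal"] - 3.9 * x[, "sugars_g"] - 4 * x[, "protein_g"] -
      9 * x[, "fat_g"]
  }
  Rm <- rowsum(nutm[res$in_period, , drop = FALSE],
               group = res$customer_id[res$in_period])
  Tm <- as.matrix(truth[paste0("target_hh_", nutrient_cols())]) * pp$period_days[
    match(truth$participant_id, pp$participant_id)]
  colnames(Tm) <- nutrient_cols()
  rownames(Tm) <- truth$participant_id

  Rfull <- matrix(0, nrow(Tm), 6, dimnames = dimnames(Tm))
  Rfull[rownames(Rm), ] <- Rm
  gT <- gfun(Tm); gR <- gfun(Rfull)
  ratio_mat <- cbind(
    ifelse(Rfull > 0, Tm / Rfull, Inf),
    ifelse(gR > 0, gT / gR, Inf),
    oil = ifelse(Rfull[, "fat_g"] - Rfull[, "satfat_g"] > 0,
                 (Tm[, "fat_g"] - Tm[, "satfat_g"]) /
                   (Rfull[, "fat_g"] - Rfull[, "satfat_g"]), Inf)
  )
  alpha <- 0.9 * apply(ratio_mat, 1, min)
  alpha[!is.finite(alpha)] <- 0

  a_line <- alpha[match(res$customer_id, rownames(Tm))]
  res$quantity <- ifelse(res$in_period, res$quantity * a_line, res$quantity)
  # alpha = 0 (e.g. a degenerate target component) zeroes a household's
  # in-period lines: drop them, the staple decomposition covers the target
  keep <- !(res$in_period & res$quantity <= 0)
  Rfull <- Rfull * alpha
  res <- res[keep, , drop = FALSE]
  line_price <- lines$price[keep]

  # residual target decomposed exactly onto the six staples
  resid <- pmax(Tm - Rfull, 0)
  g_coco <- resid[, "satfat_g"]
  g_oil <- pmax(resid[, "fat_g"] - resid[, "satfat_g"], 0)
  g_sugar <- resid[, "sugars_g"]
  g_protein <- resid[, "protein_g"]
  g_salt <- resid[, "sodium_mg"] / 390
  e_left <- pmax(resid[, "energy_kcal"] - 3.9 * g_sugar - 4 * g_protein -
                   9 * resid[, "fat_g"], 0)
  g_spirit <- e_left / 2.31
  st <- staple_products()
  gram_mat <- cbind(g_sugar, g_protein, g_oil, g_coco, g_salt, g_spirit)
  qty_mat <- sweep(gram_mat, 2, st$pack_amount, "/")
  basis <- tibble(
    customer_id = rep(rownames(Tm), 6),
    transaction_id = paste0(rep(rownames(Tm), 6), "-TB"),
    date = rep(pp$period_start[match(rownames(Tm), pp$participant_id)] +
                 pp$period_days[match(rownames(Tm), pp$participant_id)] %/% 2, 6),
    product_id = rep(st$product_id, each = nrow(Tm)),
    quantity = as.vector(qty_mat),
    price = rep(st$price, each = nrow(Tm))
  )
  basis <- basis[basis$quantity > 0, , drop = FALSE]

  transactions <- dplyr::bind_rows(
    dplyr::select(res, "customer_id", "transaction_id", "date",
                  "product_id", "quantity") %>%
      dplyr::mutate(price = line_price),
    basis
  ) %>%
    dplyr::mutate(cost = round(.data$quantity * .data$price, 2)) %>%
    dplyr::select("customer_id", "transaction_id", "date", "product_id",
                  "quantity", "cost") %>%
    dplyr::arrange(.data$customer_id, .data$date, .data$transaction_id,
                   .data$product_id)
  list(transactions = transactions, ffq = ffq)
}

#' Generate a complete synthetic study
#'
#' Runs [generate_catalogue()], [generate_cohort()] and
#' [generate_observations()] under one configuration.
#'
#' @param config A [generator_config()].
#' @return List with `catalogue`, `generics`, `participants`, `members`,
#'   `transactions`, `ffq`, `truth`.
#' @examples
#' sim <- simulate_study(generator_config(seed = 7, n_participants = 20,
#'                                        catalogue_size = 30))
#' names(sim)
#' @export
simulate_study <- function(config = generator_config()) {
  cat <- generate_catalogue(config)
  cohort <- generate_cohort(config)
  obs <- generate_observations(config, cohort, cat)
  list(catalogue = cat$catalogue, generics = cat$generics,
       participants = cohort$participants, members = cohort$members,
       transactions = obs$transactions, ffq = obs$ffq,
       truth = cohort$truth)
}

#' Write a synthetic study to CSV files (plus ground truth JSON)
#'
#' Writes `catalogue.csv`, `generic_table.csv`, `participants.csv`,
#' `household_members.csv`, `transactions.csv`, `ffq.csv` and
#' `ground_truth.json` into `dir`.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$catalogue, file.path(dir, "catalogue.csv"))
  readr::write_csv(sim$generics, file.path(dir, "generic_table.csv"))
  readr::write_csv(sim$participants, file.path(dir, "participants.csv"))
  readr::write_csv(sim$members, file.path(dir, "household_members.csv"))
  readr::write_csv(sim$transactions, file.path(dir, "transactions.csv"))
  readr::write_csv(sim$ffq, file.path(dir, "ffq.csv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic study back from CSV files
#'
#' @param dir Directory written by [write_study_csvs()].
#' @return List like [simulate_study()] (without `truth` unless present).
#' @export
read_study_csvs <- function(dir) {
  rd <- function(f, ...) readr::read_csv(file.path(dir, f),
                                         show_col_types = FALSE, ...)
  out <- list(
    catalogue = rd("catalogue.csv"),
    generics = rd("generic_table.csv"),
    participants = rd("participants.csv"),
    members = rd("household_members.csv"),
    transactions = rd("transactions.csv"),
    ffq = rd("ffq.csv")
  )
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
    truth$participants <- as_tibble(truth$participants)
    out$truth <- truth
  }
  out
}
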