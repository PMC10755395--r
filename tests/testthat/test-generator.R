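small_cfg <- function(n_participants = 25, ...) {
  generator_config(seed = 9, n_participants = n_participants,
                   catalogue_size = 30, ...)
}

test_that("catalogue carries the configured missingness exactly and valid profiles", {
  cat100 <- generate_catalogue(generator_config(seed = 1, catalogue_size = 100,
                                                missing_profile_rate = 0.28))
  prof <- !is.na(cat100$catalogue$per100_energy_kcal)
  expect_equal(sum(prof), 72)
  expect_equal(sum(!prof), 28)
  # no missingness case
  cat0 <- generate_catalogue(generator_config(seed = 1, catalogue_size = 100,
                                              missing_profile_rate = 0))
  expect_true(all(!is.na(cat0$catalogue$per100_energy_kcal)))
  # generic table covers all 15 categories once
  expect_equal(sort(cat0$generics$category), 1:15)
  # profiles are valid labels: non-negative, satfat <= fat, macro energy bound
  kk <- cat0$catalogue
  expect_true(all(kk$per100_satfat_g <= kk$per100_fat_g + 1e-9))
  expect_true(all(kk$per100_energy_kcal + 1e-9 >=
                    3.9 * kk$per100_sugars_g + 4 * kk$per100_protein_g +
                    9 * kk$per100_fat_g))
  expect_error(generate_catalogue(generator_config(catalogue_size = 10)),
               class = "basketdiet_error_config")
  expect_error(generator_config(missing_profile_rate = 1.5),
               class = "basketdiet_error_config")
})

test_that("generation is deterministic and the catalogue ignores cohort size", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1, s2)
  # catalogue stream is independent of n_participants
  c_small <- generate_catalogue(small_cfg())
  c_big <- generate_catalogue(small_cfg(n_participants = 200))
  expect_identical(c_small, c_big)
})

test_that("cohort structure follows the configured distributions", {
  # everyone lives alone under a degenerate size distribution
  solo <- generate_cohort(small_cfg(
    household_size_distribution = c("1" = 1, "2" = 0, "3" = 0, "4" = 0, "5" = 0)))
  expect_true(all(solo$participants$household_size == 1))
  expect_equal(nrow(solo$members), 0)
  # default cohort size matches the analysis-sample size emulated
  full <- generate_cohort(generator_config(seed = 4))
  expect_equal(nrow(full$participants), 686)
  expect_true(all(full$participants$age >= 18))
  expect_true(all(full$members$gender == "unknown"))
  # member counts match household sizes
  mc <- table(full$members$participant_id)
  hs <- full$participants$household_size
  names(hs) <- full$participants$participant_id
  expect_true(all(hs[names(mc)] - 1 == as.integer(mc)))
  expect_true(all(hs[setdiff(names(hs), names(mc))] == 1))
  # loyalty frequencies converge to the configured distribution
  big <- generate_cohort(generator_config(seed = 8, n_participants = 10000))
  tab <- table(factor(big$participants$loyalty_band, levels = loyalty_bands()))
  gof <- stats::chisq.test(tab, p = unname(
    generator_config()$loyalty_band_distribution))
  expect_gt(gof$p.value, 0.001)
  expect_error(generate_cohort(small_cfg(wave_scheme = default_wave_scheme()[0, ])),
               class = "basketdiet_error_config")
})

test_that("transactions span the baseline and study years and reference the catalogue", {
  sim <- cached("sim_small", simulate_study(small_cfg()))
  tx <- dplyr::left_join(sim$transactions, sim$participants,
                         by = c(customer_id = "participant_id"))
  expect_true(all(tx$date >= tx$baseline_start))
  expect_true(all(tx$date <= tx$study_start + 364))
  expect_true(all(tx$product_id %in% sim$catalogue$product_id))
  expect_true(all(tx$quantity > 0))
  # every participant has at least one purchase inside their window
  inper <- tx$date >= tx$period_start & tx$date <= tx$period_start + tx$period_days - 1
  expect_setequal(unique(tx$customer_id[inper]), sim$participants$participant_id)
})

test_that("FFQ records equal true intake scaled by under-reporting", {
  sim <- cached("sim_small", simulate_study(small_cfg()))
  tr <- sim$truth$participants
  u <- sim$truth$params$underreport_fraction
  expect_equal(tr$ffq_energy_kcal, tr$true_energy_kcal * (1 - u), tolerance = 1e-12)
  ffq <- dplyr::left_join(sim$ffq, tr, by = "participant_id")
  expect_equal(ffq$ffq_energy_kcal.x, ffq$ffq_energy_kcal.y)
  # positive intakes with satfat <= fat throughout
  expect_true(all(ffq$ffq_satfat_g.x <= ffq$ffq_fat_g.x))
})

test_that("in-period purchases invert allocation to the ground-truth targets exactly", {
  sim <- cached("sim_small", simulate_study(small_cfg()))
  built <- build_analysis_set(sim$participants, sim$members, sim$transactions,
                              sim$ffq, sim$catalogue, sim$generics)
  aset <- built$analysis_set
  tr <- sim$truth$participants
  j <- match(aset$participant_id, tr$participant_id)
  expect_equal(aset$share, tr$allocation_share[j], tolerance = 1e-12)
  for (nut in nutrient_cols()) {
    expect_equal(aset[[paste0("ind_", nut)]],
                 tr[[paste0("target_ind_", nut)]][j], tolerance = 1e-9)
    expect_equal(aset[[paste0("hh_", nut)]],
                 tr[[paste0("target_hh_", nut)]][j], tolerance = 1e-9)
  }
})

test_that("study CSVs and config round-trip through disk", {
  sim <- cached("sim_small", simulate_study(small_cfg()))
  dir <- withr::local_tempdir()
  write_study_csvs(sim, dir)
  expect_setequal(list.files(dir),
                  c("catalogue.csv", "generic_table.csv", "participants.csv",
                    "household_members.csv", "transactions.csv", "ffq.csv",
                    "ground_truth.json"))
  back <- read_study_csvs(dir)
  expect_equal(nrow(back$transactions), nrow(sim$transactions))
  expect_equal(back$truth$params$b0, sim$truth$params$b0)
  # JSON config round-trip
  cfgfile <- file.path(dir, "config.json")
  jsonlite::write_json(list(seed = 9, n_participants = 25, catalogue_size = 30),
                       cfgfile, auto_unbox = TRUE)
  cfg2 <- generator_config_from_file(cfgfile)
  expect_identical(simulate_study(cfg2)$transactions, sim$transactions)
})
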