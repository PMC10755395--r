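test_that("classic Bland-Altman matches the hand-computed oracle", {
  ba <- classic_ba(c(110, 190, 310), c(100, 200, 300))
  # d = (10, -10, 10): mean 10/3, sd sqrt(400/3)
  expect_equal(ba$mean_diff, 10 / 3)
  expect_equal(ba$sd_diff, sqrt(400 / 3))
  expect_equal(ba$loa_lo, 10 / 3 - 1.96 * sqrt(400 / 3))
  expect_equal(ba$loa_hi, 10 / 3 + 1.96 * sqrt(400 / 3))
  expect_equal(round(c(ba$loa_lo, ba$loa_hi), 2), c(-19.30, 25.97))
  # perfect agreement
  ba0 <- classic_ba(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$mean_diff, ba0$loa_lo, ba0$loa_hi), c(0, 0, 0))
  # translation equivariance
  ba_c <- classic_ba(c(110, 190, 310) + 7.5, c(100, 200, 300))
  expect_equal(ba_c$mean_diff, ba$mean_diff + 7.5)
  expect_equal(ba_c$loa_lo, ba$loa_lo + 7.5)
  expect_equal(ba_c$loa_hi, ba$loa_hi + 7.5)
  expect_error(classic_ba(1, 1), class = "basketdiet_error_insufficient_data")
})

# closed-form normal-equation oracle, independent of lm()
ols_oracle <- function(m, d) {
  mbar <- sum(m) / length(m); dbar <- sum(d) / length(d)
  sxx <- sum((m - mbar)^2); sxy <- sum((m - mbar) * (d - dbar))
  b1 <- sxy / sxx; b0 <- dbar - b1 * mbar
  r <- d - b0 - b1 * m
  list(b0 = b0, b1 = b1, s = sqrt(sum(r^2) / (length(d) - 2)))
}

pairs_from_md <- function(m, d) list(p = exp(m + d / 2), i = exp(m - d / 2))

test_that("log-scale regression equals the closed-form OLS solution", {
  # exact-fit case: d = 0.1 m - 0.8
  m <- 6:10
  pr <- pairs_from_md(m, 0.1 * m - 0.8)
  fit <- log_ba_regression(pr$p, pr$i)
  expect_equal(fit$beta1, 0.1, tolerance = 1e-10)
  expect_equal(fit$beta0, -0.8, tolerance = 1e-10)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-10)
  # 5-point oracle with residual SE on the n-2 denominator
  d2 <- c(0, -0.1, 0, 0.1, 0)
  pr2 <- pairs_from_md(m, d2)
  fit2 <- log_ba_regression(pr2$p, pr2$i)
  expect_equal(fit2$beta1, 0.02, tolerance = 1e-10)
  expect_equal(fit2$beta0, -0.16, tolerance = 1e-10)
  expect_equal(fit2$resid_sd, sqrt(0.016 / 3), tolerance = 1e-10)
  # random fixed dataset vs the normal equations
  set.seed(11)
  m3 <- rnorm(37, 7, 0.8); d3 <- 0.4 - 0.05 * m3 + rnorm(37, 0, 0.25)
  pr3 <- pairs_from_md(m3, d3)
  fit3 <- log_ba_regression(pr3$p, pr3$i)
  orc <- ols_oracle(m3, d3)
  expect_equal(fit3$beta0, orc$b0, tolerance = 1e-10)
  expect_equal(fit3$beta1, orc$b1, tolerance = 1e-10)
  expect_equal(fit3$resid_sd, orc$s, tolerance = 1e-10)
})

test_that("nonpositive pairs are excluded and counted; degenerate designs error", {
  p <- c(100, 200, 300, -5, 0, 150)
  i <- c(90, 210, 310, 100, 100, -1)
  fit <- log_ba_regression(p, i)
  expect_equal(fit$n, 3)
  expect_equal(fit$excluded_nonpositive, 3)
  expect_error(log_ba_regression(c(2, 2, 2), c(2, 2, 2)),
               class = "basketdiet_error_singular")
  expect_error(log_ba_regression(c(1, 2), c(1, 2)),
               class = "basketdiet_error_insufficient_data")
})

test_that("predict_ratio back-transforms the regression recipe", {
  # identity fit
  pr0 <- predict_ratio(list(beta0 = 0, beta1 = 0, resid_sd = 0), 1234)
  expect_equal(c(pr0$ratio, pr0$loa_lo_ratio, pr0$loa_hi_ratio), c(1, 1, 1))
  # ln(2000) rounds to 7.6, the constant quoted in the reporting recipe
  expect_equal(round(log(2000), 1), 7.6)
  # hand oracle
  fit <- list(beta0 = 2, beta1 = -0.25, resid_sd = 0.3)
  pr <- predict_ratio(fit, 2000)
  dhat <- 2 - 0.25 * log(2000)
  expect_equal(pr$ratio, exp(dhat))
  expect_equal(pr$loa_lo_ratio, exp(dhat - 1.96 * 0.3))
  expect_equal(pr$loa_hi_ratio, exp(dhat + 1.96 * 0.3))
  expect_equal(round(c(pr$ratio, pr$loa_lo_ratio, pr$loa_hi_ratio), 3),
               c(1.105, 0.614, 1.989))
  expect_error(predict_ratio(fit, 0), class = "basketdiet_error_domain")
  # ratio-unity point
  expect_equal(a_star(list(beta0 = 0.5, beta1 = -0.152)), exp(0.5 / 0.152))
  expect_equal(round(a_star(list(beta0 = 0.5, beta1 = -0.152)), 1), 26.8)
  expect_true(is.na(a_star(list(beta0 = 0.5, beta1 = 0))))
})

test_that("swap antisymmetry and units invariance of the log analysis", {
  set.seed(21)
  m <- rnorm(200, 7.5, 0.5); d <- 0.3 - 0.08 * m + rnorm(200, 0, 0.2)
  pr <- pairs_from_md(m, d)
  fit <- log_ba_regression(pr$p, pr$i)
  swap <- log_ba_regression(pr$i, pr$p)
  expect_equal(swap$beta0, -fit$beta0, tolerance = 1e-10)
  expect_equal(swap$beta1, -fit$beta1, tolerance = 1e-10)
  expect_equal(swap$resid_sd, fit$resid_sd, tolerance = 1e-10)
  A <- 1800
  expect_equal(predict_ratio(swap, A)$ratio, 1 / predict_ratio(fit, A)$ratio,
               tolerance = 1e-10)
  # common rescaling: slope and residual SD unchanged, intercept shifts by
  # -beta1 * ln(c) as implied by the model
  cc <- 4.2
  fit_c <- log_ba_regression(cc * pr$p, cc * pr$i)
  expect_equal(fit_c$beta1, fit$beta1, tolerance = 1e-10)
  expect_equal(fit_c$resid_sd, fit$resid_sd, tolerance = 1e-10)
  expect_equal(fit_c$beta0, fit$beta0 - fit$beta1 * log(cc), tolerance = 1e-10)
})

test_that("pearson correlation matches an independent sum-formula oracle", {
  i <- c(1, 2, 3, 5, 8, 13)
  expect_equal(pearson_r(2 * i, i), 1.0)
  expect_equal(pearson_r(-i + 10, i), -1.0)
  p <- c(2.2, 1.9, 3.4, 4.8, 7.7, 14.2)
  n <- length(i)
  orc <- (sum(p * i) - n * mean(p) * mean(i)) /
    sqrt((sum(p^2) - n * mean(p)^2) * (sum(i^2) - n * mean(i)^2))
  expect_equal(pearson_r(p, i), orc, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "basketdiet_error_domain")
})

test_that("parameter recovery from simulated heteroskedastic pairs", {
  set.seed(77)
  n <- 5000; b0 <- 0.6; b1 <- -0.12; sg <- 0.3
  m <- rnorm(n, 7.6, 0.4)
  d <- b0 + b1 * m + rnorm(n, 0, sg)
  pr <- pairs_from_md(m, d)
  fit <- log_ba_regression(pr$p, pr$i)
  se_b1 <- fit$resid_sd / sqrt(sum((m - mean(m))^2))
  se_b0 <- fit$resid_sd * sqrt(1 / n + mean(m)^2 / sum((m - mean(m))^2))
  expect_lt(abs(fit$beta0 - b0), 3 * se_b0)
  expect_lt(abs(fit$beta1 - b1), 3 * se_b1)
  expect_lt(abs(fit$resid_sd - sg) / sg, 0.05)
})

test_that("agreement_by_measure produces one fit per measure and handles groups", {
  set.seed(5)
  n <- 60
  mk <- function() exp(rnorm(n, 7, 0.4))
  df <- tibble::tibble(participant_id = as.character(1:n))
  for (nut in nutrient_cols()) {
    df[[paste0("ffq_", nut)]] <- mk()
    df[[paste0("hh_", nut)]] <- mk()
    df[[paste0("ind_", nut)]] <- df[[paste0("hh_", nut)]] * 0.5
  }
  for (rl in relative_cols()) {
    df[[paste0("ffq_", rl)]] <- exp(rnorm(n, 2, 0.3))
    df[[paste0("pur_", rl)]] <- exp(rnorm(n, 2, 0.3))
  }
  tab <- agreement_by_measure(df, "none")
  expect_equal(nrow(tab), 17)
  expect_setequal(unique(tab$level), c("household", "individual", "relative"))
  # energy rows are reported at the requested A
  expect_equal(tab$A[tab$measure == "energy_kcal"], c(2000, 2000))
  # non-energy rows sit at their ratio-unity point: fitted ratio is 1 there
  non_e <- tab[tab$measure != "energy_kcal" & !is.na(tab$a_star), ]
  expect_equal(non_e$ratio, rep(1, nrow(non_e)), tolerance = 1e-8)
  # grouping: small groups are skipped with a warning
  df$household_size_group <- c("1", rep("2", n - 2), "3+")
  warns <- testthat::capture_warnings(
    tab_g <- agreement_by_measure(df, "household_size", measures = "energy_kcal")
  )
  expect_true(length(warns) == 4 && all(grepl("skipping", warns)))
  expect_true(all(tab_g$group == "2"))
})
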