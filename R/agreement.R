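#' Classic Bland-Altman agreement
#'
#' Mean difference (bias), sample SD of the differences and limits of
#' agreement at bias +/- 1.96 SD. Differences are always purchase minus
#' intake (`p - i`).
#'
#' @param p,i Numeric vectors of paired measurements: purchase estimate and
#'   intake estimate per participant.
#' @return Object of class `classic_ba`: list with `mean_diff`, `sd_diff`,
#'   `loa_lo`, `loa_hi`, `n`.
#' @examples
#' classic_ba(c(110, 190, 310), c(100, 200, 300))
#' @export
classic_ba <- function(p, i) {
  ok <- stats::complete.cases(p, i)
  p <- p[ok]; i <- i[ok]
  if (length(p) != length(i)) stop_data("p and i must have equal length")
  if (length(p) < 2) stop_insufficient("classic_ba needs at least 2 pairs")
  d <- p - i
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_lo = m - 1.96 * s, loa_hi = m + 1.96 * s, n = length(d)),
    class = "classic_ba"
  )
}

#' @export
print.classic_ba <- function(x, ...) {
  cat("Bland-Altman agreement (difference scale), n =", x$n, "\n")
  cat(sprintf("  bias %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              x$mean_diff, x$sd_diff, x$loa_lo, x$loa_hi))
  invisible(x)
}

#' Regression approach to Bland-Altman limits of agreement on the log scale
#'
#' When the difference between methods depends on the magnitude of their
#' mean (heteroskedasticity), both measurements are log-transformed and the
#' difference d = ln P - ln I is regressed on the mean of logs
#' m = (ln P + ln I)/2 by ordinary least squares. The bias at magnitude m
#' is beta0 + beta1 m and the limits of agreement run parallel at
#' +/- 1.96 times the residual standard error (n - 2 denominator).
#' Pairs with a non-positive value on either side are excluded and counted.
#'
#' @inheritParams classic_ba
#' @return Object of class `agreement_fit`: list with `beta0`, `beta1`,
#'   `resid_sd`, `n`, `excluded_nonpositive`.
#' @examples
#' set.seed(1)
#' m <- rnorm(200, 7.6, 0.3)
#' d <- 0.5 - 0.1 * m + rnorm(200, 0, 0.2)
#' fit <- log_ba_regression(exp(m + d / 2), exp(m - d / 2))
#' predict_ratio(fit, 2000)
#' @export
log_ba_regression <- function(p, i) {
  if (length(p) != length(i)) stop_data("p and i must have equal length")
  ok <- stats::complete.cases(p, i) & p > 0 & i > 0
  excluded <- sum(!ok)
  p <- p[ok]; i <- i[ok]
  if (length(p) < 3) {
    stop_insufficient("log_ba_regression needs at least 3 pairs with P > 0 and I > 0")
  }
  d <- log(p) - log(i)
  m <- (log(p) + log(i)) / 2
  if (stats::var(m) < .Machine$double.eps) {
    abort("all mean-of-log values identical: regression design is singular",
          class = "basketdiet_error_singular")
  }
  fit <- stats::lm(d ~ m)
  s <- summary(fit)$sigma
  structure(
    list(beta0 = unname(stats::coef(fit)[1]),
         beta1 = unname(stats::coef(fit)[2]),
         resid_sd = s, n = length(d), excluded_nonpositive = excluded),
    class = "agreement_fit"
  )
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat("Log-scale Bland-Altman regression fit, n =", x$n,
      sprintf("(%d non-positive pair(s) excluded)\n", x$excluded_nonpositive))
  cat(sprintf("  ln(P) - ln(I) = %.4g + %.4g * m,  residual SD %.4g\n",
              x$beta0, x$beta1, x$resid_sd))
  if (!is.na(x$beta1) && x$beta1 != 0) {
    cat(sprintf("  ratio = 1 at A* = %.4g\n", a_star(x)))
  }
  invisible(x)
}

#' Predicted purchase:intake ratio and LoA at a chosen magnitude
#'
#' Following the reporting recipe for the regression approach: the natural
#' log of the magnitude A is multiplied by the slope and added to the
#' intercept, giving the log of the difference, which is back-transformed
#' to the ratio of purchase to intake; the limits of agreement are the
#' ratio times exp(-/+ 1.96 residual SD). (A is plugged in for the mean of
#' logs, the regression's x-axis, exactly as reported.)
#'
#' @param fit An `agreement_fit` from [log_ba_regression()], or any list
#'   with `beta0`, `beta1`, `resid_sd`.
#' @param A Magnitude at which to report, in the measure's units (> 0).
#' @return Object of class `ratio_prediction`: list with `A`, `ratio`,
#'   `loa_lo_ratio`, `loa_hi_ratio`.
#' @examples
#' fit <- list(beta0 = 2, beta1 = -0.25, resid_sd = 0.3)
#' predict_ratio(fit, 2000)  # ratio 1.105, LoA (0.614, 1.990)
#' @export
predict_ratio <- function(fit, A) {
  if (any(is.na(A)) || any(A <= 0)) stop_domain("A must be > 0")
  dhat <- fit$beta0 + fit$beta1 * log(A)
  structure(
    list(A = A, ratio = exp(dhat),
         loa_lo_ratio = exp(dhat - 1.96 * fit$resid_sd),
         loa_hi_ratio = exp(dhat + 1.96 * fit$resid_sd)),
    class = "ratio_prediction"
  )
}

#' @export
print.ratio_prediction <- function(x, ...) {
  cat(sprintf("At A = %.4g: purchase/intake ratio %.4g, LoA [%.4g, %.4g]\n",
              x$A, x$ratio, x$loa_lo_ratio, x$loa_hi_ratio))
  invisible(x)
}

#' Magnitude at which the fitted ratio equals one
#'
#' A* = exp(-beta0/beta1); undefined (NA) when the slope is zero.
#'
#' @param fit An `agreement_fit`.
#' @return Scalar, or NA if `beta1 == 0`.
#' @export
a_star <- function(fit) {
  if (is.na(fit$beta1) || fit$beta1 == 0) return(NA_real_)
  exp(-fit$beta0 / fit$beta1)
}

#' Pearson product-moment correlation for paired measurements
#'
#' @inheritParams classic_ba
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(p, i) {
  ok <- stats::complete.cases(p, i)
  p <- p[ok]; i <- i[ok]
  if (length(p) < 3) stop_insufficient("pearson_r needs at least 3 pairs")
  if (stats::var(p) == 0 || stats::var(i) == 0) {
    stop_domain("pearson_r is undefined when either measure has zero variance")
  }
  stats::cor(p, i)
}

# The 17 default measures: 6 absolute analytes at household and individual
# level (purchase vs FFQ intake) and 5 relative measures (purchase relative
# profile vs intake relative profile).
measure_table <- function() {
  abs_m <- tibble(
    measure = rep(nutrient_cols(), 2),
    level = rep(c("household", "individual"), each = 6),
    p_col = c(paste0("hh_", nutrient_cols()), paste0("ind_", nutrient_cols())),
    i_col = rep(paste0("ffq_", nutrient_cols()), 2)
  )
  rel_m <- tibble(
    measure = relative_cols(),
    level = "relative",
    p_col = paste0("pur_", relative_cols()),
    i_col = paste0("ffq_", relative_cols())
  )
  dplyr::bind_rows(abs_m, rel_m)
}

#' Agreement fits across measures and subgroups
#'
#' Runs the log-scale Bland-Altman regression for each requested measure
#' (all 17 by default: six absolute analytes at household and individual
#' level, and five relative energy-adjusted measures), optionally within
#' subgroups, and reports the back-transformed purchase:intake ratio and
#' limits of agreement at a chosen magnitude plus the ratio-unity point A*.
#'
#' Energy measures are reported at `at_kcal`; every other measure is
#' reported at its own A* (where the fitted ratio is 1, so the LoA columns
#' show pure spread), falling back to the geometric-mean magnitude of the
#' data when the slope is zero.
#'
#' @param data Analysis-set tibble carrying `hh_*`, `ind_*`, `ffq_*`
#'   nutrient columns and `pur_*`/`ffq_*` relative columns (as produced by
#'   [build_analysis_set()]).
#' @param grouping `"none"`, `"household_size"` or `"loyalty"`; subgroup
#'   columns must be present (see [assign_subgroups()]).
#' @param at_kcal Magnitude A for the energy measures (default 2000 kcal).
#' @param measures Optional subset of measure names to fit.
#' @return Tibble with one row per (measure, level, group): `n`,
#'   `excluded_nonpositive`, `beta0`, `beta1`, `resid_sd`, `A`, `ratio`,
#'   `loa_lo_ratio`, `loa_hi_ratio`, `a_star`. Groups with fewer than 3
#'   valid pairs are skipped with a warning.
#' @export
agreement_by_measure <- function(data, grouping = c("none", "household_size", "loyalty"),
                                 at_kcal = 2000, measures = NULL) {
  grouping <- match.arg(grouping)
  if (nrow(data) == 0) stop_data("analysis set is empty")
  spec <- measure_table()
  if (!is.null(measures)) spec <- spec[spec$measure %in% measures, ]
  gcol <- switch(grouping, none = NULL,
                 household_size = "household_size_group", loyalty = "loyalty_group")
  if (!is.null(gcol) && !gcol %in% names(data)) {
    stop_data(paste0("grouping column '", gcol, "' not found; run assign_subgroups()"))
  }
  groups <- if (is.null(gcol)) list(pooled = data) else split(data, data[[gcol]])

  rows <- purrr::imap(groups, function(gdat, gname) {
    purrr::pmap(spec, function(measure, level, p_col, i_col) {
      p <- gdat[[p_col]]; i <- gdat[[i_col]]
      n_valid <- sum(stats::complete.cases(p, i) & p > 0 & i > 0)
      if (n_valid < 3) {
        warn(sprintf("skipping %s/%s in group '%s': %d valid pair(s)",
                     level, measure, gname, n_valid))
        return(NULL)
      }
      fit <- log_ba_regression(p, i)
      astar <- a_star(fit)
      A <- if (measure == "energy_kcal") {
        at_kcal
      } else if (!is.na(astar) && astar > 0) {
        astar
      } else {
        ok <- stats::complete.cases(p, i) & p > 0 & i > 0
        exp(mean((log(p[ok]) + log(i[ok])) / 2))
      }
      pr <- predict_ratio(fit, A)
      tibble(
        measure = measure, level = level, group = gname,
        n = fit$n, excluded_nonpositive = fit$excluded_nonpositive,
        beta0 = fit$beta0, beta1 = fit$beta1, resid_sd = fit$resid_sd,
        A = pr$A, ratio = pr$ratio,
        loa_lo_ratio = pr$loa_lo_ratio, loa_hi_ratio = pr$loa_hi_ratio,
        a_star = astar
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
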