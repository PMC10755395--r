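#' Bland-Altman plot for a pair of measures
#'
#' Four variants: `"scatter"` (purchase vs intake), `"classic"` (mean vs
#' difference with bias and LoA lines), `"log"` (mean of logs vs log
#' difference) and `"ratio"` (the regression approach: mean of logs on a
#' back-transformed axis vs purchase:intake ratio, with fitted bias line
#' and parallel LoA at +/- 1.96 residual SD).
#'
#' Requires ggplot2 (in Suggests).
#'
#' @param p,i Paired purchase and intake values.
#' @param type Plot variant.
#' @param xlab,ylab Optional axis labels.
#' @return A ggplot object.
#' @export
ba_plot <- function(p, i, type = c("ratio", "scatter", "classic", "log"),
                    xlab = NULL, ylab = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("ba_plot requires the ggplot2 package")
  }
  type <- match.arg(type)
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  if (type == "scatter") {
    df <- tibble(p = p, i = i)
    return(gg(df, aes(x = i, y = p)) + ggplot2::geom_point(alpha = 0.5) +
             ggplot2::geom_abline(slope = 1, intercept = 0) +
             ggplot2::labs(x = xlab %||% "intake estimate",
                           y = ylab %||% "purchase estimate") +
             ggplot2::theme_minimal())
  }
  if (type == "classic") {
    ba <- classic_ba(p, i)
    df <- tibble(m = (p + i) / 2, d = p - i)
    return(gg(df, aes(x = m, y = d)) + ggplot2::geom_point(alpha = 0.5) +
             ggplot2::geom_hline(yintercept = 0) +
             ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
             ggplot2::geom_hline(yintercept = c(ba$loa_lo, ba$loa_hi),
                                 linetype = "dashed") +
             ggplot2::labs(x = xlab %||% "mean of measures",
                           y = ylab %||% "difference (purchase - intake)") +
             ggplot2::theme_minimal())
  }
  ok <- p > 0 & i > 0
  df <- tibble(m = (log(p[ok]) + log(i[ok])) / 2,
               d = log(p[ok]) - log(i[ok]))
  fit <- log_ba_regression(p, i)
  df$fitted <- fit$beta0 + fit$beta1 * df$m
  if (type == "log") {
    return(gg(df, aes(x = m, y = d)) + ggplot2::geom_point(alpha = 0.5) +
             ggplot2::geom_hline(yintercept = 0) +
             ggplot2::geom_line(aes(y = fitted), colour = "blue") +
             ggplot2::geom_line(aes(y = fitted + 1.96 * fit$resid_sd),
                                linetype = "dashed") +
             ggplot2::geom_line(aes(y = fitted - 1.96 * fit$resid_sd),
                                linetype = "dashed") +
             ggplot2::labs(x = xlab %||% "mean of log measures",
                           y = ylab %||% "log difference") +
             ggplot2::theme_minimal())
  }
  # ratio: back-transformed axes
  gg(df, aes(x = exp(m), y = exp(d))) + ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1) +
    ggplot2::geom_line(aes(y = exp(fitted)), colour = "blue") +
    ggplot2::geom_line(aes(y = exp(fitted + 1.96 * fit$resid_sd)),
                       linetype = "dashed") +
    ggplot2::geom_line(aes(y = exp(fitted - 1.96 * fit$resid_sd)),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab %||% "mean of measures",
                  y = ylab %||% "ratio purchase/intake") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
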