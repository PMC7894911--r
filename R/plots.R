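# ggplot2 helpers for the diagnostic objects. These render the numeric data
# the analysis functions emit; all styling is deliberately minimal.

#' TTT plot
#'
#' Scaled total-time-on-test transform against \eqn{r/n} with the diagonal
#' for reference; concavity diagnoses an increasing hazard.
#'
#' @param x positive lifetimes.
#' @return a ggplot object.
#' @export
plot_ttt <- function(x) {
  d <- ttt_transform(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p, y = .data$ttt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "r/n", y = "scaled TTT")
}

#' PP plot of one or more fitted models
#'
#' @param x positive lifetimes.
#' @param cdfs a named list of fitted cdf functions (parameters fixed).
#' @return a ggplot object, faceted by model when several are given.
#' @export
plot_pp <- function(x, cdfs) {
  if (is.function(cdfs)) cdfs <- list(model = cdfs)
  d <- purrr::imap_dfr(cdfs, function(f, nm) {
    dplyr::mutate(pp_points(x, f), model = nm)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$empirical, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "empirical probability", y = "fitted probability")
}

#' @export
autoplot.olihl_comparison <- function(object, ...) {
  d <- dplyr::filter(object, !purrr::map_lgl(.data$pp, is.null))
  d <- tidyr::unnest(dplyr::select(d, "model", "pp"), "pp")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$empirical, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "empirical probability", y = "fitted probability")
}

#' Residual diagnostics plot for a LOLiHL regression
#'
#' Index plot of the modified deviance residuals and their normal QQ plot.
#'
#' @param object a fitted [lolihl_reg()] model.
#' @param ... unused.
#' @return a ggplot object (two panels via faceting).
#' @export
autoplot.lolihl_reg <- function(object, ...) {
  r <- residuals(object, type = "both")
  qq <- stats::qqnorm(r$deviance, plot.it = FALSE)
  d <- dplyr::bind_rows(
    tibble::tibble(panel = "index plot", x = r$index, y = r$deviance),
    tibble::tibble(panel = "normal QQ", x = qq$x, y = qq$y)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "modified deviance residual")
}
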