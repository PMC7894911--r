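# Monte-Carlo comparison of the four shape-parameter estimators: bias and
# mean squared error as functions of the sample size,
#   Bias(n) = (1/N) sum(lambda_hat_i - lambda)
#   MSE(n)  = (1/N) sum(lambda_hat_i - lambda)^2.
# Each replicate draws one sample which all methods see (paired design);
# the per-replicate seed stream is seed + replicate offset, so results are
# reproducible and methods are compared on identical data.

#' Monte-Carlo bias/MSE study of the OLiHL estimators
#'
#' For each sample size in `n_grid`, draws `n_reps` OLiHL samples at
#' `lambda_true` and applies every requested estimator to each sample,
#' aggregating empirical bias and MSE. Estimator failures on individual
#' replicates are counted and excluded from that method's averages.
#'
#' @param lambda_true true shape parameter (the reference design uses 0.1).
#' @param n_grid strictly increasing sample sizes (reference: 20, 25, ..., 100).
#' @param n_reps Monte-Carlo replications per sample size (reference: 1000).
#' @param methods subset of `c("mle", "lse", "wlse", "cvme")`; the
#'   degenerate reference estimator `"oracle"` (returns `lambda_true`,
#'   giving zero bias and MSE by construction) is accepted for validating
#'   the aggregation.
#' @param seed base seed; replicate r at the g-th grid size uses
#'   `seed + 10000 * g + r`.
#' @return a tibble of class `olihl_sim_study` with columns `method`, `n`,
#'   `bias`, `mse`, `n_failures`, plus attributes recording the design.
#' @examples
#' res <- olihl_sim_study(0.1, n_grid = c(20, 50), n_reps = 25, seed = 1)
#' autoplot(res)
#' @export
olihl_sim_study <- function(lambda_true = 0.1,
                            n_grid = seq(20, 100, by = 5),
                            n_reps = 1000,
                            methods = c("mle", "lse", "wlse", "cvme"),
                            seed = 1) {
  check_lambda(lambda_true)
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("`n_grid` must be strictly increasing", call. = FALSE)
  }
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  methods <- match.arg(methods, c("mle", "lse", "wlse", "cvme", "oracle"),
                       several.ok = TRUE)

  out <- purrr::map_dfr(seq_along(n_grid), function(g) {
    n <- n_grid[g]
    est <- matrix(NA_real_, nrow = n_reps, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(n_reps)) {
      set.seed(seed + 10000L * g + r)
      x <- rolihl(n, lambda_true)
      for (m in methods) {
        est[r, m] <- if (m == "oracle") lambda_true else
          tryCatch(fit_olihl(x, method = m)$lambda,
                   error = function(e) NA_real_)
      }
    }
    purrr::map_dfr(methods, function(m) {
      e <- est[, m]
      ok <- is.finite(e)
      tibble::tibble(
        method = m, n = n,
        bias = mean(e[ok] - lambda_true),
        mse = mean((e[ok] - lambda_true)^2),
        n_failures = sum(!ok)
      )
    })
  })
  attr(out, "lambda_true") <- lambda_true
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- c("olihl_sim_study", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.olihl_sim_study <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("bias", "mse"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "sample size n", y = NULL, colour = "estimator")
}
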