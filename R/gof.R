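# Goodness-of-fit machinery: Kolmogorov-Smirnov test, Anderson-Darling and
# Cramer-von Mises EDF statistics, the scaled total-time-on-test transform,
# PP-plot point pairs, and the multi-model comparison table.

#' Kolmogorov–Smirnov test of a fitted cdf
#'
#' One-sample KS statistic
#' \eqn{D_n = \max_i \max(i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n)} with
#' p-value from the asymptotic Kolmogorov distribution of \eqn{\sqrt{n} D_n}
#' (via [stats::ks.test()] with `exact = FALSE`; the ties warning is
#' suppressed since lifetime data are routinely recorded with ties).
#'
#' @param x positive lifetimes.
#' @param cdf a vectorized cdf function of one argument (parameters already
#'   fixed at their estimates).
#' @return a tibble with columns `statistic`, `p.value`.
#' @examples
#' x <- rolihl(100, 0.5)
#' lam <- fit_olihl(x)$lambda
#' ks_stat(x, function(q) polihl(q, lam))
#' @export
ks_stat <- function(x, cdf) {
  check_sample(x)
  u <- cdf(sort(x))
  if (anyNA(u) || any(!is.finite(u))) {
    stop("fitted cdf returned non-finite values", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, cdf, exact = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 p.value = unname(res$p.value))
}

#' Anderson–Darling and Cramér–von Mises EDF statistics
#'
#' Computes \eqn{A^2} and \eqn{W^2} from the probability-integral transforms
#' \eqn{u_i = F(x_{(i)})}. With `modified = TRUE` (default) the
#' small-sample modification factors standard in distribution-fitting work
#' are applied:
#' \deqn{W^* = W^2 (1 + 0.5/n), \qquad A^* = A^2 (1 + 0.75/n + 2.25/n^2).}
#' Transforms are clipped into \eqn{(10^{-12}, 1-10^{-12})}; values pinned
#' at 0 or 1 even after clipping are an error.
#'
#' @inheritParams ks_stat
#' @param modified apply the small-sample modification factors?
#' @return a tibble with columns `A_star`, `W_star` (or `A_sq`, `W_sq` when
#'   `modified = FALSE`).
#' @examples
#' x <- rolihl(100, 0.5)
#' lam <- fit_olihl(x)$lambda
#' edf_stats(x, function(q) polihl(q, lam))
#' @export
edf_stats <- function(x, cdf, modified = TRUE) {
  check_sample(x)
  n <- length(x)
  u <- sort(cdf(sort(x)))
  if (anyNA(u)) stop("fitted cdf returned NA", call. = FALSE)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  if (any(u <= 0 | u >= 1)) {
    stop("probability-integral transforms collapse to 0/1", call. = FALSE)
  }
  i <- seq_len(n)
  W2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  if (modified) {
    tibble::tibble(A_star = A2 * (1 + 0.75 / n + 2.25 / n^2),
                   W_star = W2 * (1 + 0.5 / n))
  } else {
    tibble::tibble(A_sq = A2, W_sq = W2)
  }
}

#' Scaled total-time-on-test (TTT) transform
#'
#' \eqn{G(r/n) = [\sum_{i \le r} x_{(i)} + (n-r) x_{(r)}] / \sum_i x_{(i)}}
#' for \eqn{r = 1, \dots, n}. A concave TTT curve diagnoses an increasing
#' hazard rate; a curve on the diagonal a constant one.
#'
#' @param x positive lifetimes, \eqn{n \ge 2}.
#' @return a tibble with columns `r`, `p` (= r/n) and `ttt`.
#' @examples
#' ttt_transform(c(1, 2, 3))
#' @export
ttt_transform <- function(x) {
  check_sample(x)
  n <- length(x)
  if (n < 2) stop("the TTT transform needs at least two observations", call. = FALSE)
  xs <- sort(x)
  total <- sum(xs)
  if (total <= 0) stop("sample total must be positive", call. = FALSE)
  r <- seq_len(n)
  g <- (cumsum(xs) + (n - r) * xs) / total
  tibble::tibble(r = r, p = r / n, ttt = g)
}

#' Probability–probability (PP) plot coordinates
#'
#' Pairs the empirical plotting positions \eqn{(i - 0.5)/n} with the fitted
#' probabilities \eqn{F(x_{(i)})}.
#'
#' @inheritParams ks_stat
#' @return a tibble with columns `empirical`, `fitted`.
#' @export
pp_points <- function(x, cdf) {
  check_sample(x)
  n <- length(x)
  tibble::tibble(empirical = (seq_len(n) - 0.5) / n,
                 fitted = cdf(sort(x)))
}

#' Compare lifetime models on a sample
#'
#' Fits each requested model from [olihl_competitors()] by maximum
#' likelihood and assembles the goodness-of-fit panel: estimate, standard
#' error, \eqn{-\ell}, AIC, modified Anderson–Darling \eqn{A^*} and
#' Cramér–von Mises \eqn{W^*}, the Kolmogorov–Smirnov statistic and its
#' asymptotic p-value. The table is ranked by \eqn{-\ell} (the headline
#' criterion; with one parameter per model the AIC ordering coincides).
#' Individual model failures are recorded as `NA` rows, not fatal.
#'
#' @param x positive lifetimes.
#' @param models model names; defaults to all seven.
#' @return a tibble of class `olihl_comparison`, one row per model, ranked
#'   by `neg_loglik`, with a `pp` list-column of PP-plot coordinates.
#' @examples
#' x <- rolihl(200, 0.5)
#' compare_lifetime_models(x, c("olihl", "li", "exp"))
#' @export
compare_lifetime_models <- function(x, models = names(olihl_competitors())) {
  check_sample(x)
  reg <- olihl_competitors(models)
  if (length(models) == 1L) reg <- stats::setNames(list(reg), tolower(models))
  rows <- purrr::map_dfr(reg, function(m) {
    res <- tryCatch({
      fit <- fit_competitor(x, m)
      cdf <- function(q) m$cdf(q, fit$lambda)
      ks_res <- ks_stat(x, cdf)
      edf <- edf_stats(x, cdf)
      tibble::tibble(
        model = m$name, lambda = fit$lambda, se = fit$se,
        neg_loglik = -fit$loglik, aic = 2 - 2 * fit$loglik,
        A_star = edf$A_star, W_star = edf$W_star,
        ks = ks_res$statistic, ks_pvalue = ks_res$p.value,
        boundary = isTRUE(fit$boundary), converged = fit$converged,
        pp = list(pp_points(x, cdf)), error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(model = m$name, lambda = NA_real_, se = NA_real_,
                     neg_loglik = NA_real_, aic = NA_real_,
                     A_star = NA_real_, W_star = NA_real_,
                     ks = NA_real_, ks_pvalue = NA_real_,
                     boundary = NA, converged = FALSE,
                     pp = list(NULL), error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::arrange(rows, dplyr::desc(is.na(.data$neg_loglik) == FALSE),
                        .data$neg_loglik)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  class(out) <- c("olihl_comparison", class(out))
  out
}
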