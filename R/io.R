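# Data ingestion and synthetic fixture generation. CSV with header is the
# sole ingestion dialect (comma by default).

#' Read a univariate lifetime sample from a delimited text file
#'
#' @param path path to a delimited file with header.
#' @param column column holding the lifetimes; defaults to the only column
#'   (an error if the file has several).
#' @param sep field separator.
#' @return a numeric vector of validated positive lifetimes.
#' @export
read_lifetime_sample <- function(path, column = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (is.null(column)) {
    if (ncol(df) != 1L) {
      stop("file has ", ncol(df), " columns; name one via `column`", call. = FALSE)
    }
    column <- names(df)[1]
  }
  if (!column %in% names(df)) {
    stop("column '", column, "' not found in ", path, call. = FALSE)
  }
  x <- df[[column]]
  check_sample(x)
  x
}

#' Read a censored survival-regression dataset from a delimited text file
#'
#' Returns a tibble with the response `y` (log-lifetime when `log_time` is
#' `TRUE`), the event indicator `event` (1 = observed event, 0 = censored;
#' an absent event column means no censoring) and the covariates. The file's
#' event column may use the alive/death coding of clinical data (0 = alive =
#' censored, 1 = death = event), which is already the internal convention.
#'
#' @param path path to a delimited file with header.
#' @param time_col name of the lifetime column.
#' @param event_col name of the 0/1 event column, or `NULL`.
#' @param covariate_cols names of numeric covariate columns.
#' @param log_time take logs of the lifetimes? Non-positive lifetimes are an
#'   error naming the offending rows.
#' @param sep field separator.
#' @return a tibble with columns `y`, `event`, then the covariates.
#' @export
read_survival_data <- function(path, time_col = "time", event_col = NULL,
                               covariate_cols = character(), log_time = FALSE,
                               sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  needed <- c(time_col, event_col, covariate_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  time <- df[[time_col]]
  if (anyNA(time) || any(!is.finite(time))) {
    stop("non-finite lifetimes in column '", time_col, "'", call. = FALSE)
  }
  if (log_time) {
    bad <- which(time <= 0)
    if (length(bad)) {
      stop("log-time requested but non-positive lifetimes in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    y <- log(time)
  } else {
    y <- time
  }
  event <- if (is.null(event_col)) rep(1, length(y)) else df[[event_col]]
  if (!all(event %in% c(0, 1))) {
    stop("event column '", event_col, "' must contain only 0/1", call. = FALSE)
  }
  out <- tibble::tibble(y = y, event = as.numeric(event))
  for (cv in covariate_cols) out[[cv]] <- df[[cv]]
  out
}

#' Generate a synthetic OLiHL lifetime sample
#'
#' Inversion sampling with an explicit seed, optionally written to CSV with
#' a JSON manifest of the generator settings alongside.
#'
#' @param n sample size.
#' @param lambda shape parameter.
#' @param seed integer seed.
#' @param file optional CSV path; a `<file>.manifest.json` is written next
#'   to it.
#' @return the numeric sample, invisibly when written to file.
#' @export
generate_olihl_sample <- function(n, lambda, seed = 1, file = NULL) {
  set.seed(seed)
  x <- rolihl(n, lambda)
  if (!is.null(file)) {
    utils::write.csv(data.frame(lifetime = x), file, row.names = FALSE)
    jsonlite::write_json(
      list(kind = "sample", n = n, lambda = lambda, seed = seed),
      paste0(file, ".manifest.json"), auto_unbox = TRUE)
    return(invisible(x))
  }
  x
}

#' Generate a synthetic censored LOLiHL regression dataset
#'
#' Emulates a clinical survival design: a binary exposure
#' `x1 ~ Bernoulli(0.5)` (e.g. drug-use history) and a continuous covariate
#' `x2 ~ Uniform(20, 60)` (e.g. age), log-lifetimes from the LOLiHL law at
#' \eqn{\mu_i = x_i^\top \beta}, and right-censoring times drawn from a
#' location-shifted LOLiHL whose offset is tuned by root search so the
#' expected censored share matches `censor_fraction`. The recorded response
#' is \eqn{y_i = \min} of the two with the event indicator.
#'
#' @param n number of individuals.
#' @param lambda LOLiHL shape.
#' @param beta regression coefficients: intercept then one per covariate
#'   (length 2 uses `x1` only; length 3 uses `x1` and `x2`).
#' @param sigma LOLiHL scale.
#' @param censor_fraction target expected fraction of censored rows in
#'   \eqn{[0, 1)}; 0 disables censoring.
#' @param seed integer seed.
#' @param file optional CSV path (with JSON manifest).
#' @return a tibble with columns `y` (log-lifetime, censored), `event`,
#'   and the covariates; attribute `censor_offset` records the tuned shift.
#' @examples
#' d <- simulate_lolihl_data(200, 2, c(2, -0.5), 0.8, 0.2, seed = 1)
#' mean(d$event == 0)
#' @export
simulate_lolihl_data <- function(n, lambda, beta, sigma,
                                 censor_fraction = 0, seed = 1, file = NULL) {
  check_lambda(lambda)
  stopifnot(length(beta) %in% c(1, 2, 3), sigma > 0,
            censor_fraction >= 0, censor_fraction < 1)
  set.seed(seed)
  X <- cbind(intercept = rep(1, n))
  if (length(beta) >= 2) X <- cbind(X, x1 = stats::rbinom(n, 1, 0.5))
  if (length(beta) >= 3) X <- cbind(X, x2 = stats::runif(n, 20, 60))
  mu <- drop(X %*% beta)
  t_latent <- rlolihl(n, lambda, mu, sigma)
  if (censor_fraction > 0) {
    c_raw <- rlolihl(n, lambda, mu, sigma)
    share <- function(d) mean(c_raw + d < t_latent)
    # censored share decreases in the offset d; bracket then root-find
    lo <- -50; hi <- 50
    if (share(lo) < censor_fraction || share(hi) > censor_fraction) {
      warning("target censor_fraction ", censor_fraction,
              " unattainable; achieved ",
              round(min(max(share(lo), censor_fraction), share(hi)), 3))
      d <- if (share(lo) < censor_fraction) lo else hi
    } else {
      d <- stats::uniroot(function(d) share(d) - censor_fraction,
                          c(lo, hi), tol = 1e-6)$root
    }
    cens <- c_raw + d
    y <- pmin(t_latent, cens)
    event <- as.numeric(t_latent <= cens)
  } else {
    d <- Inf
    y <- t_latent
    event <- rep(1, n)
  }
  out <- tibble::tibble(y = y, event = event)
  if (ncol(X) >= 2) out$x1 <- X[, "x1"]
  if (ncol(X) >= 3) out$x2 <- X[, "x2"]
  attr(out, "censor_offset") <- d
  if (!is.null(file)) {
    utils::write.csv(as.data.frame(out), file, row.names = FALSE)
    jsonlite::write_json(
      list(kind = "regression", n = n, lambda = lambda, beta = beta,
           sigma = sigma, censor_fraction = censor_fraction, seed = seed,
           censor_offset = d),
      paste0(file, ".manifest.json"), auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}
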