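# The six one-parameter competitor lifetime models used in the
# goodness-of-fit comparison, each defined by its cdf with the pdf obtained
# by analytic differentiation. Shorthand used throughout:
#   G(x)  = (1 - e^-x)/(1 + e^-x)     half-logistic cdf
#   H(x)  = 2/(e^x + 1)               half-logistic survival function

.hl_cdf <- function(x) (1 - exp(-x)) / (1 + exp(-x))
.hl_sf <- function(x) 2 / (exp(x) + 1)
.hl_logpdf <- function(x) log(2) - x - 2 * log1p(exp(-x))

#' Registry of competitor lifetime models
#'
#' Returns the seven one-parameter models of the comparison suite: the
#' OLiHL distribution itself plus the exponentiated half-logistic (EHL),
#' generalized half-logistic (GHL), Lindley (Li), inverse Lindley (ILi),
#' transmuted half-logistic (THL, parameter domain \eqn{|\lambda| < 1}) and
#' exponential (Exp) distributions. Each entry carries the model's cdf,
#' log-pdf and parameter domain; the exponential additionally has the
#' closed-form MLE \eqn{\hat\lambda = 1/\bar x}.
#'
#' @param models character vector selecting a subset (case-insensitive).
#' @return a named list of model definitions, each a list with elements
#'   `name`, `cdf(x, lambda)`, `logpdf(x, lambda)`, `lower`, `upper` (the
#'   parameter domain) and optionally `closed_form(x)`.
#' @examples
#' names(olihl_competitors())
#' olihl_competitors("exp")$cdf(1, 0.5)
#' @export
olihl_competitors <- function(models = NULL) {
  reg <- list(
    olihl = list(
      name = "OLiHL", lower = 1e-6, upper = 1e3,
      cdf = function(x, l) polihl(x, l),
      logpdf = function(x, l) dolihl(x, l, log = TRUE),
      closed_form = function(x) olihl_mle_root(x)
    ),
    ehl = list(
      name = "EHL", lower = 1e-6, upper = 1e3,
      # F = G(x)^lambda; f = lambda G^(lambda-1) g
      cdf = function(x, l) .hl_cdf(x)^l,
      logpdf = function(x, l) log(l) + (l - 1) * log(.hl_cdf(x)) + .hl_logpdf(x)
    ),
    ghl = list(
      name = "GHL", lower = 1e-6, upper = 1e3,
      # F = 1 - H(x)^lambda; f = lambda H^lambda / (1 + e^-x)
      cdf = function(x, l) 1 - .hl_sf(x)^l,
      logpdf = function(x, l) log(l) + l * log(.hl_sf(x)) - log1p(exp(-x))
    ),
    li = list(
      name = "Li", lower = 1e-6, upper = 1e3,
      cdf = function(x, l) 1 - (1 + l * x / (1 + l)) * exp(-l * x),
      logpdf = function(x, l) 2 * log(l) - log(1 + l) + log1p(x) - l * x
    ),
    ili = list(
      name = "ILi", lower = 1e-6, upper = 1e3,
      cdf = function(x, l) (1 + l / ((1 + l) * x)) * exp(-l / x),
      logpdf = function(x, l) 2 * log(l) - log(1 + l) + log1p(x) - 3 * log(x) - l / x
    ),
    thl = list(
      name = "THL", lower = -1 + 1e-9, upper = 1 - 1e-9,
      # F = (e^x - 1)(1 + 2 lambda + e^x)/(1 + e^x)^2
      cdf = function(x, l) {
        E <- exp(x)
        (E - 1) * (1 + 2 * l + E) / (1 + E)^2
      },
      # f = 2 e^x [(1 - lambda) e^x + 1 + 3 lambda] / (1 + e^x)^3
      logpdf = function(x, l) {
        E <- exp(x)
        log(2) + x + log((1 - l) * E + 1 + 3 * l) - 3 * log1p(E)
      }
    ),
    exp = list(
      name = "Exp", lower = 1e-6, upper = 1e3,
      cdf = function(x, l) stats::pexp(x, rate = l),
      logpdf = function(x, l) stats::dexp(x, rate = l, log = TRUE),
      closed_form = function(x) 1 / mean(x)
    )
  )
  if (is.null(models)) return(reg)
  key <- tolower(models)
  unknown <- setdiff(key, names(reg))
  if (length(unknown)) {
    stop("unknown model(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(key) == 1L) reg[[key]] else reg[key]
}

#' Maximum-likelihood fit of a competitor lifetime model
#'
#' Fits a single model from [olihl_competitors()] by bounded scalar
#' maximization of its log-likelihood (closed forms are used where they
#' exist: the exponential rate \eqn{1/\bar x} and the OLiHL score-quadratic
#' root). The standard error comes from the numerically differentiated
#' observed information (analytic for the OLiHL model). Transmuted
#' half-logistic estimates are clamped to the open domain \eqn{(-1, 1)} and
#' flagged when they sit against a boundary.
#'
#' @param x positive lifetimes.
#' @param model a model name (see [olihl_competitors()]) or a model
#'   definition from that registry.
#' @return an `olihl_fit` object whose `method` is `"mle"` and which carries
#'   the model name in `$model`; `$boundary` flags a domain-boundary fit.
#' @examples
#' x <- rolihl(100, 0.5)
#' fit_competitor(x, "exp")
#' @export
fit_competitor <- function(x, model) {
  check_sample(x)
  if (is.character(model)) model <- olihl_competitors(model)
  nll <- function(l) -sum(model$logpdf(x, l))
  boundary <- FALSE
  if (!is.null(model$closed_form)) {
    lam <- model$closed_form(x)
    converged <- TRUE
  } else if (model$name == "THL") {
    opt <- stats::optimize(nll, c(model$lower, model$upper), tol = 1e-12)
    lam <- opt$minimum
    eps <- 1e-6
    if (lam < -1 + eps || lam > 1 - eps) {
      lam <- min(max(lam, -1 + eps), 1 - eps)
      boundary <- TRUE
    }
    converged <- TRUE
  } else {
    res <- .minimize_scalar(nll, model$lower, model$upper)
    lam <- res$minimum
    converged <- res$converged
  }
  ll <- -nll(lam)
  se <- if (model$name == "OLiHL") {
    olihl_mle_se(lam, length(x))
  } else {
    h <- 1e-5 * (1 + abs(lam))
    info <- (nll(lam + h) - 2 * nll(lam) + nll(lam - h)) / h^2
    if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  }
  structure(list(lambda = lam, se = se, ci = NULL, ci_level = NA_real_,
                 loglik = ll, objective = -ll, method = "mle",
                 model = model$name, boundary = boundary,
                 converged = converged, n = length(x)),
            class = "olihl_fit")
}
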