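# Shared fixtures and independent oracles.

carbon_fibers <- function() {
  read_lifetime_sample(system.file("extdata", "carbon_fibers.csv",
                                   package = "olihl"))
}

# Independent maximizer of the OLiHL log-likelihood: dense grid scan,
# golden-section refinement, then bisection on the central-difference score
# (function-value search alone cannot localize a maximum much below
# sqrt(machine eps)). Deliberately ignorant of the closed-form score root.
mle_grid_oracle <- function(x, lower = 1e-4, upper = 50, grid_n = 400L) {
  grid <- exp(seq(log(lower), log(upper), length.out = grid_n))
  vals <- olihl_loglik(x, grid)
  i <- which.max(vals)
  est <- stats::optimize(function(l) olihl_loglik(x, l),
                         c(grid[max(1, i - 1)], grid[min(grid_n, i + 1)]),
                         maximum = TRUE, tol = 1e-10)$maximum
  score <- function(l) {
    h <- 1e-6 * (1 + l)
    (olihl_loglik(x, l + h) - olihl_loglik(x, l - h)) / (2 * h)
  }
  lo <- est * 0.999; hi <- est * 1.001
  if (score(lo) > 0 && score(hi) < 0) {
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (score(mid) > 0) lo <- mid else hi <- mid
    }
    est <- (lo + hi) / 2
  }
  est
}

# Reference cdf written straight from the distribution's defining formula,
# with no shared code path with polihl().
cdf_reference <- function(x, lambda) {
  ifelse(x <= 0, 0,
         1 - (lambda * exp(x) + lambda + 2) / (2 * (lambda + 1)) *
           exp(-lambda / 2 * (exp(x) - 1)))
}
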