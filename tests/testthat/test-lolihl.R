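# Naive transcription of the censored log-likelihood, expanded term by term
# (events and censored parts written out separately), used as the dual-route
# cross-check for lolihl_loglik().
expanded_loglik <- function(y, event, lambda, mu, sigma) {
  z <- (y - mu) / sigma
  w <- exp(z)
  r <- sum(event == 1)
  zf <- z[event == 1]; wf <- w[event == 1]; wc <- w[event == 0]
  r * log(lambda^2 / (4 * sigma * (lambda + 1))) +
    sum(log(exp(wf) + 1) + zf + wf) -
    sum(lambda / 2 * (exp(wf) - 1)) +
    sum(log(lambda + lambda * exp(wc) + 2) - log(2 * lambda + 2) -
          lambda / 2 * (exp(wc) - 1))
}

test_that("log-density follows from the lifetime law by change of variables", {
  for (lam in c(0.5, 2)) {
    for (y in c(-1, 0, 1)) {
      expect_equal(dlolihl(y, lam, log = TRUE),
                   dolihl(exp(y), lam, log = TRUE) + y, tolerance = 1e-12)
    }
  }
})

test_that("the location-scale family is well normalized", {
  total <- integrate(function(y) dlolihl(y, 1), -40, 10, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # family identity
  y <- seq(-3, 2, by = 0.5)
  expect_equal(dlolihl(y, 2, mu = 1.5, sigma = 0.7, log = TRUE),
               dlolihl((y - 1.5) / 0.7, 2, log = TRUE) - log(0.7),
               tolerance = 1e-12)
})

test_that("survival function has unit mass at -Inf only under the corrected sign", {
  for (lam in c(0.5, 2, 17)) {
    expect_equal(plolihl(-50, lam, lower.tail = FALSE), 1, tolerance = 1e-10)
    expect_equal(plolihl(-Inf, lam, lower.tail = FALSE), 1)
    # the printed "+1" exponent loses a factor exp(-lambda) at the boundary
    expect_equal(plolihl(-Inf, lam, lower.tail = FALSE,
                         survival_form = "printed"), exp(-lam),
                 tolerance = 1e-12)
  }
  # S decreasing, S(+Inf) = 0
  y <- seq(-6, 3, length.out = 80)
  s <- plolihl(y, 1, lower.tail = FALSE)
  expect_true(all(diff(s) <= 0))
  expect_equal(plolihl(10, 1, lower.tail = FALSE), 0, tolerance = 1e-12)
})

test_that("survival matches the lifetime law and complements the cdf", {
  y <- seq(-4, 2, by = 0.25)
  for (lam in c(0.5, 2)) {
    expect_equal(plolihl(y, lam, lower.tail = FALSE),
                 polihl(exp(y), lam, lower.tail = FALSE), tolerance = 1e-10)
    expect_equal(exp(plolihl(y, lam, log.p = TRUE, lower.tail = FALSE)) +
                   plolihl(y, lam), rep(1, length(y)), tolerance = 1e-10)
  }
  # hazard positivity: log S is nonincreasing
  ls <- plolihl(y, 1, lower.tail = FALSE, log.p = TRUE)
  expect_true(all(diff(ls) <= 0))
})

test_that("censored likelihood reduces to its two pure branches", {
  set.seed(43)
  y <- rlolihl(30, 1.5, mu = 0.5, sigma = 0.8)
  all_events <- lolihl_loglik(y, rep(1, 30), 1.5, 0.5, 0.8)
  expect_equal(as.numeric(all_events),
               sum(dlolihl(y, 1.5, 0.5, 0.8, log = TRUE)), tolerance = 1e-12)
  all_cens <- lolihl_loglik(y, rep(0, 30), 1.5, 0.5, 0.8)
  expect_equal(as.numeric(all_cens),
               sum(plolihl(y, 1.5, 0.5, 0.8, lower.tail = FALSE,
                           log.p = TRUE)), tolerance = 1e-12)
  expect_equal(attr(all_events, "n_events"), 30)
})

test_that("branch-sum likelihood equals the expanded closed form", {
  set.seed(47)
  y <- rlolihl(5, 2, mu = 1, sigma = 0.6)
  event <- c(1, 0, 1, 1, 0)
  mu_i <- c(0.8, 1.2, 1.0, 0.9, 1.1)
  got <- lolihl_loglik(y, event, 2, mu_i, 0.6)
  expect_equal(as.numeric(got), expanded_loglik(y, event, 2, mu_i, 0.6),
               tolerance = 1e-10)
})

test_that("regression recovers known parameters on simulated data", {
  d <- simulate_lolihl_data(1500, lambda = 2, beta = c(2, -0.5), sigma = 0.8,
                            censor_fraction = 0.2, seed = 101)
  expect_equal(mean(d$event == 0), 0.2, tolerance = 0.02)
  fit <- lolihl_reg(survival::Surv(y, event) ~ x1, data = d)
  expect_true(fit$converged)
  truth <- c(lambda = 2, 2, -0.5, sigma = 0.8)
  est <- fit$coefficients
  expect_true(all(abs(est - truth) < 3 * fit$se))
  # AIC identity holds exactly
  expect_equal(fit$aic - 2 * fit$n_par + 2 * fit$loglik, 0)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(td$p.value[2:3] >= 0 & td$p.value[2:3] <= 1))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  # martingale residuals average out for a well-specified model
  rM <- residuals(fit, type = "martingale")
  expect_lt(abs(mean(rM)), 0.05)      # soft centering check
  expect_true(all(rM <= 1 + 1e-12))
  expect_true(all(rM[d$event == 0] <= 0))
})

test_that("residual formulas hit their boundary limits", {
  d <- simulate_lolihl_data(200, 2, c(1.5, -0.3), 0.7, 0.25, seed = 7)
  fit <- lolihl_reg(survival::Surv(y, event) ~ x1, data = d)
  # an event far in the left tail has S ~ 1, so martingale residual ~ 1;
  # a censored point there has residual ~ 0 and deviance exactly 0
  probe <- fit
  probe$y <- c(-30, -30)
  probe$event <- c(1, 0)
  probe$X <- fit$X[1:2, , drop = FALSE]
  r <- suppressWarnings(residuals(probe, type = "both"))
  expect_equal(r$martingale, c(1, 0), tolerance = 1e-8)
  expect_equal(r$deviance[2], 0, tolerance = 1e-4)
  # the event case warns: deviance diverges as the martingale residual -> 1
  expect_warning(residuals(probe, type = "deviance"), "infinite")
  # full-sample deviance residuals are finite and signed with martingale
  rr <- residuals(fit, type = "both")
  expect_true(all(is.finite(rr$deviance)))
  expect_equal(sign(rr$deviance), sign(rr$martingale))
})

test_that("regression input contracts are enforced", {
  d <- simulate_lolihl_data(50, 1, c(1, 0.5), 0.5, 0, seed = 9)
  expect_error(lolihl_reg(y ~ x1, data = d), "Surv")
  d$x1b <- d$x1
  expect_warning(lolihl_reg(survival::Surv(y, event) ~ x1 + x1b, data = d),
                 "rank")
  expect_error(lolihl_loglik(d$y, d$event[-1], 1), "length")
  expect_error(lolihl_loglik(d$y, d$y, 1), "0/1")
})
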