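test_that("the log-likelihood is the sum of log densities", {
  set.seed(5)
  for (lam in c(0.3, 1.2)) {
    x <- rolihl(40, lam)
    expect_equal(olihl_loglik(x, lam), sum(dolihl(x, lam, log = TRUE)),
                 tolerance = 1e-10)
  }
  # single-point hand evaluation: both forms at x = ln 2, lambda = 1
  expect_equal(olihl_loglik(log(2), 1), log(0.75) - 0.5, tolerance = 1e-12)
})

test_that("closed-form MLE solves the score equation", {
  # two-point sample {ln 2, ln 3}: S = 1.5, root (0.5 + sqrt(24.25))/3
  x <- c(log(2), log(3))
  fit <- fit_olihl(x)
  expect_equal(fit$lambda, (0.5 + sqrt(24.25)) / 3, tolerance = 1e-12)
  # the score changes sign across the root
  score <- function(l) {
    h <- 1e-6
    (olihl_loglik(x, l + h) - olihl_loglik(x, l - h)) / (2 * h)
  }
  expect_gt(score(fit$lambda * 0.99), 0)
  expect_lt(score(fit$lambda * 1.01), 0)
})

test_that("closed-form MLE equals the grid + golden-section maximizer", {
  set.seed(17)
  for (i in 1:25) {
    lam <- runif(1, 0.1, 3)
    x <- rolihl(sample(20:150, 1), lam)
    expect_equal(fit_olihl(x)$lambda, mle_grid_oracle(x), tolerance = 1e-8)
  }
})

test_that("MLE standard error and Wald interval follow the observed information", {
  set.seed(23)
  x <- rolihl(200, 0.5)
  fit <- fit_olihl(x, ci_level = 0.95)
  expect_gt(fit$se, 0)
  info <- 2 * fit$n / fit$lambda^2 - fit$n / (1 + fit$lambda)^2
  expect_equal(fit$se, 1 / sqrt(info), tolerance = 1e-12)
  expect_lt(fit$ci[["lower"]], fit$lambda)
  expect_gt(fit$ci[["upper"]], fit$lambda)
  expect_equal(unname(diff(fit$ci)), 2 * qnorm(0.975) * fit$se,
               tolerance = 1e-12)
})

test_that("Wald intervals cover the truth at close to nominal rate", {
  lam <- 0.5; n <- 200; reps <- 1000
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    fit <- fit_olihl(rolihl(n, lam))
    covered[r] <- fit$ci[["lower"]] < lam && lam < fit$ci[["upper"]]
  }
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("single-observation minimum-distance fits hit their plotting position", {
  x1 <- 1.2
  # LSE: the perfect-fit shape solves F(x1) = j/(n+1) = 1/2
  expect_equal(polihl(x1, fit_olihl(x1, "lse")$lambda), 0.5, tolerance = 1e-5)
  # CVME: the single-term quadratic is minimized at F(x1) = (2j-1)/(2n) = 1/2
  expect_equal(polihl(x1, fit_olihl(x1, "cvme")$lambda), 0.5, tolerance = 1e-5)
  # ... so the two single-point estimates coincide while WLSE shares the
  # LSE position with a constant weight
  expect_equal(fit_olihl(x1, "cvme")$lambda, fit_olihl(x1, "lse")$lambda,
               tolerance = 1e-6)
})

test_that("minimum-distance objectives attain their minimum at the estimate", {
  set.seed(29)
  x <- rolihl(80, 0.7)
  for (m in c("lse", "wlse", "cvme")) {
    fit <- fit_olihl(x, m)
    xs <- sort(x); n <- length(x); j <- seq_len(n)
    obj <- switch(m,
      lse = function(l) sum((polihl(xs, l) - j / (n + 1))^2),
      wlse = function(l) sum((n + 1)^2 * (n + 2) / (j * (n - j + 1)) *
                               (polihl(xs, l) - j / (n + 1))^2),
      cvme = function(l) 1 / (12 * n) +
        sum((polihl(xs, l) - (2 * j - 1) / (2 * n))^2))
    expect_equal(fit$objective, obj(fit$lambda), tolerance = 1e-10)
    expect_lte(fit$objective, obj(fit$lambda * 1.1))
    expect_lte(fit$objective, obj(fit$lambda * 0.9))
    if (m == "cvme") expect_gte(fit$objective, 1 / (12 * n))
    expect_true(fit$converged)
  }
})

test_that("estimates are invariant to the ordering of the input", {
  set.seed(37)
  x <- rolihl(60, 0.4)
  xp <- sample(x)
  for (m in c("mle", "lse", "wlse", "cvme")) {
    expect_identical(fit_olihl(x, m)$lambda, fit_olihl(xp, m)$lambda)
  }
})

test_that("all four estimators are consistent as n grows", {
  methods <- c("mle", "lse", "wlse", "cvme")
  reps <- 30
  for (lam in c(0.1, 0.5, 2)) {
    mae <- matrix(NA_real_, 3, 4, dimnames = list(NULL, methods))
    for (k in seq_along(c(50, 200, 1000))) {
      n <- c(50, 200, 1000)[k]
      err <- matrix(NA_real_, reps, 4, dimnames = list(NULL, methods))
      for (r in seq_len(reps)) {
        set.seed(1e6 * k + 1000 * r + round(100 * lam))
        x <- rolihl(n, lam)
        for (m in methods) err[r, m] <- abs(fit_olihl(x, m)$lambda - lam)
      }
      mae[k, ] <- apply(err, 2, median)
    }
    for (m in methods) expect_true(all(diff(mae[, m]) < 0))
  }
})

test_that("tidy and glance give broom-shaped summaries", {
  set.seed(41)
  x <- rolihl(100, 0.6)
  fit <- fit_olihl(x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "method"))
  expect_equal(td$estimate, fit$lambda)
  gl <- glance(fit)
  expect_equal(gl$AIC, 2 - 2 * fit$loglik)
  expect_equal(gl$nobs, 100)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_olihl(c(1, -2)), "positive")
  expect_error(fit_olihl(numeric(0)), "at least one")
  expect_error(fit_olihl(c(1, Inf)), "positive")
  expect_error(olihl_loglik(c(1, 750), 1), "overflow")
})
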