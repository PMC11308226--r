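test_that("Harrell's c reproduces hand-computable cases", {
  expect_equal(harrell_c(c(0.9, 0.1), c(1, 0))$value, 1)
  expect_equal(harrell_c(c(0.2, 0.4, 0.4, 0.8), c(0, 1, 0, 1))$value, 0.875)
  y <- rep(c(0, 1), 10)
  expect_equal(harrell_c(y, y)$value, 1)
  expect_error(harrell_c(c(0.2, 0.8), c(1, 1)), "degenerate|non-event")
})

test_that("rank-based c equals brute-force enumeration on random instances", {
  withr::with_seed(101, {
    for (i in 1:30) {
      n <- sample(4:50, 1)
      p <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
      y <- rbinom(n, 1, 0.5)
      if (sum(y) %in% c(0, n)) y[1:2] <- c(0, 1)
      expect_identical(harrell_c(p, y)$value, brute_force_c(p, y))
    }
  })
})

test_that("c is monotone-transform invariant and complement-symmetric", {
  withr::with_seed(7, {
    p <- runif(60)
    y <- rbinom(60, 1, p)
    if (sum(y) %in% c(0, 60)) y[1:2] <- c(0, 1)
    c1 <- harrell_c(p, y)$value
    expect_equal(harrell_c(plogis(5 * qlogis(p)), y)$value, c1)
    expect_equal(harrell_c(rank(p) / 61, y)$value, c1)
    expect_equal(harrell_c(1 - p, y)$value, 1 - c1)
  })
})

test_that("the DeLong standard error matches an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    p <- runif(200)
    y <- rbinom(200, 1, p)
    est <- harrell_c(p, y)
    roc <- pROC::roc(y, p, quiet = TRUE, direction = "<")
    expect_equal(est$value, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
    expect_equal(est$se, sqrt(pROC::var(roc, method = "delong")),
                 tolerance = 1e-8)
  })
  # bootstrap CI option returns a sane interval
  withr::with_seed(2, {
    p <- runif(80)
    y <- rbinom(80, 1, p)
    bs <- harrell_c(p, y, ci = "bootstrap", boot_b = 200, seed = 4)
    expect_true(bs$ci_low < bs$value && bs$value < bs$ci_high)
  })
})

test_that("model-based c matches its single-pair formula and brute force", {
  expect_equal(model_based_c(c(0.5, 0.5))$value, 0.5)
  expect_equal(model_based_c(c(0.2, 0.8))$value, 0.64 / 0.68)
  expect_equal(model_based_c(c(0, 1))$value, 1)
  withr::with_seed(55, {
    for (i in 1:25) {
      n <- sample(3:40, 1)
      p <- round(runif(n), sample(1:3, 1))
      if (brute_force_is_degenerate(p)) p <- c(p, 0.5, 0.7)
      expect_equal(model_based_c(p)$value, brute_force_model_based_c(p),
                   tolerance = 1e-12)
    }
  })
  expect_error(model_based_c(0.4), "two")
  expect_error(model_based_c(c(1, 1, 1)), "undefined")
})

test_that("calibration intercept behaves as an offset identity", {
  # symmetric construction with exact expected frequencies forces a = 0
  lp <- rep(c(-1, 1), each = 50)
  y <- c(rep(c(1, 0), c(round(50 * plogis(-1)), 50 - round(50 * plogis(-1)))),
         rep(c(1, 0), c(round(50 * plogis(1)), 50 - round(50 * plogis(1)))))
  a0 <- calibration_intercept(lp, y)$value
  # oracle: Newton solve of sum(y - plogis(a + lp)) = 0
  newton <- function(a) sum(y - plogis(a + lp))
  a_star <- uniroot(newton, c(-2, 2), tol = 1e-12)$root
  expect_equal(a0, a_star, tolerance = 1e-6)

  # shifting lp by +delta moves the intercept to -delta
  d <- toy_data(k = 2, n = 1500, seed = 21)
  fit <- fit_outcome_model(d)
  pr <- predict_risk(fit, d)
  expect_equal(calibration_intercept(pr$lp, d$y_favorable)$value, 0,
               tolerance = 1e-6)
  expect_equal(calibration_intercept(pr$lp + 0.7, d$y_favorable)$value, -0.7,
               tolerance = 1e-6)
})

test_that("calibration slope is 1 for a refit model, 0 under independence", {
  d <- toy_data(k = 2, n = 1500, seed = 22)
  fit <- fit_outcome_model(d)
  pr <- predict_risk(fit, d)
  expect_equal(calibration_slope(pr$lp, d$y_favorable)$value, 1,
               tolerance = 1e-6)
  expect_equal(calibration_slope(c(-1, 1, -1, 1), c(0, 1, 1, 0))$value, 0,
               tolerance = 1e-8)
  expect_error(calibration_slope(c(-2, -1, 1, 2), c(0, 0, 1, 1)), "separat")
  expect_error(calibration_slope(rep(0.3, 10), rep(c(0, 1), 5)), "constant")
})

test_that("slope estimation is consistent under a correctly specified model", {
  withr::with_seed(77, {
    lp <- rnorm(1e5, 0, 1.2)
    y <- rbinom(1e5, 1, plogis(lp))
    expect_equal(calibration_slope(lp, y)$value, 1, tolerance = 0.05)
    expect_equal(calibration_intercept(lp, y)$value, 0, tolerance = 0.05)
  })
})

test_that("calibration curves bin correctly and detect miscalibration", {
  withr::with_seed(31, {
    p <- runif(5000)
    y <- rbinom(5000, 1, p)
    cc <- calibration_curve(p, y)
    expect_equal(sum(cc$bins$n), 5000)
    expect_equal(nrow(cc$bins), 10)
    # calibrated data: all bins within 3 binomial SEs of the diagonal
    se <- sqrt(cc$bins$p_mean * (1 - cc$bins$p_mean) / cc$bins$n)
    expect_true(all(abs(cc$bins$obs_frac - cc$bins$p_mean) < 3 * se))

    # miscalibrated: y ~ Bernoulli(p^2) falls below the diagonal
    y2 <- rbinom(5000, 1, p^2)
    cc2 <- calibration_curve(p, y2)
    mid <- cc2$bins$p_mean < 0.9
    expect_true(all(cc2$bins$obs_frac[mid] < cc2$bins$p_mean[mid] + 3 * se[mid]))
    expect_gt(mean(cc2$bins$p_mean[mid] - cc2$bins$obs_frac[mid]), 0.05)
  })
  # degenerate spread: one usable bin at the mean
  cc3 <- calibration_curve(rep(0.3, 100), rbinom(100, 1, 0.3))
  expect_equal(nrow(cc3$bins), 1)
  expect_equal(cc3$bins$p_mean, 0.3)
  expect_error(calibration_curve(runif(50), rbinom(50, 1, 0.5), n_bins = 1),
               "n_bins")
})
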