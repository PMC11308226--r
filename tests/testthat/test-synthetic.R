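test_that("the SAHIT-like preset reproduces the published repository structure", {
  cfg <- sahit_like_preset(seed = 1)
  specs <- cfg$cluster_specs
  expect_length(specs, 14)
  sizes <- vapply(specs, function(s) s$n, integer(1))
  expect_equal(sum(sizes), 11931L)
  expect_setequal(sizes, c(60L, 75L, 117L, 160L, 228L, 327L, 413L, 433L, 439L,
                           1000L, 1484L, 1500L, 2143L, 3552L))
  wfns <- vapply(specs, function(s) s$p_wfns_high, numeric(1))
  expect_equal(round(min(wfns), 2), 0)
  expect_equal(round(max(wfns), 2), 0.78)
  targets <- attr(cfg, "targets")
  expect_equal(round(range(targets$p_favorable), 2), c(0.60, 0.92))
  # some studies did not record hypertension: block-missing columns present
  miss <- unlist(lapply(specs, function(s) s$missing_columns))
  expect_true("hypertension" %in% miss)
})

test_that("generated preset data matches the repository's marginal structure", {
  cfg <- sahit_like_preset(seed = 23)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 11931)
  expect_equal(length(unique(d$cluster_id)), 14)
  # overall favorable fraction close to the repository's 80%
  targets <- attr(cfg, "targets")
  expected <- sum(targets$n * targets$p_favorable) / sum(targets$n)
  se <- sqrt(expected * (1 - expected) / nrow(d))
  expect_lt(abs(mean(d$y_favorable) - expected), 3 * se)
  expect_lt(abs(mean(d$y_favorable) - 0.80), 0.02)
  # block-missing columns are missing for the whole cluster, observed elsewhere
  hhu <- d[d$cluster_id == "HHU", ]
  expect_true(all(is.na(hhu$hypertension)))
  expect_true(all(!is.na(d$hypertension[d$cluster_id == "IHAST"])))
  expect_true(all(is.na(d$location[d$cluster_id == "Chicago"])))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  cfg1 <- toy_config(seed = 42)
  d1 <- generate_dataset(cfg1)
  d2 <- generate_dataset(cfg1)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_dataset(toy_config(seed = 43))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("empirical prevalences converge to the cluster spec", {
  spec <- cluster_spec("big", 1e5, p_wfns_high = 0.3, p_hypertension = 0.45,
                       fisher_probs = c(0.1, 0.2, 0.3, 0.4), p_size_large = 0.2)
  d <- generate_dataset(generator_config(list(spec), seed = 5))
  for (chk in list(c("wfns_high", 0.3), c("hypertension", 0.45),
                   c("size_large", 0.2))) {
    p <- as.numeric(chk[2])
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mean(d[[chk[1]]]) - p), 3 * se)
  }
  f4 <- mean(d$fisher == 4)
  expect_lt(abs(f4 - 0.4), 3 * sqrt(0.4 * 0.6 / 1e5))
})

test_that("a pooled logistic fit recovers the generating coefficients", {
  specs <- list(cluster_spec("A", 25000), cluster_spec("B", 25000))
  cfg <- generator_config(specs, seed = 31)
  d <- generate_dataset(cfg)
  fit <- fit_outcome_model(d)
  est <- c(`(Intercept)` = fit$intercept, fit$beta)
  truth <- c(`(Intercept)` = cfg$true_intercept, cfg$true_beta)
  ses <- sqrt(diag(fit$vcov))
  names(truth) <- names(est)
  expect_true(all(abs(est - truth) < 3 * ses))
})

test_that("exchangeable clusters under zero heterogeneity look exchangeable", {
  d <- toy_data(k = 2, n = 2000, seed = 99)
  a <- d[d$cluster_id == "C1", ]
  b <- d[d$cluster_id == "C2", ]
  expect_gt(t.test(a$age, b$age)$p.value, 0.01)
  expect_gt(prop.test(c(sum(a$y_favorable), sum(b$y_favorable)),
                      c(nrow(a), nrow(b)))$p.value, 0.01)
})

test_that("MAR injection hits target rates and respects the boundaries", {
  d <- toy_data(k = 2, n = 5000, seed = 3)
  same <- inject_mar_missingness(d, c(hypertension = 0), seed = 1)
  expect_identical(as.data.frame(same), as.data.frame(d))
  all_miss <- inject_mar_missingness(d, c(hypertension = 1), seed = 1)
  expect_true(all(is.na(all_miss$hypertension)))
  mar <- inject_mar_missingness(d, c(hypertension = 0.36), seed = 8)
  rate <- mean(is.na(mar$hypertension))
  expect_lt(abs(rate - 0.36), 3 * sqrt(0.36 * 0.64 / nrow(d)))
  # mechanism is covariate-dependent (MAR, not MCAR)
  expect_gt(
    mean(d$age[is.na(mar$hypertension)]) - mean(d$age[!is.na(mar$hypertension)]),
    0
  )
  expect_error(inject_mar_missingness(d, c(hypertension = 1.2)), "probabilit")
})

test_that("per-coefficient heterogeneity spreads the calibration slope", {
  specs <- lapply(1:6, function(i) cluster_spec(paste0("k", i), 1500))
  d0 <- generate_dataset(generator_config(specs, seed = 11))
  d1 <- generate_dataset(generator_config(specs, tau_beta = 0.4, seed = 11))
  slope_spread <- function(d) {
    sl <- vapply(unique(d$cluster_id), function(k) {
      fit <- fit_outcome_model(d[d$cluster_id != k, ])
      pr <- predict_risk(fit, d[d$cluster_id == k, ])
      calibration_slope(pr$lp, d$y_favorable[d$cluster_id == k])$value
    }, numeric(1))
    sd(sl)
  }
  expect_gt(slope_spread(d1), slope_spread(d0))
})

test_that("invalid specs are rejected", {
  expect_error(cluster_spec("x", 0), "positive")
  expect_error(cluster_spec("x", 10, fisher_probs = c(0.5, 0.5, 0.1, 0.1)),
               "fisher_probs")
  expect_error(cluster_spec("x", 10, location_probs = rep(0.2, 5)),
               "location_probs")
  expect_error(generator_config(list(cluster_spec("x", 10)), tau_intercept = -1),
               "non-negative")
  expect_error(generator_config(list(), seed = 1), "non-empty")
})
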