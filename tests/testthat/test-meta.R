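test_that("homogeneous estimates pool to themselves with zero heterogeneity", {
  mp <- meta_pool(c(0.7, 0.7, 0.7), se = c(0.05, 0.05, 0.05))
  expect_equal(mp$pooled, 0.7, tolerance = 1e-10)
  expect_equal(mp$tau2, 0)
  expect_equal(mp$Q, 0, tolerance = 1e-20)
  expect_equal(mp$i2, 0)
})

test_that("DerSimonian-Laird matches its closed form on a two-study case", {
  mp <- meta_pool(c(0, 2), se = c(1, 1), transform = "identity", method = "DL")
  expect_equal(mp$Q, 2)
  expect_equal(mp$df, 1)
  expect_equal(mp$tau2, 1) # (Q - df) / (sum(w) - sum(w^2)/sum(w)) = 1/1
  expect_equal(mp$i2, 50)
  expect_equal(mp$pooled, 1)
})

test_that("I-squared follows its defining formula with a zero floor", {
  expect_equal(i_squared(1, 4), 0)
  expect_equal(i_squared(2, 1), 50)
  expect_equal(i_squared(100, 8), 92)
  expect_equal(i_squared(0, 3), 0)
  expect_error(i_squared(2, 0), "df")
})

test_that("with tau2 = 0 pooling reduces to fixed-effect inverse-variance weighting", {
  est <- c(0.10, 0.12, 0.11, 0.09)
  ses <- c(0.02, 0.03, 0.025, 0.04)
  mp <- meta_pool(est, se = ses, transform = "identity", method = "DL")
  expect_equal(mp$tau2, 0)
  w <- 1 / ses^2
  expect_equal(mp$pooled, sum(w * est) / sum(w), tolerance = 1e-12)
  expect_true(mp$pooled >= min(est) && mp$pooled <= max(est))
})

test_that("in-package DL and REML agree with metafor on random inputs", {
  skip_if_not_installed("metafor")
  withr::with_seed(61, {
    for (i in 1:10) {
      k <- sample(5:20, 1)
      ses <- runif(k, 0.05, 0.3)
      theta <- rnorm(k, 0.5, sqrt(0.04 + ses^2))
      for (m in c("DL", "REML")) {
        mp <- meta_pool(theta, se = ses, transform = "identity", method = m)
        rf <- metafor::rma(yi = theta, sei = ses, method = m)
        # metafor's Fisher-scoring REML stops at its own (looser) threshold
        expect_equal(mp$pooled, as.numeric(rf$b), tolerance = 1e-4)
        expect_equal(mp$tau2, rf$tau2, tolerance = 1e-3)
        expect_equal(mp$Q, rf$QE, tolerance = 1e-8)
      }
    }
  })
})

test_that("DL and REML agree on well-conditioned balanced inputs", {
  withr::with_seed(44, {
    ses <- rep(0.1, 50)
    theta <- rnorm(50, 0, sqrt(0.09 + 0.01))
    dl <- meta_pool(theta, se = ses, transform = "identity", method = "DL")
    reml <- meta_pool(theta, se = ses, transform = "identity", method = "REML")
    expect_lt(abs(dl$tau2 - reml$tau2) / reml$tau2, 0.10)
  })
})

test_that("the DL moment estimator is unbiased for tau2 in simulation", {
  withr::with_seed(90, {
    tau2 <- 0.04
    ses <- runif(12, 0.08, 0.2)
    est <- replicate(1000, {
      theta <- rnorm(12, 0.3, sqrt(tau2 + ses^2))
      meta_pool(theta, se = ses, transform = "identity", method = "DL")$tau2
    })
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - tau2), 3 * mc_se)
  })
})

test_that("logit pooling back-transforms and accepts transformed-scale SEs", {
  cs <- c(0.65, 0.72, 0.78, 0.70)
  ses <- c(0.03, 0.02, 0.025, 0.03)
  mp <- meta_pool(cs, se = ses, transform = "logit")
  expect_true(mp$pooled > min(cs) && mp$pooled < max(cs))
  expect_equal(mp$pooled, plogis(mp$mu_transformed))
  se_t <- se_from_ci(cs - 1.96 * ses, cs + 1.96 * ses, "logit")
  mp2 <- meta_pool(cs, se = se_t, transform = "logit", se_scale = "transformed")
  expect_equal(mp2$pooled, mp$pooled, tolerance = 0.01)
  expect_error(meta_pool(c(0.5, 1.2), se = c(0.1, 0.1), transform = "logit"),
               "inside")
  expect_error(meta_pool(c(0.5, 0.6), se = c(0.1, -0.1)), "positive")
  expect_error(meta_pool(0.5, se = 0.1), "two")
})

test_that("the Hartung-Knapp option widens the pooled CI under heterogeneity", {
  est <- c(0.1, 0.5, -0.2, 0.8, 0.3)
  ses <- rep(0.05, 5)
  wald <- meta_pool(est, se = ses, transform = "identity")
  hk <- meta_pool(est, se = ses, transform = "identity", ci = "hartung-knapp")
  expect_equal(hk$pooled, wald$pooled)
  expect_lt(hk$ci_low, wald$ci_low)
  expect_gt(hk$ci_high, wald$ci_high)
})

test_that("forest data carries every cluster plus a consistent pooled row", {
  mp <- meta_pool(sahit_performance(), estimate = "c",
                  se = se_from_ci(sahit_performance()$c_low,
                                  sahit_performance()$c_high, "logit"),
                  se_scale = "transformed")
  fd <- forest_data(mp)
  expect_equal(nrow(fd), 15)
  pooled_row <- fd[fd$type == "pooled", ]
  expect_equal(pooled_row$estimate, mp$pooled)
  expect_equal(pooled_row$ci_low, mp$ci_low)
  expect_equal(pooled_row$i2, mp$i2)
  # positional labels generated when none supplied
  mp2 <- meta_pool(c(0.1, 0.2), se = c(0.1, 0.1), transform = "identity")
  expect_equal(forest_data(mp2, labels = character(0))$label[1], "cluster_1")
  expect_error(forest_data(mp2, labels = c("only-one")), "match")
})
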