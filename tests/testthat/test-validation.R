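test_that("leave-one-cluster-out equals a hand-scripted fit-then-evaluate oracle", {
  d <- toy_data(k = 3, n = 150, seed = 7)
  res <- loco_cv(d)
  expect_s3_class(res, "iecv_result")
  expect_equal(nrow(res$estimates), 3 * 4) # 3 clusters x 4 metrics
  for (k in unique(d$cluster_id)) {
    train <- as.data.frame(d[d$cluster_id != k, ])
    test <- as.data.frame(d[d$cluster_id == k, ])
    oracle_fit <- glm(
      y_favorable ~ age + wfns_high + hypertension + factor(fisher) +
        size_large + factor(location, levels = c("ACA", "ACOM", "ICA", "MCA",
                                                 "PCOM", "Posterior")),
      family = binomial(), data = train
    )
    p <- unname(predict(oracle_fit, newdata = test, type = "response"))
    lp <- unname(predict(oracle_fit, newdata = test))
    rows <- res$estimates[res$estimates$cluster_id == k, ]
    expect_equal(rows$value[rows$metric == "c"],
                 brute_force_c(p, test$y_favorable), tolerance = 1e-10)
    expect_equal(rows$value[rows$metric == "c_model_based"],
                 brute_force_model_based_c(p), tolerance = 1e-8)
    oracle_int <- glm(test$y_favorable ~ 1, offset = lp, family = binomial())
    expect_equal(rows$value[rows$metric == "cal_intercept"],
                 unname(coef(oracle_int)[1]), tolerance = 1e-6)
    oracle_slope <- glm(test$y_favorable ~ lp, family = binomial())
    expect_equal(rows$value[rows$metric == "cal_slope"],
                 unname(coef(oracle_slope)[2]), tolerance = 1e-6)
  }
})

test_that("cross-validation results do not depend on cluster order", {
  d <- toy_data(k = 3, n = 120, seed = 15)
  res1 <- loco_cv(d)
  perm <- order(rev(seq_len(nrow(d))))
  res2 <- loco_cv(d[rev(seq_len(nrow(d))), ])
  e1 <- res1$estimates[order(res1$estimates$cluster_id, res1$estimates$metric), ]
  e2 <- res2$estimates[order(res2$estimates$cluster_id, res2$estimates$metric), ]
  expect_equal(e1$value, e2$value, tolerance = 1e-10)
  # dropping a cluster leaves the other evaluations against the same
  # training complements unchanged only when their complements are unchanged;
  # here we check the engine reruns reproducibly
  res3 <- loco_cv(d)
  expect_equal(res1$estimates$value, res3$estimates$value)
})

test_that("exchangeable clusters show apparent-level discrimination and unit slope", {
  d <- toy_data(k = 2, n = 4000, seed = 33)
  res <- loco_cv(d)
  app_c <- res$apparent$value[res$apparent$metric == "c"]
  for (k in c("C1", "C2")) {
    rows <- res$estimates[res$estimates$cluster_id == k, ]
    cc <- rows[rows$metric == "c", ]
    expect_lt(abs(cc$value - app_c), 3 * cc$se)
    sl <- rows[rows$metric == "cal_slope", ]
    expect_lt(abs(sl$value - 1), 3 * sl$se)
  }
})

test_that("the full SAHIT-like repository yields one row per cluster per metric", {
  d <- generate_dataset(sahit_like_preset(seed = 3))
  # complete-case predictor columns for a fast engine check: impute with m = 1
  res <- loco_cv(d, m = 1, iterations = 2, seed = 5)
  expect_equal(sort(unique(res$estimates$cluster_id)),
               sort(unique(d$cluster_id)))
  counts <- table(res$estimates$metric)
  expect_true(all(counts == 14))
  expect_true(all(res$estimates$value[res$estimates$metric == "c"] > 0.5,
                  na.rm = TRUE))
})

test_that("errors and degenerate clusters are handled explicitly", {
  d <- toy_data(k = 1, n = 100, seed = 2)
  expect_error(loco_cv(d), "2 clusters")
  d2 <- toy_data(k = 3, n = 100, seed = 2)
  d2$y_favorable[d2$cluster_id == "C3"] <- 1L
  expect_warning(res <- loco_cv(d2), "degenerate")
  expect_true(all(is.na(res$estimates$value[res$estimates$cluster_id == "C3"])))
})

test_that("optimism correction is zero at B = 0 and negative-direction under overfitting", {
  d <- toy_data(k = 2, n = 300, seed = 41)
  b0 <- optimism_corrected_c(d, B = 0)
  expect_equal(b0$value, b0$apparent)
  expect_equal(b0$optimism, 0)

  # overfit: full 11-column design on 100 patients
  d_small <- toy_data(k = 2, n = 50, seed = 43)
  bc <- optimism_corrected_c(d_small, B = 50, seed = 9)
  expect_gt(bc$optimism, 0)
  expect_lt(bc$value, bc$apparent)
})

test_that("optimism vanishes for large samples with few predictors", {
  d <- generate_dataset(generator_config(list(cluster_spec("A", 30000)),
                                         seed = 47))
  bc <- optimism_corrected_c(d, small_spec(), B = 100, seed = 11)
  expect_lt(abs(bc$optimism), 0.005)
})

test_that("the single-study view decomposes discrimination by case-mix", {
  d <- toy_data(k = 3, n = 400, seed = 51)
  res <- loco_cv(d)
  v <- single_study_view(res, "C1")
  expect_equal(v$delta,
               res$estimates$value[res$estimates$cluster_id == "C1" &
                                     res$estimates$metric == "c"] -
                 res$estimates$value[res$estimates$cluster_id == "C1" &
                                       res$estimates$metric == "c_model_based"])
  expect_true(v$case_mix_label %in% c(
    "no case-mix contribution", "case-mix-driven decrease",
    "miscalibration-consistent"
  ))
  expect_error(single_study_view(res, "nope"), "Unknown cluster")

  # label logic on synthetic result rows
  res2 <- res
  res2$estimates$value[res2$estimates$cluster_id == "C2" &
                         res2$estimates$metric == "c"] <- 0.66
  res2$estimates$value[res2$estimates$cluster_id == "C2" &
                         res2$estimates$metric == "c_model_based"] <- 0.76
  expect_equal(single_study_view(res2, "C2")$case_mix_label,
               "case-mix-driven decrease")
  res2$estimates$value[res2$estimates$cluster_id == "C2" &
                         res2$estimates$metric == "c"] <- 0.76
  res2$estimates$value[res2$estimates$cluster_id == "C2" &
                         res2$estimates$metric == "c_model_based"] <- 0.76
  expect_equal(single_study_view(res2, "C2")$case_mix_label,
               "no case-mix contribution")
})
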