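# Validation orchestration: apparent performance, bootstrap optimism
# correction, leave-one-cluster-out internal-external cross-validation, and
# the single-study external-validation view of one left-out cluster.

metric_names <- function() c("c", "c_model_based", "cal_intercept", "cal_slope")

# All four metrics of one model evaluated on one validation set.
evaluate_cluster <- function(model, data, cluster_id = NA_character_) {
  pr <- predict_risk(model, data)
  y <- data[[model$spec$outcome]]
  if (all(y == 1, na.rm = TRUE) || all(y == 0, na.rm = TRUE)) {
    warn(sprintf("Cluster `%s` has a degenerate outcome; metrics undefined.", cluster_id))
    return(bind_rows(lapply(metric_names(), function(mn) {
      performance_estimate(mn, NA_real_, n = length(y), n_events = sum(y),
                           cluster_id = cluster_id)
    })))
  }
  bind_rows(
    harrell_c(pr$p, y, cluster_id = cluster_id),
    model_based_c(pr$p, cluster_id = cluster_id),
    calibration_intercept(pr$lp, y, cluster_id = cluster_id),
    tryCatch(calibration_slope(pr$lp, y, cluster_id = cluster_id),
             error = function(e) {
               warn(sprintf("Cluster `%s`: %s", cluster_id, conditionMessage(e)))
               performance_estimate("cal_slope", NA_real_, n = length(y),
                                    n_events = sum(y), cluster_id = cluster_id)
             })
  )
}

#' Leave-one-cluster-out internal-external cross-validation
#'
#' Each cluster is left out of model development in turn and used as a
#' stand-alone external validation set: the model is refitted on all
#' remaining clusters and Harrell's c, the model-based c, and the calibration
#' intercept and slope are evaluated in the left-out cluster. The split is
#' non-random, so results do not depend on iteration order. When the data
#' contain missing predictor values and `m > 0`, the whole dataset is
#' multiply imputed first (once, over all clusters jointly), the
#' cross-validation runs per completed dataset, and per-cluster estimates are
#' combined with Rubin's rules (c on the logit scale).
#'
#' @param data Clustered dataset with `cluster_id`, the predictors, and the
#'   binary outcome.
#' @param spec A [model_spec()].
#' @param m Number of imputations when predictors have missing values
#'   (default 5; ignored for complete data).
#' @param iterations Chained-equation cycles per imputation.
#' @param seed Seed for imputation.
#' @return An object of class `iecv_result`: `$estimates` (tidy per-cluster
#'   tibble, one row per cluster per metric), `$models` (the K leave-one-out
#'   fits from the first completed dataset), `$apparent` (apparent
#'   performance of the full-data fit), `$curves` (per-cluster
#'   [calibration_curve()] data), and `$provenance`. Use [tidy()] /
#'   [glance()] and [meta_pool()] downstream.
#' @export
loco_cv <- function(data, spec = model_spec(), m = 5, iterations = 5, seed = 1L) {
  data <- as_tibble(data)
  if (!"cluster_id" %in% names(data)) abort("`data` needs a `cluster_id` column.")
  clusters <- unique(as.character(data$cluster_id))
  if (length(clusters) < 2) abort("Cross-validation needs at least 2 clusters.")
  modeled <- c(spec$predictors, spec$outcome)
  has_miss <- anyNA(data[modeled])
  if (has_miss) {
    if (m < 1) abort("Data contain missing values; set `m >= 1` to impute.")
    imps <- impute_chained(data, m = m, iterations = iterations, seed = seed,
                           columns = modeled)
    completed <- imps$completed
  } else {
    completed <- list(data)
  }
  runs <- map(completed, function(d) loco_pass(d, spec))
  estimates <- pool_imputation_runs(map(runs, "estimates"))
  apparent <- pool_imputation_runs(map(runs, "apparent"))
  structure(
    list(
      estimates = estimates,
      models = runs[[1]]$models,
      apparent = apparent,
      curves = runs[[1]]$curves,
      provenance = list(
        seed = seed, m = length(completed), imputed = has_miss,
        clusters = clusters, n = nrow(data)
      )
    ),
    class = "iecv_result"
  )
}

# One full leave-one-cluster-out pass over a completed (no-missing) dataset.
loco_pass <- function(data, spec) {
  clusters <- unique(as.character(data$cluster_id))
  models <- list()
  curves <- list()
  est <- map(clusters, function(k) {
    train <- data[data$cluster_id != k, ]
    test <- data[data$cluster_id == k, ]
    fit <- fit_outcome_model(train, spec)
    models[[k]] <<- fit
    pr <- predict_risk(fit, test)
    curves[[k]] <<- tryCatch(
      calibration_curve(pr$p, test[[spec$outcome]],
                        n_bins = min(10, max(2, nrow(test) %/% 20))),
      error = function(e) NULL
    )
    evaluate_cluster(fit, test, cluster_id = k)
  })
  full_fit <- fit_outcome_model(data, spec)
  apparent <- evaluate_cluster(full_fit, data, cluster_id = "apparent")
  list(estimates = list_rbind(est), models = models, curves = curves,
       apparent = apparent)
}

# Rubin's-rules combination of per-cluster metric rows across imputations
# (c-type metrics on the logit scale). With one run, rows pass through.
pool_imputation_runs <- function(runs) {
  if (length(runs) == 1) return(runs[[1]])
  all <- list_rbind(imap(runs, function(r, i) mutate(r, .imp = i)))
  all |>
    group_by(.data$cluster_id, .data$metric) |>
    group_modify(function(g, key) {
      logit_scale <- key$metric %in% c("c", "c_model_based")
      pooled <- rubin_pool(
        g$value, g$se^2,
        transform = if (logit_scale) "logit" else "identity"
      )
      tibble(
        value = pooled$estimate, se = pooled$se,
        ci_low = pooled$ci_low, ci_high = pooled$ci_high,
        n = g$n[1], n_events = g$n_events[1]
      )
    }) |>
    ungroup() |>
    select(all_of(c("metric", "value", "se", "ci_low", "ci_high",
                    "n", "n_events", "cluster_id")))
}

#' @export
print.iecv_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-cluster-out cross-validation: %d clusters, n = %d%s\n",
    length(x$provenance$clusters), x$provenance$n,
    if (x$provenance$imputed) sprintf(" (m = %d imputations)", x$provenance$m) else ""
  ))
  wide <- tidyr::pivot_wider(
    x$estimates[, c("cluster_id", "metric", "value")],
    names_from = "metric", values_from = "value"
  )
  print(mutate(wide, across(-1, ~ round(.x, 3))), n = Inf)
  invisible(x)
}

#' @export
tidy.iecv_result <- function(x, ...) x$estimates

#' @export
glance.iecv_result <- function(x, ...) {
  tibble(
    k = length(x$provenance$clusters),
    n = x$provenance$n,
    apparent_c = x$apparent$value[x$apparent$metric == "c"],
    m_imputations = x$provenance$m,
    imputed = x$provenance$imputed
  )
}

#' Bootstrap optimism-corrected c-statistic
#'
#' Harrell's bootstrap: for each of `B` resamples of patients (with
#' replacement) the model is refitted; the optimism is the mean difference
#' between the refit's c on its own bootstrap sample and on the original
#' data, and is subtracted from the apparent c. This internally validated
#' benchmark is the reference against which per-cluster external performance
#' is compared.
#'
#' @param data Complete clustered dataset.
#' @param spec A [model_spec()].
#' @param B Number of bootstrap resamples (default 200). `B = 0` returns the
#'   apparent c unchanged.
#' @param seed Seed for resampling.
#' @return One-row tibble with metric `"c_optimism_corrected"` plus columns
#'   `apparent` and `optimism`.
#' @export
optimism_corrected_c <- function(data, spec = model_spec(), B = 200, seed = 1L) {
  data <- as_tibble(data)
  y <- assert_binary_outcome(data[[spec$outcome]])
  X <- design_matrix(data, spec)
  apparent_fit <- fit_logistic_raw(X, y)
  p_app <- expit(clamp_lp(apparent_fit$intercept + drop(X %*% apparent_fit$beta)))
  app <- harrell_c(p_app, y)
  if (B == 0) {
    out <- performance_estimate("c_optimism_corrected", app$value, app$se,
                                app$ci_low, app$ci_high,
                                n = length(y), n_events = sum(y))
    out$apparent <- app$value
    out$optimism <- 0
    return(out)
  }
  n <- length(y)
  optimisms <- with_seed(seed, map_dbl(seq_len(B), function(b) {
    for (try in 1:20) {
      idx <- sample.int(n, replace = TRUE)
      if (!(sum(y[idx]) %in% c(0L, n))) break
      if (try == 20) abort("Bootstrap resamples persistently degenerate.")
    }
    fit_b <- fit_logistic_raw(X[idx, , drop = FALSE], y[idx])
    lp_all <- fit_b$intercept + drop(X %*% fit_b$beta)
    p_all <- expit(clamp_lp(lp_all))
    c_boot <- c_from_ranks(p_all[idx], y[idx])
    c_orig <- c_from_ranks(p_all, y)
    c_boot - c_orig
  }))
  optimism <- mean(optimisms)
  corrected <- app$value - optimism
  out <- performance_estimate(
    "c_optimism_corrected", corrected, app$se,
    corrected - qnorm(0.975) * app$se, corrected + qnorm(0.975) * app$se,
    n = n, n_events = sum(y)
  )
  out$apparent <- app$value
  out$optimism <- optimism
  out
}

#' Single-study external-validation view of one cluster
#'
#' Formats one cluster of a cross-validation result as a stand-alone
#' external-validation report, including the case-mix decomposition
#' `delta = Harrell's c - model-based c`. A clearly negative delta marks a
#' discrimination drop attributable to a homogeneous case-mix in the
#' validation cluster; a clearly positive delta, with the model-based c as
#' the case-mix ceiling, is consistent with miscalibration driving the
#' difference. `|delta| <= 0.02` is read as no case-mix contribution (a
#' package convention).
#'
#' @param result An `iecv_result` from [loco_cv()].
#' @param cluster_id Which cluster to report.
#' @return An object of class `single_study_view`: estimates tibble, `delta`,
#'   and a `case_mix_label`.
#' @export
single_study_view <- function(result, cluster_id) {
  stopifnot(inherits(result, "iecv_result"))
  est <- filter(result$estimates, .data$cluster_id == !!cluster_id)
  if (!nrow(est)) abort(sprintf("Unknown cluster `%s`.", cluster_id))
  cval <- est$value[est$metric == "c"]
  mb <- est$value[est$metric == "c_model_based"]
  slope <- est$value[est$metric == "cal_slope"]
  delta <- cval - mb
  label <- if (is.na(delta)) {
    "undefined"
  } else if (abs(delta) <= 0.02) {
    "no case-mix contribution"
  } else if (delta < 0) {
    "case-mix-driven decrease"
  } else {
    "miscalibration-consistent"
  }
  structure(
    list(cluster_id = cluster_id, estimates = est, delta = delta,
         case_mix_label = label, cal_slope = slope),
    class = "single_study_view"
  )
}

#' @export
print.single_study_view <- function(x, ...) {
  cat(sprintf("External validation view: cluster `%s`\n", x$cluster_id))
  print(mutate(x$estimates, across(c("value", "se", "ci_low", "ci_high"),
                                   ~ round(.x, 3))))
  cat(sprintf("  case-mix decomposition delta = %.3f (%s)\n",
              x$delta, x$case_mix_label))
  invisible(x)
}
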