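# Random-effects meta-analysis of per-cluster performance estimates.
# c-statistics are pooled on the logit scale (delta-method SEs); calibration
# intercepts and slopes on the identity scale. Between-cluster variance by
# REML (default) or DerSimonian-Laird; Cochran's Q always uses fixed-effect
# weights, and I^2 = max(0, (Q - df)/Q) * 100.

#' Random-effects pooling of performance estimates
#'
#' Pools per-cluster estimates with inverse-variance random-effects weights
#' `1 / (se_i^2 + tau^2)`. `tau^2` is estimated by REML (default) or the
#' DerSimonian-Laird moment estimator. For `transform = "logit"` the
#' estimates are logit-transformed first with delta-method standard errors
#' `se / (est * (1 - est))` (the convention for c-statistics), and the pooled
#' mean and CI are back-transformed.
#'
#' @param data Data frame of per-cluster estimates, or a bare numeric vector
#'   of estimates (then `se` must be the vector of standard errors).
#' @param estimate,se Column names in `data` (defaults `"value"`, `"se"`),
#'   or numeric vectors when `data` is a vector.
#' @param transform `"logit"` (for c-statistics) or `"identity"`.
#' @param method `"REML"` (default) or `"DL"`.
#' @param labels Optional column name (or character vector) of cluster labels.
#' @param se_scale `"natural"` (default: `se` accompanies the untransformed
#'   estimate and is delta-transformed along with it) or `"transformed"`
#'   (`se` is already on the transformed scale, e.g. reconstructed from a CI
#'   whose bounds were logit-transformed first).
#' @param ci `"wald"` (default) or `"hartung-knapp"` (t-based small-sample
#'   adjustment of the pooled CI).
#' @return An object of class `meta_result`: pooled mean (back-transformed),
#'   95% CI, `tau2`, Cochran's `Q`, `df`, `i2` (percent), the transform and
#'   method used, and the per-cluster inputs. Inspect with [tidy()],
#'   [glance()], or [forest_data()].
#' @examples
#' meta_pool(c(0, 2), se = c(1, 1), transform = "identity", method = "DL")
#' @export
meta_pool <- function(data, estimate = "value", se = "se",
                      transform = c("logit", "identity"),
                      method = c("REML", "DL"), labels = NULL,
                      se_scale = c("natural", "transformed"),
                      ci = c("wald", "hartung-knapp")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  se_scale <- match.arg(se_scale)
  ci <- match.arg(ci)
  if (is.data.frame(data)) {
    est <- if (is.numeric(estimate)) estimate else data[[estimate]]
    ses <- if (is.numeric(se)) se else data[[se]]
    labs <- if (!is.null(labels) && is.character(labels) && length(labels) == 1 &&
                labels %in% names(data)) {
      as.character(data[[labels]])
    } else if ("cluster_id" %in% names(data)) {
      as.character(data$cluster_id)
    } else {
      NULL
    }
  } else {
    est <- as.numeric(data)
    ses <- as.numeric(se)
    labs <- if (!is.null(labels)) as.character(labels) else NULL
  }
  if (length(est) != length(ses)) abort("Estimates and SEs must have equal length.")
  if (length(est) < 2) abort("Need at least two estimates to pool.")
  if (any(!is.finite(ses)) || any(ses <= 0)) abort("All SEs must be positive and finite.")
  if (is.null(labs)) labs <- paste0("cluster_", seq_along(est))
  if (transform == "logit") {
    if (any(est <= 0 | est >= 1)) {
      abort("Logit pooling needs estimates strictly inside (0, 1).")
    }
    theta <- logit(est)
    se_t <- if (se_scale == "transformed") ses else ses / (est * (1 - est))
  } else {
    theta <- est
    se_t <- ses
  }
  k <- length(theta)
  v <- se_t^2
  w_fe <- 1 / v
  mu_fe <- sum(w_fe * theta) / sum(w_fe)
  Q <- sum(w_fe * (theta - mu_fe)^2)
  df <- k - 1
  i2 <- i_squared(Q, df)
  tau2 <- switch(method,
    DL = max(0, (Q - df) / (sum(w_fe) - sum(w_fe^2) / sum(w_fe))),
    REML = reml_tau2(theta, v)
  )
  w_re <- 1 / (v + tau2)
  mu <- sum(w_re * theta) / sum(w_re)
  se_mu <- sqrt(1 / sum(w_re))
  if (ci == "hartung-knapp") {
    se_hk <- sqrt(sum(w_re * (theta - mu)^2) / ((k - 1) * sum(w_re)))
    se_mu <- max(se_hk, se_mu) # truncated HK variant: never below Wald
    ci_t <- mu + c(-1, 1) * stats::qt(0.975, df) * se_mu
  } else {
    ci_t <- wald_ci(mu, se_mu)
  }
  back <- if (transform == "logit") expit else identity
  structure(
    list(
      pooled = back(mu), ci_low = back(ci_t[1]), ci_high = back(ci_t[2]),
      mu_transformed = mu, se_transformed = se_mu,
      tau2 = tau2, Q = Q, df = df, i2 = i2,
      transform = transform, method = method,
      inputs = tibble(cluster_id = labs, estimate = est, se = ses,
                      theta = theta, se_theta = se_t)
    ),
    class = "meta_result"
  )
}

# Restricted maximum likelihood for the between-cluster variance of a
# random-effects mean model with known within-cluster variances v_i.
reml_tau2 <- function(theta, v) {
  nll <- function(tau2) {
    wi <- 1 / (v + tau2)
    mu <- sum(wi * theta) / sum(wi)
    0.5 * (sum(log(v + tau2)) + log(sum(wi)) + sum(wi * (theta - mu)^2))
  }
  upper <- max(var(theta) * 10, max(v) * 10, 1e-3)
  opt <- optimize(nll, c(0, upper), tol = 1e-10)
  # the boundary tau2 = 0 is a valid REML solution; keep whichever is better
  if (nll(0) <= opt$objective + 1e-12) 0 else opt$minimum
}

#' Higgins' I-squared heterogeneity statistic
#'
#' Percentage of the total variability in the per-cluster estimates that is
#' attributable to between-cluster heterogeneity rather than sampling error:
#' `max(0, (Q - df) / Q) * 100`.
#'
#' @param Q Cochran's Q (non-negative).
#' @param df Degrees of freedom, `k - 1` (at least 1).
#' @return I-squared in percent, in `[0, 100]`.
#' @examples
#' i_squared(2, 1) # 50
#' @export
i_squared <- function(Q, df) {
  if (df < 1) abort("`df` must be at least 1.")
  if (Q < 0) abort("`Q` must be non-negative.")
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Forest-plot data for a pooled result
#'
#' @param meta A [meta_pool()] result.
#' @param labels Optional character labels overriding the stored cluster ids.
#' @return Tibble with one row per cluster plus a pooled summary row
#'   (`type = "pooled"`) and the heterogeneity statistics repeated on the
#'   pooled row.
#' @export
forest_data <- function(meta, labels = NULL) {
  stopifnot(inherits(meta, "meta_result"))
  k <- nrow(meta$inputs)
  if (!is.null(labels)) {
    if (length(labels) && length(labels) != k) {
      abort("`labels` must match the number of pooled inputs.")
    }
    if (!length(labels)) labels <- paste0("cluster_", seq_len(k))
  } else {
    labels <- meta$inputs$cluster_id
  }
  z <- qnorm(0.975)
  back <- if (meta$transform == "logit") expit else identity
  per <- tibble(
    label = labels, type = "cluster",
    estimate = meta$inputs$estimate,
    ci_low = back(meta$inputs$theta - z * meta$inputs$se_theta),
    ci_high = back(meta$inputs$theta + z * meta$inputs$se_theta),
    tau2 = NA_real_, i2 = NA_real_
  )
  pooled <- tibble(
    label = "Pooled", type = "pooled",
    estimate = meta$pooled, ci_low = meta$ci_low, ci_high = meta$ci_high,
    tau2 = meta$tau2, i2 = meta$i2
  )
  bind_rows(per, pooled)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects pooling (%s, %s scale) of %d clusters\n",
    x$method, x$transform, nrow(x$inputs)
  ))
  cat(sprintf("  pooled %.3f (95%% CI %.3f to %.3f)\n", x$pooled, x$ci_low, x$ci_high))
  cat(sprintf("  tau^2 %.4f; Q %.2f on %d df; I^2 %.0f%%\n", x$tau2, x$Q, x$df, x$i2))
  invisible(x)
}

#' @export
tidy.meta_result <- function(x, ...) forest_data(x)

#' @export
glance.meta_result <- function(x, ...) {
  tibble(
    pooled = x$pooled, ci_low = x$ci_low, ci_high = x$ci_high,
    tau2 = x$tau2, Q = x$Q, df = x$df, i2 = x$i2,
    transform = x$transform, method = x$method, k = nrow(x$inputs)
  )
}

#' Reconstruct a standard error from a printed 95% confidence interval
#'
#' `se = (upper - lower) / (2 * 1.96)` on the chosen scale. For the logit
#' scale the printed bounds are logit-transformed first (the reconstructed SE
#' then accompanies the logit of the estimate, so pass
#' `se_scale = "transformed"` to [meta_pool()]); asymmetry of the
#' back-transformed interval is expected.
#'
#' @param low,high Printed CI bounds.
#' @param transform `"identity"` or `"logit"`.
#' @return Numeric standard error(s).
#' @export
se_from_ci <- function(low, high, transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  if (transform == "logit") {
    (logit(high) - logit(low)) / (2 * qnorm(0.975))
  } else {
    (high - low) / (2 * qnorm(0.975))
  }
}
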