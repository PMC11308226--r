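# Discrimination and calibration measures. Harrell's c uses an O(n log n)
# rank formulation identical to exhaustive pair enumeration with ties
# counted 1/2; its SE is the DeLong rank-statistic variance. The model-based
# c-statistic is the concordance expected if outcomes truly followed the
# predicted probabilities; it depends only on the spread of the predictions
# (case-mix), not on observed outcomes, so the gap between Harrell's c and
# the model-based c isolates the case-mix contribution to a validation
# result.

#' Harrell's c-statistic for binary outcomes
#'
#' Probability that, for a random event/non-event pair, the event patient has
#' the higher predicted risk; tied predictions count 1/2. Computed from ranks
#' in O(n log n), exactly equal to exhaustive enumeration over all pairs. The
#' standard error is the DeLong rank-statistic variance; a percentile
#' bootstrap CI is available as an option.
#'
#' @param p Predicted probabilities (any monotone risk score works; c is
#'   rank-invariant).
#' @param y Binary 0/1 outcomes.
#' @param ci `"delong"` (default) or `"bootstrap"`.
#' @param boot_b Bootstrap resamples when `ci = "bootstrap"`.
#' @param seed Seed for the bootstrap CI.
#' @param cluster_id Optional label carried into the result row.
#' @return One-row tibble: `metric`, `value`, `se`, `ci_low`, `ci_high`, `n`,
#'   `n_events`, `cluster_id`.
#' @examples
#' harrell_c(c(0.2, 0.4, 0.4, 0.8), c(0, 1, 0, 1))$value # 0.875
#' @export
harrell_c <- function(p, y, ci = c("delong", "bootstrap"), boot_b = 2000,
                      seed = 1L, cluster_id = NA_character_) {
  ci <- match.arg(ci)
  stopifnot(length(p) == length(y))
  ok <- !is.na(p) & !is.na(y)
  p <- p[ok]
  y <- assert_binary_outcome(y[ok])
  cval <- c_from_ranks(p, y)
  n1 <- sum(y)
  n0 <- sum(1 - y)
  if (ci == "delong") {
    se <- delong_se(p, y)
    bounds <- wald_ci(cval, se)
  } else {
    se <- NA_real_
    boots <- with_seed(seed, map_dbl(seq_len(boot_b), function(b) {
      idx <- sample.int(length(p), replace = TRUE)
      if (sum(y[idx]) %in% c(0, length(idx))) return(NA_real_)
      c_from_ranks(p[idx], y[idx])
    }))
    boots <- boots[!is.na(boots)]
    se <- sd(boots)
    bounds <- unname(quantile(boots, c(0.025, 0.975)))
  }
  performance_estimate(
    "c", cval, se, max(bounds[1], 0), min(bounds[2], 1),
    n = n1 + n0, n_events = n1, cluster_id = cluster_id
  )
}

c_from_ranks <- function(p, y) {
  n1 <- sum(y)
  n0 <- length(y) - n1
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

delong_se <- function(p, y) {
  p1 <- p[y == 1]
  p0 <- p[y == 0]
  n1 <- length(p1)
  n0 <- length(p0)
  s0 <- sort(p0)
  s1 <- sort(p1)
  # V10_i: fraction of non-events below event i, ties 1/2
  less0 <- findInterval(p1, s0, left.open = TRUE)
  leq0 <- findInterval(p1, s0)
  v10 <- (less0 + 0.5 * (leq0 - less0)) / n0
  less1 <- findInterval(p0, s1, left.open = TRUE)
  leq1 <- findInterval(p0, s1)
  v01 <- 1 - (less1 + 0.5 * (leq1 - less1)) / n1
  if (n1 < 2 || n0 < 2) return(NA_real_)
  sqrt(var(v10) / n1 + var(v01) / n0)
}

#' Model-based c-statistic
#'
#' The concordance expected if outcomes truly followed the predicted
#' probabilities: over all pairs, the probability that the pair is concordant
#' given that it is discordant in outcome, with the pair's higher prediction
#' taken as the "event" side and exact ties contributing 1/2. The pairwise
#' sums reduce to sorted cumulative sums, so the exact value is computed in
#' O(n log n) at any n (identical to full pair enumeration, ties included).
#' It depends only on the distribution of predictions, making it the
#' case-mix reference against which Harrell's c is compared.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param cluster_id Optional label carried into the result row.
#' @return One-row tibble as in [harrell_c()] with metric `"c_model_based"`
#'   (no SE: the statistic is a deterministic function of the predictions).
#' @examples
#' model_based_c(c(0.2, 0.8))$value # 0.64 / 0.68
#' @export
model_based_c <- function(p, cluster_id = NA_character_) {
  p <- p[!is.na(p)]
  if (length(p) < 2) abort("Need at least two predictions for the model-based c.")
  assert_prob(p, "p")
  q <- sort(p)
  n <- length(q)
  j <- seq_len(n)
  cum <- c(0, cumsum(q))[j] # sum of q_i for i < j
  num <- sum(q * ((j - 1) - cum))
  s1 <- sum(q)
  s2 <- sum(q^2)
  denom <- (n - 1) * s1 - (s1^2 - s2)
  if (denom <= 0) {
    abort("Model-based c undefined: predictions admit no outcome-discordant pairs.")
  }
  performance_estimate("c_model_based", num / denom, n = n,
                       cluster_id = cluster_id)
}

#' Calibration intercept (calibration-in-the-large)
#'
#' Intercept of a logistic regression of the outcomes on the model's linear
#' predictor entered as a fixed offset. Zero means predictions agree with
#' observed risk on average; negative means the model overestimates risk.
#'
#' @param lp Linear predictor (log-odds) of the model being validated.
#' @param y Binary outcomes.
#' @param cluster_id Optional label.
#' @return One-row tibble as in [harrell_c()] with metric `"cal_intercept"`.
#' @export
calibration_intercept <- function(lp, y, cluster_id = NA_character_) {
  ok <- !is.na(lp) & !is.na(y)
  lp <- lp[ok]
  y <- assert_binary_outcome(y[ok])
  fit <- fit_logistic_raw(matrix(numeric(0), nrow = length(y), ncol = 0), y,
                          offset = lp)
  se <- sqrt(fit$vcov[1, 1])
  bounds <- wald_ci(fit$intercept, se)
  performance_estimate("cal_intercept", fit$intercept, se, bounds[1], bounds[2],
                       n = length(y), n_events = sum(y), cluster_id = cluster_id)
}

#' Calibration slope
#'
#' Slope of a logistic regression of the outcomes on the model's linear
#' predictor (with a free intercept). One is ideal; below one the predictions
#' are too extreme (the overfitting signature); above one, too moderate.
#'
#' @inheritParams calibration_intercept
#' @return One-row tibble as in [harrell_c()] with metric `"cal_slope"`.
#' @export
calibration_slope <- function(lp, y, cluster_id = NA_character_) {
  ok <- !is.na(lp) & !is.na(y)
  lp <- lp[ok]
  y <- assert_binary_outcome(y[ok])
  if (sd(lp) == 0) abort("Calibration slope undefined: constant linear predictor.")
  fit <- fit_logistic_raw(cbind(lp = lp), y)
  if (fit$separation) {
    abort("Calibration slope not estimable: outcomes separated by the linear predictor.")
  }
  b <- unname(fit$beta[["lp"]])
  se <- sqrt(fit$vcov[2, 2])
  bounds <- wald_ci(b, se)
  performance_estimate("cal_slope", b, se, bounds[1], bounds[2],
                       n = length(y), n_events = sum(y), cluster_id = cluster_id)
}

#' Calibration-curve data
#'
#' Grouped and smooth calibration-plot data: equal-count quantile bins of the
#' predicted probability (mean prediction vs observed event fraction per bin)
#' plus a smooth curve from a natural-spline logistic fit of the outcome on
#' the logit of the prediction (predictions clipped to `[0.001, 0.999]`
#' before the logit).
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param n_bins Number of quantile bins (default 10); collapses gracefully
#'   when predictions have few distinct values.
#' @return An object of class `calibration_curve`: list with tibbles `bins`
#'   (`bin`, `p_mean`, `obs_frac`, `n`) and `smooth` (`p`, `p_observed`),
#'   plus `n`. Plot with [ggplot2::autoplot()].
#' @export
calibration_curve <- function(p, y, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  ok <- !is.na(p) & !is.na(y)
  p <- p[ok]
  y <- as.numeric(y[ok])
  if (length(p) < n_bins) abort("Need at least `n_bins` observations.")
  breaks <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) {
    bins <- tibble(bin = 1L, p_mean = mean(p), obs_frac = mean(y),
                   n = length(p))
  } else {
    grp <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    bins <- tibble(p = p, y = y, bin = grp) |>
      group_by(.data$bin) |>
      summarise(p_mean = mean(.data$p), obs_frac = mean(.data$y), n = n(),
                .groups = "drop")
  }
  pc <- clamp01(p, 0.001)
  lp <- logit(pc)
  grid_p <- seq(min(pc), max(pc), length.out = 100)
  smooth <- tibble(p = grid_p, p_observed = NA_real_)
  if (length(unique(lp)) >= 4 && !(all(y == 0) || all(y == 1))) {
    df_s <- min(3, length(unique(lp)) - 1)
    sfit <- suppressWarnings(
      glm(y ~ splines::ns(lp, df = df_s), family = binomial())
    )
    smooth$p_observed <- as.numeric(
      predict(sfit, newdata = data.frame(lp = logit(grid_p)), type = "response")
    )
  } else {
    smooth$p_observed <- mean(y)
  }
  structure(list(bins = bins, smooth = smooth, n = length(p)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve:", nrow(x$bins), "bins over", x$n, "observations\n")
  print(x$bins)
  invisible(x)
}
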