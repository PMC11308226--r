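# Internal helpers shared across the package.

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

# Guard against overflow before exponentiation; |lp| beyond 700 would over-
# or underflow exp() in double precision.
clamp_lp <- function(lp) pmin(pmax(lp, -700), 700)

clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a distinct child seed from a base seed; stays well below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483587L)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", name))
  }
  invisible(x)
}

assert_binary_outcome <- function(y) {
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) {
    abort("Outcome vector must be binary 0/1.")
  }
  if (all(y == 1) || all(y == 0)) {
    abort("Outcome is degenerate: need at least one event and one non-event.")
  }
  y
}

wald_ci <- function(value, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(value - z * se, value + z * se)
}

# One-row tibble for a named performance metric (discrimination/calibration).
performance_estimate <- function(metric, value, se = NA_real_,
                                 ci_low = NA_real_, ci_high = NA_real_,
                                 n = NA_integer_, n_events = NA_integer_,
                                 cluster_id = NA_character_) {
  tibble(
    metric = metric, value = value, se = se,
    ci_low = ci_low, ci_high = ci_high,
    n = as.integer(n), n_events = as.integer(n_events),
    cluster_id = cluster_id
  )
}
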