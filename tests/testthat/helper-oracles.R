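# Independent oracles and small fixture builders used across tests.

# Exhaustive pair enumeration of Harrell's c, ties counted 1/2.
brute_force_c <- function(p, y) {
  pe <- p[y == 1]
  pn <- p[y == 0]
  num <- 0
  for (a in pe) {
    for (b in pn) {
      num <- num + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  num / (length(pe) * length(pn))
}

# O(n^2) pair enumeration of the model-based c-statistic.
brute_force_model_based_c <- function(p) {
  n <- length(p)
  num <- 0
  den <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      hi <- max(p[i], p[j])
      lo <- min(p[i], p[j])
      num <- num + if (p[i] == p[j]) {
        0.5 * (hi * (1 - lo) + lo * (1 - hi))
      } else {
        hi * (1 - lo)
      }
      den <- den + p[i] * (1 - p[j]) + p[j] * (1 - p[i])
    }
  }
  num / den
}

# Fast rank-form c for Monte-Carlo loops (its equality with brute force is
# established separately).
c_from_ranks_oracle <- function(p, y) {
  n1 <- sum(y)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * (length(y) - n1))
}

list_rbind_base <- function(x) do.call(rbind, x)

# All pairs outcome-concordant with probability 0 (degenerate denominator).
brute_force_is_degenerate <- function(p) {
  length(unique(p)) == 1 && all(p %in% c(0, 1))
}

# Small homogeneous multi-cluster config for engine tests.
toy_config <- function(k = 3, n = 150, seed = 7, tau_intercept = 0,
                       shifts = rep(0, k)) {
  specs <- lapply(seq_len(k), function(i) {
    cluster_spec(paste0("C", i), n, intercept_shift = shifts[i])
  })
  generator_config(specs, seed = seed, tau_intercept = tau_intercept)
}

toy_data <- function(...) generate_dataset(toy_config(...))

# Reduced two-predictor spec for speed-sensitive simulations.
small_spec <- function() model_spec(predictors = c("age", "wfns_high"))

predictor_cols_present <- function(d) {
  intersect(c("age", "wfns_high", "hypertension", "fisher", "size_large",
              "location", "y_favorable"), names(d))
}
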