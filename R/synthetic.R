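# Synthetic multi-study data generator. Emulates the structure of the SAHIT
# repository: 14 clusters of very different sizes, cluster-specific case-mix
# (WFNS severity, Fisher grade, aneurysm size and location, hypertension),
# cluster-specific outcome prevalence, between-study heterogeneity expressed
# as intercept shifts and a multiplier on the linear predictor, and
# block-missing predictors in some clusters.

aneurysm_locations <- function() {
  c("ACA", "ACOM", "ICA", "MCA", "PCOM", "Posterior")
}

predictor_columns <- function() {
  c("age", "wfns_high", "hypertension", "fisher", "size_large", "location")
}

#' Default generating coefficients for the synthetic repository
#'
#' Log-odds effects on *favorable* outcome used by the synthetic generator:
#' higher age, poor WFNS grade (IV-V), premorbid hypertension, higher Fisher
#' grade and large (>= 13 mm) aneurysms reduce the odds of favorable outcome;
#' location effects are modest. Values are chosen once as clinically plausible
#' magnitudes for aneurysmal subarachnoid hemorrhage.
#'
#' @return Named numeric vector of coefficients on the standard encoding
#'   (age linear per year; binary indicators; Fisher dummies vs grade 1;
#'   location dummies vs ACA).
#' @export
default_true_beta <- function() {
  c(
    age = -0.040,
    wfns_high = -1.30,
    hypertension = -0.30,
    fisher2 = -0.20, fisher3 = -0.50, fisher4 = -0.90,
    size_large = -0.50,
    locationACOM = 0.10, locationICA = 0.20, locationMCA = -0.10,
    locationPCOM = 0.20, locationPosterior = -0.30
  )
}

#' Specify one synthetic study cluster
#'
#' A `cluster_spec` describes the case-mix and heterogeneity of one study:
#' sample size, age distribution, prevalence of poor WFNS grade and
#' hypertension, Fisher-grade and location distributions, prevalence of large
#' aneurysms, a cluster intercept shift and a multiplier on the linear
#' predictor (the between-study heterogeneity), the outcome scale the study
#' records, and predictor columns that are entirely unrecorded in that study.
#'
#' @param cluster_id Study label.
#' @param n Number of patients (positive integer).
#' @param age_mean,age_sd Age distribution in years (truncated to 18--95 at
#'   generation time).
#' @param p_wfns_high,p_hypertension,p_size_large Prevalences in `[0, 1]`.
#' @param fisher_probs Length-4 probability vector over Fisher grades 1--4.
#' @param location_probs Length-6 probability vector over
#'   `r paste(aneurysm_locations(), collapse = ", ")`.
#' @param intercept_shift Cluster shift of the outcome-model intercept
#'   (log-odds units).
#' @param slope_multiplier Positive multiplier on the covariate part of the
#'   linear predictor; 1 means the common predictor effects hold exactly.
#' @param outcome_scale Scale the study records: `"GOS"`, `"eGOS"`, `"mRS"`.
#' @param missing_columns Character vector of predictor columns unrecorded
#'   (block-missing) in this cluster.
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(cluster_id, n, age_mean = 53, age_sd = 13,
                         p_wfns_high = 0.20, p_hypertension = 0.38,
                         fisher_probs = c(0.05, 0.21, 0.39, 0.35),
                         p_size_large = 0.16,
                         location_probs = c(0.20, 0.20, 0.20, 0.18, 0.09, 0.13),
                         intercept_shift = 0, slope_multiplier = 1,
                         outcome_scale = "GOS",
                         missing_columns = character()) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  assert_prob(c(p_wfns_high, p_hypertension, p_size_large),
              "p_wfns_high/p_hypertension/p_size_large")
  for (nm in c("fisher_probs", "location_probs")) {
    v <- get(nm)
    len <- if (nm == "fisher_probs") 4L else 6L
    if (length(v) != len || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      abort(sprintf("`%s` must be %d non-negative probabilities summing to 1.",
                    nm, len))
    }
  }
  if (!is.finite(slope_multiplier) || slope_multiplier <= 0) {
    abort("`slope_multiplier` must be positive.")
  }
  bad <- setdiff(missing_columns, predictor_columns())
  if (length(bad)) {
    abort(sprintf("Unknown `missing_columns`: %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      cluster_id = as.character(cluster_id), n = n,
      age_mean = age_mean, age_sd = age_sd,
      p_wfns_high = p_wfns_high, p_hypertension = p_hypertension,
      fisher_probs = as.numeric(fisher_probs),
      p_size_large = p_size_large,
      location_probs = as.numeric(location_probs),
      intercept_shift = intercept_shift,
      slope_multiplier = slope_multiplier,
      outcome_scale = outcome_scale,
      missing_columns = as.character(missing_columns)
    ),
    class = "cluster_spec"
  )
}

#' Configure the synthetic multi-study generator
#'
#' @param cluster_specs List of [cluster_spec()] objects.
#' @param true_beta Named coefficient vector on the standard encoding (see
#'   [default_true_beta()]).
#' @param true_intercept Common model intercept (log-odds of favorable outcome
#'   at the reference covariate pattern).
#' @param tau_intercept SD of additional random cluster intercept shifts
#'   (log-odds units); 0 disables.
#' @param tau_slope SD of additional random deviations of the slope
#'   multiplier around each cluster's `slope_multiplier`; 0 disables.
#' @param tau_beta Optional per-coefficient between-study heterogeneity (an
#'   extension beyond the shift-plus-multiplier mechanism): each cluster's
#'   coefficients are `true_beta * exp(N(0, tau_beta^2))`, a sign-preserving
#'   relative perturbation so effects on different scales stay plausible;
#'   0 disables.
#' @param seed Integer seed governing all randomness of [generate_dataset()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(cluster_specs, true_beta = default_true_beta(),
                             true_intercept = 3.6, tau_intercept = 0,
                             tau_slope = 0, tau_beta = 0, seed = 1L) {
  if (!length(cluster_specs) || !all(map_chr(cluster_specs, ~class(.x)[1]) == "cluster_spec")) {
    abort("`cluster_specs` must be a non-empty list of cluster_spec objects.")
  }
  if (tau_intercept < 0 || tau_slope < 0 || tau_beta < 0) {
    abort("`tau_intercept`, `tau_slope` and `tau_beta` must be non-negative.")
  }
  need <- names(default_true_beta())
  if (!setequal(names(true_beta), need)) {
    abort(sprintf("`true_beta` must be named with exactly: %s.",
                  paste(need, collapse = ", ")))
  }
  structure(
    list(
      cluster_specs = cluster_specs,
      true_beta = true_beta[need], true_intercept = true_intercept,
      tau_intercept = tau_intercept, tau_slope = tau_slope,
      tau_beta = tau_beta,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Linear predictor x'beta (no intercept) on the standard encoding, from the
# always-complete generating covariates.
true_linear_predictor <- function(covariates, beta) {
  lp <- beta[["age"]] * covariates$age +
    beta[["wfns_high"]] * covariates$wfns_high +
    beta[["hypertension"]] * covariates$hypertension +
    beta[["size_large"]] * covariates$size_large
  lp <- lp + c(0, beta[["fisher2"]], beta[["fisher3"]], beta[["fisher4"]])[covariates$fisher]
  loc_eff <- c(0, beta[["locationACOM"]], beta[["locationICA"]],
               beta[["locationMCA"]], beta[["locationPCOM"]],
               beta[["locationPosterior"]])
  lp + loc_eff[match(covariates$location, aneurysm_locations())]
}

draw_cluster_covariates <- function(spec) {
  n <- spec$n
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  # truncate by redraw; the tails clipped are tiny for realistic mean/SD
  for (i in 1:20) {
    out <- age < 18 | age > 95
    if (!any(out)) break
    age[out] <- rnorm(sum(out), spec$age_mean, spec$age_sd)
  }
  age <- pmin(pmax(age, 18), 95)
  tibble(
    cluster_id = spec$cluster_id,
    age = round(age, 1),
    wfns_high = rbinom(n, 1L, spec$p_wfns_high),
    hypertension = rbinom(n, 1L, spec$p_hypertension),
    fisher = sample.int(4L, n, replace = TRUE, prob = spec$fisher_probs),
    size_large = rbinom(n, 1L, spec$p_size_large),
    location = sample(aneurysm_locations(), n, replace = TRUE,
                      prob = spec$location_probs)
  )
}

# Map the binary outcome back to a raw score so dichotomization reproduces y
# exactly: a monotone latent draw picks the level within the favorable or
# unfavorable band of the cluster's scale.
draw_raw_score <- function(y, scale, u) {
  pick <- function(levels, probs, u) {
    levels[findInterval(u, cumsum(probs / sum(probs)), left.open = TRUE) + 1L]
  }
  switch(scale,
    GOS = ifelse(y == 1L, pick(4:5, c(0.45, 0.55), u), pick(1:3, c(0.35, 0.25, 0.40), u)),
    eGOS = ifelse(y == 1L, pick(4:8, c(0.15, 0.20, 0.20, 0.20, 0.25), u),
                  pick(1:3, c(0.35, 0.25, 0.40), u)),
    mRS = ifelse(y == 1L, pick(0:3, c(0.25, 0.30, 0.25, 0.20), u),
                 pick(4:6, c(0.40, 0.25, 0.35), u)),
    abort(sprintf("Unknown outcome scale `%s`.", scale))
  )
}

#' Generate a synthetic clustered dataset
#'
#' Draws one row per patient from the configured multi-study mechanism:
#' covariates from each cluster's case-mix, outcome
#' `y ~ Bernoulli(plogis(intercept + shift + multiplier * x'beta))` with the
#' cluster's intercept shift and slope multiplier (plus random heterogeneity
#' when `tau_intercept`/`tau_slope` are positive), a raw outcome-scale score
#' consistent with the binary outcome, and whole-column (block) missingness
#' for each cluster's unrecorded predictors. The generating configuration and
#' the realized per-cluster parameters are attached as the `"generator"`
#' attribute for parameter-recovery checks.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `cluster_id`, the six predictors,
#'   `outcome_scale`, `outcome_raw`, `y_favorable`.
#' @examples
#' cfg <- generator_config(list(cluster_spec("A", 200), cluster_spec("B", 200)),
#'                         seed = 7)
#' d <- generate_dataset(cfg)
#' table(d$cluster_id)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a generator_config object.")
  }
  with_seed(config$seed, {
    realized <- list()
    rows <- map(config$cluster_specs, function(spec) {
      cov <- draw_cluster_covariates(spec)
      shift_rand <- if (config$tau_intercept > 0) rnorm(1, 0, config$tau_intercept) else 0
      mult_rand <- if (config$tau_slope > 0) rnorm(1, 0, config$tau_slope) else 0
      mult <- max(spec$slope_multiplier + mult_rand, 0.05)
      icpt <- config$true_intercept + spec$intercept_shift + shift_rand
      beta_k <- config$true_beta
      if (config$tau_beta > 0) {
        beta_k <- beta_k * exp(rnorm(length(beta_k), 0, config$tau_beta))
      }
      lp <- icpt + mult * true_linear_predictor(cov, beta_k)
      y <- rbinom(spec$n, 1L, expit(clamp_lp(lp)))
      raw <- draw_raw_score(y, spec$outcome_scale, runif(spec$n))
      realized[[spec$cluster_id]] <<- tibble(
        cluster_id = spec$cluster_id, intercept = icpt, slope_multiplier = mult
      )
      out <- cov
      out$outcome_scale <- spec$outcome_scale
      out$outcome_raw <- as.integer(raw)
      out$y_favorable <- y
      for (col in spec$missing_columns) out[[col]] <- out[[col]][NA]
      out
    })
    data <- list_rbind(rows)
    attr(data, "generator") <- list(
      config = config,
      realized = list_rbind(unname(realized))
    )
    data
  })
}

#' Inject item-level missing-at-random missingness
#'
#' Adds item-level missingness to chosen columns with a logistic
#' missing-at-random mechanism: each row's probability of being set missing
#' depends on observed age and WFNS grade, with the mechanism's intercept
#' calibrated so the marginal missingness rate matches the requested rate.
#' Block-missingness (whole columns per cluster) is a separate mechanism
#' handled by the generator.
#'
#' @param data A clustered dataset tibble.
#' @param rates Named numeric vector of target missingness rates in `[0, 1]`;
#'   names are predictor columns.
#' @param seed Integer seed.
#' @return The dataset with additional `NA`s; rate 0 leaves a column
#'   untouched, rate 1 blanks it entirely.
#' @export
inject_mar_missingness <- function(data, rates, seed = 1L) {
  assert_prob(rates, "rates")
  bad <- setdiff(names(rates), names(data))
  if (length(bad)) abort(sprintf("Unknown columns in `rates`: %s.",
                                 paste(bad, collapse = ", ")))
  data <- as_tibble(data)
  z_age <- if ("age" %in% names(data)) as.numeric(scale(ifelse(is.na(data$age), mean(data$age, na.rm = TRUE), data$age))) else numeric(nrow(data))
  z_wfns <- if ("wfns_high" %in% names(data)) ifelse(is.na(data$wfns_high), 0, data$wfns_high) else numeric(nrow(data))
  driver <- 0.4 * z_age + 0.4 * z_wfns
  with_seed(seed, {
    for (col in names(rates)) {
      r <- rates[[col]]
      if (r <= 0) next
      if (r >= 1) {
        data[[col]] <- data[[col]][NA]
        next
      }
      a <- uniroot_scalar(function(a) mean(expit(a + driver)) - r, c(-30, 30))
      miss <- runif(nrow(data)) < expit(a + driver)
      data[[col]][miss] <- NA
    }
  })
  data
}

uniroot_scalar <- function(f, interval) {
  stats::uniroot(f, interval, tol = 1e-10)$root
}

# Table of per-study marginals for the SAHIT-like preset. Proportions are
# study-level counts normalised over their reported denominators; NA marks a
# predictor the study did not record (block-missing), for which the
# full-cohort marginal is used as the generating distribution.
sahit_marginals <- function() {
  loc <- function(...) {
    v <- c(...)
    v / sum(v)
  }
  full_fisher <- c(493, 2050, 3762, 3440) / 9745
  full_loc <- loc(1952, 2020, 1962, 1840, 899, 1307)
  tibble::tribble(
    ~cluster_id, ~n, ~age_mean, ~age_sd, ~p_wfns, ~p_hyp, ~fisher, ~p_size, ~location, ~p_fav, ~scale, ~missing,
    "Conscious-1", 413L, 51, 11, 100/413, 172/413, loc(4, 85, 35, 284), NA, loc(22, 160, 46, 69, 66, 50), 325/413, "GOS", "size_large",
    "Chicago", 75L, 51, 16, 31/75, 38/75, loc(5, 12, 58, 0.5), NA, NULL, 44/73, "mRS", "size_large,location",
    "EPO/Statin", 160L, 55, 13, 48/160, NA, loc(11, 8, 17, 124), NA, loc(0.5, 51, 8, 37, 32, 15), 101/160, "mRS", "hypertension,size_large",
    "HHU", 60L, 56, 10, 47/60, NA, loc(0.5, 2, 9, 49), 4/60, loc(2, 18, 3, 21, 8, 8), 49/60, "eGOS", "hypertension",
    "IHAST", 1000L, 52, 13, 0, 398/1000, loc(54, 342, 474, 130), 118/996, loc(37, 354, 81, 206, 237, 84), 871/1000, "GOS", "",
    "IMASH", 327L, 57, 13, 118/327, 198/327, loc(2, 24, 262, 39), NA, NULL, 213/327, "mRS", "size_large,location",
    "ISAT", 2143L, 52, 12, 94/2112, NA, loc(114, 360, 902, 753), 65/2143, loc(536, 549, 492, 303, 0.5, 263), 1790/2068, "mRS", "hypertension",
    "Leeds", 117L, 57, 9, 18/105, NA, loc(3, 45, 39, 17), NA, NULL, 87/109, "eGOS", "hypertension,size_large,location",
    "MAPS", 228L, 52, 13, NA, 85/226, NULL, 14/228, loc(13, 80, 36, 22, 54, 23), 190/207, "mRS", "wfns_high,fisher",
    "MASH1/2", 1484L, 56, 13, 345/1483, 57/207, loc(1, 22, 43, 141), 16/159, loc(6, 184, 38, 89, 79, 61), 1083/1481, "GOS", "",
    "D-SAT", 439L, 51, 15, NA, 162/439, loc(19, 79, 182, 32), 104/435, loc(14, 119, 46, 88, 87, 83), 333/435, "mRS", "wfns_high",
    "SHOP", 1500L, 55, 15, 577/1431, 696/1441, loc(206, 315, 695, 218), 156/1176, loc(63, 332, 134, 209, 268, 218), 755/1151, "mRS", "",
    "Tirilazad", 3552L, 52, 13, 800/3551, 1147/3481, loc(74, 756, 1046, 1653), 928/3522, loc(1256, 0.5, 1046, 711, 0.5, 475), 2861/3498, "GOS", "",
    "Utrecht", 433L, 55, 13, 97/427, NA, NULL, NA, loc(3, 173, 32, 85, 68, 28), 381/433, "mRS", "hypertension,fisher,size_large"
  ) |>
    mutate(
      p_hyp = ifelse(is.na(.data$p_hyp), 2884 / 7609, .data$p_hyp),
      p_wfns = ifelse(is.na(.data$p_wfns), 2275 / 11144, .data$p_wfns),
      p_size = ifelse(is.na(.data$p_size), 1405 / 8719, .data$p_size),
      fisher = map(.data$fisher, ~ .x %||% full_fisher),
      location = map(.data$location, ~ .x %||% full_loc)
    )
}

#' SAHIT-like generator preset
#'
#' Builds a 14-cluster [generator_config()] mirroring the published structure
#' of the SAHIT data repository: the 14 study sizes (total n = 11,931),
#' per-study age distributions, WFNS IV-V prevalence spanning 0--0.78,
#' Fisher-grade, aneurysm-size and location distributions, per-study
#' favorable-outcome targets spanning 0.60--0.92, the outcome scale each study
#' records, and block-missing predictors where a study did not record a
#' variable. Each cluster's intercept shift is calibrated by root-finding so
#' the expected favorable-outcome fraction under that cluster's case-mix
#' matches its target.
#'
#' @param seed Seed stored in the returned config (governs
#'   [generate_dataset()], not the calibration, which is deterministic).
#' @return A `generator_config` with 14 cluster specs; the per-cluster target
#'   prevalences are attached as attribute `"targets"`.
#' @export
sahit_like_preset <- function(seed = 1L) {
  marg <- sahit_marginals()
  beta <- default_true_beta()
  true_intercept <- 3.6
  specs <- map(seq_len(nrow(marg)), function(i) {
    row <- marg[i, ]
    spec <- cluster_spec(
      cluster_id = row$cluster_id, n = row$n,
      age_mean = row$age_mean, age_sd = row$age_sd,
      p_wfns_high = row$p_wfns, p_hypertension = row$p_hyp,
      fisher_probs = row$fisher[[1]], p_size_large = row$p_size,
      location_probs = row$location[[1]],
      outcome_scale = row$scale,
      missing_columns = strsplit(row$missing, ",")[[1]]
    )
    # deterministic calibration sample, independent of the user's seed
    cov <- with_seed(derive_seed(971L, i), {
      spec_big <- spec
      spec_big$n <- 4000L
      draw_cluster_covariates(spec_big)
    })
    lp0 <- true_linear_predictor(cov, beta)
    spec$intercept_shift <- uniroot_scalar(
      function(d) mean(expit(true_intercept + d + lp0)) - row$p_fav, c(-10, 10)
    )
    spec
  })
  cfg <- generator_config(specs, true_beta = beta,
                          true_intercept = true_intercept, seed = seed)
  attr(cfg, "targets") <- marg |> select("cluster_id", "n", p_favorable = "p_fav")
  cfg
}
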