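# Membership model: a logistic regression predicting whether a patient
# belongs to the development (0) or validation (1) sample, fitted on all
# predictors plus the dichotomized outcome. Its apparent c-statistic
# measures how distinguishable -- how unrelated -- the two samples are: 0.5
# means exchangeable samples, 1 means disjoint. Combined with the validation
# c-statistic it gives a gross readout of generalizability (related samples)
# versus transportability (distinct samples).

#' Membership-model c-statistic for a development/validation pair
#'
#' Fits the membership model on the combined sample (complete cases on the
#' modeled columns) and returns its apparent Harrell's c. Complete separation
#' of the two samples is not an error: it is the "fully distinct" extreme, so
#' c is reported as 1 with a separation flag.
#'
#' @param dev,val Data frames: development and validation samples sharing the
#'   predictor and outcome columns.
#' @param spec A [model_spec()]; its predictors plus its outcome enter the
#'   membership model.
#' @return An object of class `membership_result`: `c_membership`, `se`,
#'   `ci_low`, `ci_high`, `separation`, `n_dev`, `n_val`, and the
#'   `relatedness` label (`related` < 0.70 <= `moderately distinct` < 0.80 <=
#'   `distinct`).
#' @export
membership_c <- function(dev, val, spec = model_spec()) {
  if (!nrow(dev) || !nrow(val)) abort("Both samples must be non-empty.")
  cols <- c(spec$predictors, spec$outcome)
  miss <- setdiff(cols, intersect(names(dev), names(val)))
  if (length(miss)) {
    abort(sprintf("Shared columns missing: %s.", paste(miss, collapse = ", ")))
  }
  combined <- bind_rows(
    mutate(as_tibble(dev)[cols], .member = 0L),
    mutate(as_tibble(val)[cols], .member = 1L)
  )
  combined <- combined[complete.cases(combined[cols]), ]
  if (!nrow(combined) || !all(c(0L, 1L) %in% combined$.member)) {
    abort("No complete-case rows left in one of the samples.")
  }
  # outcome enters as a predictor of membership
  mspec <- model_spec(outcome = ".member", predictors = spec$predictors)
  X <- cbind(design_matrix(combined, mspec),
             outcome = as.numeric(combined[[spec$outcome]]))
  fit <- fit_logistic_raw(X, combined$.member)
  p <- expit(clamp_lp(fit$intercept + drop(X %*% fit$beta)))
  cc <- harrell_c(p, combined$.member)
  if (fit$separation) {
    cc$value <- 1
    cc$ci_low <- cc$ci_high <- 1
    cc$se <- 0
  }
  structure(
    list(
      c_membership = cc$value, se = cc$se,
      ci_low = cc$ci_low, ci_high = cc$ci_high,
      separation = fit$separation,
      n_dev = sum(combined$.member == 0L), n_val = sum(combined$.member == 1L),
      relatedness = relatedness_label(cc$value)
    ),
    class = "membership_result"
  )
}

relatedness_label <- function(c_membership) {
  dplyr::case_when(
    is.na(c_membership) ~ NA_character_,
    c_membership < 0.70 ~ "related",
    c_membership < 0.80 ~ "moderately distinct",
    TRUE ~ "distinct"
  )
}

#' @export
print.membership_result <- function(x, ...) {
  cat(sprintf(
    "Membership model: c = %.3f (%s)%s; n_dev = %d, n_val = %d\n",
    x$c_membership, x$relatedness,
    if (x$separation) " [complete separation]" else "",
    x$n_dev, x$n_val
  ))
  invisible(x)
}

#' Membership c-statistic for every leave-one-out cluster
#'
#' Convenience wrapper running [membership_c()] with each cluster in turn as
#' the validation sample against all remaining clusters as the development
#' sample.
#'
#' @param data Clustered dataset with a `cluster_id` column.
#' @param spec A [model_spec()].
#' @return Tibble with one row per cluster: `cluster_id`, `c_membership`,
#'   `se`, `ci_low`, `ci_high`, `separation`, `relatedness`.
#' @export
membership_by_cluster <- function(data, spec = model_spec()) {
  data <- as_tibble(data)
  clusters <- unique(as.character(data$cluster_id))
  list_rbind(map(clusters, function(k) {
    res <- membership_c(data[data$cluster_id != k, ], data[data$cluster_id == k, ],
                        spec)
    tibble(
      cluster_id = k, c_membership = res$c_membership, se = res$se,
      ci_low = res$ci_low, ci_high = res$ci_high,
      separation = res$separation, relatedness = res$relatedness
    )
  }))
}

#' Joint transportability report
#'
#' Combines per-cluster membership c-statistics (relatedness) with the
#' validation c-statistics into the joint transportability reading: for
#' related samples the validation performance speaks to *generalizability*,
#' for distinct samples to *transportability*. Validation discrimination at
#' or above 0.70 is read as satisfactory (a package convention).
#'
#' @param data Data frame with one row per cluster.
#' @param c_membership,c_validation Column names (defaults `"c_membership"`,
#'   `"c_validation"`).
#' @param labels Column of cluster labels (default `"cluster_id"`).
#' @param c_satisfactory Threshold for satisfactory validation
#'   discrimination.
#' @return Tibble with `cluster_id`, both c's, `relatedness`, and the joint
#'   `transportability` label.
#' @export
transportability_report <- function(data, c_membership = "c_membership",
                                    c_validation = "c_validation",
                                    labels = "cluster_id",
                                    c_satisfactory = 0.70) {
  if (!nrow(data)) abort("Need at least one cluster.")
  cm <- data[[c_membership]]
  cv <- data[[c_validation]]
  labs <- if (labels %in% names(data)) as.character(data[[labels]]) else paste0("cluster_", seq_along(cm))
  related <- cm < 0.70
  good <- cv >= c_satisfactory
  tibble(
    cluster_id = labs,
    c_membership = cm,
    c_validation = cv,
    relatedness = relatedness_label(cm),
    transportability = dplyr::case_when(
      is.na(cm) | is.na(cv) ~ NA_character_,
      related & good ~ "good generalizability",
      related & !good ~ "poor generalizability",
      !related & good ~ "good transportability",
      TRUE ~ "poor transportability"
    )
  )
}
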