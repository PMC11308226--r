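# Logistic-regression core: the fixed predictor encoding of the outcome
# model, ML fitting via IRLS (stats::glm), prediction, and JSON
# (de)serialization so externally published coefficient vectors can be
# validated without refitting.

#' Standard outcome-model specification
#'
#' The fixed predictor set and encoding of the subarachnoid-hemorrhage outcome
#' model: age (linear, per year), WFNS grade IV-V (binary), premorbid
#' hypertension (binary), CT Fisher grade (categorical, reference grade 1),
#' aneurysm size >= 13 mm (binary), aneurysm location (categorical, reference
#' ACA). Reference levels are fixed so the design row has a reproducible
#' layout.
#'
#' @param outcome Name of the binary outcome column (favorable = 1).
#' @param predictors Optional character subset of the six standard predictors.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = "y_favorable", predictors = predictor_columns()) {
  bad <- setdiff(predictors, predictor_columns())
  if (length(bad)) abort(sprintf("Unknown predictors: %s.", paste(bad, collapse = ", ")))
  structure(
    list(outcome = outcome, predictors = predictors,
         fisher_levels = as.character(1:4), location_levels = aneurysm_locations()),
    class = "model_spec"
  )
}

# Design matrix (without intercept column) on the spec's encoding.
design_matrix <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(spec$predictors, names(data))
  if (length(miss)) {
    abort(sprintf("Dataset lacks predictor column(s): %s.", paste(miss, collapse = ", ")))
  }
  df <- as_tibble(data)[spec$predictors]
  if ("fisher" %in% names(df)) {
    bad <- !is.na(df$fisher) & !df$fisher %in% c(1:4, spec$fisher_levels)
    if (any(bad)) abort("`fisher` outside grades 1..4.")
    df$fisher <- factor(as.character(df$fisher), levels = spec$fisher_levels)
  }
  if ("location" %in% names(df)) {
    bad <- !is.na(df$location) & !df$location %in% spec$location_levels
    if (any(bad)) {
      abort(sprintf("Unknown aneurysm location(s): %s.",
                    paste(unique(df$location[bad]), collapse = ", ")))
    }
    df$location <- factor(df$location, levels = spec$location_levels)
  }
  if (anyNA(df)) {
    abort("Design rows must be complete; impute missing predictors upstream.")
  }
  f <- as.formula(paste("~", paste(spec$predictors, collapse = " + ")))
  X <- model.matrix(f, data = df)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

#' Fit the logistic outcome model
#'
#' Maximum-likelihood logistic regression of a binary outcome on the spec's
#' encoding, by iteratively reweighted least squares, with an optional fixed
#' per-row offset (log-odds) as needed for calibration intercepts. Degenerate
#' outcomes error; (quasi-)complete separation is detected from non-converged
#' or exploding coefficients and reported rather than silently smoothed away.
#'
#' @param data Data frame with complete predictor rows and the 0/1 outcome.
#' @param spec A [model_spec()].
#' @param offset Optional numeric vector of per-row fixed log-odds offsets.
#' @param on_separation `"error"` (default) or `"warn"`.
#' @return An object of class `fitted_model` with elements `spec`,
#'   `intercept`, `beta`, `converged`, `separation`, `n`, `n_events`.
#' @export
fit_outcome_model <- function(data, spec = model_spec(), offset = NULL,
                              on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  y <- assert_binary_outcome(data[[spec$outcome]])
  X <- design_matrix(data, spec)
  fit <- fit_logistic_raw(X, y, offset)
  if (fit$separation) {
    msg <- "Detected (quasi-)complete separation: monotone likelihood, coefficients diverge."
    if (on_separation == "error") abort(msg) else warn(msg)
  }
  structure(
    list(
      spec = spec, intercept = fit$intercept, beta = fit$beta,
      converged = fit$converged, separation = fit$separation,
      n = length(y), n_events = sum(y), vcov = fit$vcov
    ),
    class = "fitted_model"
  )
}

# Bare-matrix logistic fit used in hot loops (bootstrap, cross-validation).
fit_logistic_raw <- function(X, y, offset = NULL) {
  Xi <- cbind(`(Intercept)` = 1, X)
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  fit <- suppressWarnings(glm.fit(Xi, y, family = binomial(),
                                  offset = offset, control = ctrl))
  cf <- coef(fit)
  vc <- tryCatch({
    w <- fit$weights
    XtWX <- crossprod(Xi * sqrt(w))
    solve(XtWX)
  }, error = function(e) matrix(NA_real_, ncol(Xi), ncol(Xi)))
  se_cf <- suppressWarnings(sqrt(diag(vc)))
  # monotone likelihood: coefficients drift large while their Wald SEs
  # explode (or IRLS fails to converge at extreme values)
  big <- abs(cf) > 15
  separation <- (!fit$converged && any(big, na.rm = TRUE)) ||
    any(abs(cf) > 30, na.rm = TRUE) ||
    any(big & (is.na(se_cf) | se_cf > 50 * pmax(abs(cf), 1)), na.rm = TRUE)
  list(
    intercept = unname(cf[1]),
    beta = cf[-1],
    converged = fit$converged,
    separation = separation,
    vcov = vc
  )
}

#' Predicted risk and linear predictor
#'
#' @param model A [fit_outcome_model()] result (or deserialized model).
#' @param data Data frame of complete predictor rows.
#' @param offset Optional fixed per-row log-odds offset.
#' @return A tibble with columns `lp` (linear predictor, log-odds) and `p`
#'   (predicted probability, machine-representable in (0,1)).
#' @export
predict_risk <- function(model, data, offset = NULL) {
  stopifnot(inherits(model, "fitted_model"))
  X <- design_matrix(data, model$spec)
  if (!identical(colnames(X), names(model$beta))) {
    abort("Design columns do not match the model's coefficient vector.")
  }
  lp <- model$intercept + drop(X %*% model$beta)
  if (!is.null(offset)) lp <- lp + offset
  lp <- unname(lp)
  tibble(lp = lp, p = expit(clamp_lp(lp)))
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("Logistic outcome model (", x$n, " patients, ", x$n_events, " favorable)\n",
      sep = "")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  print(round(x$beta, 4))
  if (x$separation) cat("  ! separation detected\n")
  invisible(x)
}

#' @export
tidy.fitted_model <- function(x, ...) {
  cf <- c(`(Intercept)` = x$intercept, x$beta)
  se <- if (is.null(x$vcov)) rep(NA_real_, length(cf)) else sqrt(diag(x$vcov))
  tibble(
    term = names(cf), estimate = unname(cf), std.error = unname(se),
    statistic = unname(cf / se),
    p.value = 2 * pnorm(-abs(unname(cf / se)))
  )
}

#' @export
glance.fitted_model <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, converged = x$converged,
         separation = x$separation)
}

#' Write / read a fitted model as JSON
#'
#' Serializes the model spec and coefficients so an externally developed
#' model can be validated on new clusters without refitting.
#'
#' @param model A `fitted_model`.
#' @param path File path for the JSON.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns a `fitted_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  jsonlite::write_json(
    list(
      outcome = model$spec$outcome,
      predictors = model$spec$predictors,
      intercept = model$intercept,
      beta = as.list(model$beta),
      n = model$n, n_events = model$n_events
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(outcome = obj$outcome, predictors = obj$predictors)
  structure(
    list(
      spec = spec, intercept = obj$intercept,
      beta = unlist(obj$beta), converged = TRUE, separation = FALSE,
      n = obj$n %||% NA_integer_, n_events = obj$n_events %||% NA_integer_,
      vcov = NULL
    ),
    class = "fitted_model"
  )
}
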