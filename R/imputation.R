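# Chained-equations multiple imputation for item- and block-missing
# predictors. Imputation runs once over the pooled repository (all clusters
# jointly), so block-missing columns in a cluster borrow the other clusters'
# predictor-outcome relationships; the outcome is part of every conditional
# model. Conditional models: Bayesian-draw linear regression for age
# (predictive-mean matching optional), logistic regression with a posterior
# coefficient draw for binary variables, and multinomial regression for
# Fisher grade and location (class drawn from fitted probabilities).

#' Multiple imputation by chained equations
#'
#' @param data Clustered dataset tibble.
#' @param m Number of completed datasets (default 5).
#' @param iterations Chained-equation cycles per imputation (default 10).
#' @param seed Integer seed; equal seeds give identical imputation sets.
#' @param columns Columns eligible for imputation (default: the six standard
#'   predictors plus `y_favorable` where present).
#' @param pmm_age Use predictive-mean matching for age instead of parametric
#'   draws.
#' @return An object of class `imputation_set`: `m`, `completed` (list of
#'   tibbles with no missing values in the modeled columns), `methods`,
#'   `iterations`, `seed`.
#' @export
impute_chained <- function(data, m = 5, iterations = 10, seed = 1L,
                           columns = NULL, pmm_age = FALSE) {
  data <- as_tibble(data)
  if (is.null(columns)) {
    columns <- intersect(c(predictor_columns(), "y_favorable"), names(data))
  }
  if (m < 1) abort("`m` must be at least 1.")
  miss_cols <- columns[map_dbl(columns, ~ sum(is.na(data[[.x]]))) > 0]
  fully_missing <- miss_cols[map_dbl(miss_cols, ~ mean(is.na(data[[.x]]))) >= 1]
  if (length(fully_missing)) {
    abort(sprintf("Variable(s) with no observed values anywhere: %s.",
                  paste(fully_missing, collapse = ", ")))
  }
  methods <- setNames(map_chr(columns, function(col) {
    if (col == "age") {
      if (pmm_age) "pmm" else "norm"
    } else if (col %in% c("fisher", "location")) {
      "multinom"
    } else {
      "logreg"
    }
  }), columns)
  if (!length(miss_cols)) {
    completed <- rep(list(data), m)
  } else {
    completed <- with_seed(seed, {
      map(seq_len(m), function(i) {
        impute_once(data, columns, miss_cols, methods, iterations)
      })
    })
  }
  structure(
    list(m = m, completed = completed, methods = methods,
         iterations = iterations, seed = seed, imputed_columns = miss_cols),
    class = "imputation_set"
  )
}

impute_once <- function(data, columns, miss_cols, methods, iterations) {
  work <- data
  na_idx <- setNames(map(miss_cols, ~ which(is.na(data[[.x]]))), miss_cols)
  # initialize: random draws from each column's observed values
  for (col in miss_cols) {
    obs <- data[[col]][!is.na(data[[col]])]
    work[[col]][na_idx[[col]]] <- sample(obs, length(na_idx[[col]]), replace = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (col in miss_cols) {
      idx <- na_idx[[col]]
      rhs <- setdiff(columns, col)
      X <- imputation_design(work, rhs)
      yv <- data[[col]]
      obs <- which(!is.na(yv))
      work[[col]][idx] <- switch(
        methods[[col]],
        norm = draw_norm(X[obs, , drop = FALSE], yv[obs], X[idx, , drop = FALSE]),
        pmm = draw_pmm(X[obs, , drop = FALSE], yv[obs], X[idx, , drop = FALSE]),
        logreg = draw_logreg(X[obs, , drop = FALSE], yv[obs], X[idx, , drop = FALSE]),
        multinom = draw_multinom(yv[obs], X[obs, , drop = FALSE], X[idx, , drop = FALSE],
                                 template = data[[col]])
      )
    }
  }
  work
}

# Numeric design matrix (no intercept) from the current working values.
imputation_design <- function(work, rhs) {
  parts <- map(rhs, function(col) {
    v <- work[[col]]
    if (col == "fisher") {
      f <- factor(as.character(v), levels = as.character(1:4))
      stats::model.matrix(~f)[, -1, drop = FALSE]
    } else if (col == "location") {
      f <- factor(v, levels = aneurysm_locations())
      stats::model.matrix(~f)[, -1, drop = FALSE]
    } else {
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, col))
    }
  })
  do.call(cbind, parts)
}

# Bayesian linear regression draw: sigma^2 from its scaled inverse-chi-square
# posterior, beta from N(beta_hat, sigma^2 (X'X)^-1), then y* = x'beta + e.
draw_norm <- function(X, y, Xmis) {
  Xi <- cbind(1, X)
  qr_ <- qr(Xi)
  beta_hat <- qr.coef(qr_, y)
  beta_hat[is.na(beta_hat)] <- 0
  res <- y - Xi %*% beta_hat
  df <- max(length(y) - ncol(Xi), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtX_inv <- tryCatch(chol2inv(qr.R(qr_)), error = function(e) diag(ncol(Xi)) * 0)
  beta <- beta_hat + drop(t(chol(sigma2 * XtX_inv + diag(1e-10, ncol(Xi)))) %*%
                            rnorm(ncol(Xi)))
  drop(cbind(1, Xmis) %*% beta) + rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

# Predictive-mean matching: impute each missing row with the observed value
# of one of the 5 nearest donors by predicted mean.
draw_pmm <- function(X, y, Xmis, donors = 5L) {
  Xi <- cbind(1, X)
  beta_hat <- qr.coef(qr(Xi), y)
  beta_hat[is.na(beta_hat)] <- 0
  pred_obs <- drop(Xi %*% beta_hat)
  pred_mis <- drop(cbind(1, Xmis) %*% beta_hat)
  vapply(pred_mis, function(pm) {
    near <- order(abs(pred_obs - pm))[seq_len(min(donors, length(pred_obs)))]
    y[sample(near, 1)]
  }, numeric(1))
}

draw_logreg <- function(X, y, Xmis) {
  fit <- fit_logistic_raw(X, as.numeric(y))
  cf <- c(fit$intercept, fit$beta)
  vc <- fit$vcov
  if (!anyNA(vc)) {
    cf <- cf + drop(t(chol(vc + diag(1e-10, length(cf)))) %*% rnorm(length(cf)))
  }
  p <- expit(clamp_lp(drop(cbind(1, Xmis) %*% cf)))
  rbinom(nrow(Xmis), 1L, p)
}

draw_multinom <- function(y, X, Xmis, template) {
  lev <- if (is.numeric(template)) sort(unique(y)) else levels(factor(template[!is.na(template)]))
  f <- factor(y, levels = lev)
  if (length(lev) < 2) return(rep(y[1], nrow(Xmis)))
  fit <- nnet::multinom(f ~ ., data = as.data.frame(X), trace = FALSE,
                        maxit = 200)
  probs <- predict(fit, newdata = as.data.frame(Xmis), type = "probs")
  if (is.null(dim(probs))) probs <- cbind(1 - probs, probs)
  draws <- apply(probs, 1, function(pr) sample(lev, 1, prob = pmax(pr, 0)))
  if (is.numeric(template)) as.numeric(draws) else draws
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d, %d iterations, seed %d\n",
              x$m, x$iterations, x$seed))
  if (length(x$imputed_columns)) {
    cat("  imputed:", paste(x$imputed_columns, collapse = ", "), "\n")
  } else {
    cat("  no missing values; completed datasets are copies of the input\n")
  }
  invisible(x)
}

#' Write an imputation set as CSVs plus a manifest
#'
#' @param imps An [impute_chained()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_imputation_set <- function(imps, dir) {
  stopifnot(inherits(imps, "imputation_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- map_chr(seq_len(imps$m), function(i) {
    p <- file.path(dir, sprintf("imputation_%02d.csv", i))
    utils::write.csv(imps$completed[[i]], p, row.names = FALSE)
    p
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(m = imps$m, iterations = imps$iterations, seed = imps$seed,
         methods = as.list(imps$methods), files = basename(paths)),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Rubin's-rules pooling of estimates across imputations
#'
#' Pools `m` per-imputation estimates: the pooled estimate is the mean, and
#' the total variance is `W + (1 + 1/m) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance. c-statistics are pooled
#' on the logit scale (delta-method variances) and back-transformed.
#'
#' @param estimates Per-imputation point estimates.
#' @param variances Per-imputation squared standard errors (same length).
#' @param transform `"identity"` or `"logit"`.
#' @return One-row tibble: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `total_variance`, `within`, `between`, `m` (variance components on the
#'   transformed scale when `transform = "logit"`).
#' @examples
#' rubin_pool(c(1, 2, 3), c(1, 1, 1)) # estimate 2, total variance 2.33
#' @export
rubin_pool <- function(estimates, variances, transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  m <- length(estimates)
  if (m == 0) abort("Need at least one estimate.")
  if (length(variances) != m) abort("`estimates` and `variances` lengths differ.")
  if (transform == "logit") {
    theta <- logit(clamp01(estimates, 1e-10))
    vtheta <- variances / (estimates * (1 - estimates))^2
  } else {
    theta <- estimates
    vtheta <- variances
  }
  qbar <- mean(theta)
  W <- mean(vtheta)
  B <- if (m > 1) var(theta) else 0
  Tvar <- W + (1 + 1 / m) * B
  ci_t <- wald_ci(qbar, sqrt(Tvar))
  back <- if (transform == "logit") expit else identity
  se_nat <- if (transform == "logit") sqrt(Tvar) * back(qbar) * (1 - back(qbar)) else sqrt(Tvar)
  tibble(
    estimate = back(qbar), se = se_nat,
    ci_low = back(ci_t[1]), ci_high = back(ci_t[2]),
    total_variance = Tvar, within = W, between = B, m = m
  )
}
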