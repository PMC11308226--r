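# End-to-end pipeline and dataset I/O. CSV is the canonical interchange
# format, with a sidecar JSON carrying column types and the generating
# configuration when the data are synthetic.

#' Read a clustered patient dataset from CSV
#'
#' Reads and validates a delimited dataset: typed columns, Fisher grade in
#' 1--4, known aneurysm locations, no duplicated patient ids (when an id
#' column is present), and at least one data row. Empty strings and `NA`
#' tokens become missing values.
#'
#' @param path CSV file with a header.
#' @return A tibble.
#' @export
read_clustered_data <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!nrow(data)) abort("Dataset is empty (header only).")
  data <- as_tibble(data)
  if (!"cluster_id" %in% names(data)) abort("Missing `cluster_id` column.")
  if ("patient_id" %in% names(data) && anyDuplicated(data$patient_id)) {
    abort("Duplicate `patient_id` values.")
  }
  if ("fisher" %in% names(data)) {
    bad <- which(!is.na(data$fisher) & !data$fisher %in% 1:4)
    if (length(bad)) {
      abort(sprintf("Row %d: `fisher` value %s outside grades 1..4.",
                    bad[1], data$fisher[bad[1]]))
    }
  }
  if ("location" %in% names(data)) {
    bad <- which(!is.na(data$location) & !data$location %in% aneurysm_locations())
    if (length(bad)) {
      abort(sprintf("Row %d: unknown `location` value \"%s\".",
                    bad[1], data$location[bad[1]]))
    }
  }
  for (col in intersect(c("wfns_high", "hypertension", "size_large", "y_favorable"),
                        names(data))) {
    bad <- which(!is.na(data[[col]]) & !data[[col]] %in% 0:1)
    if (length(bad)) {
      abort(sprintf("Row %d: `%s` must be 0/1.", bad[1], col))
    }
  }
  data
}

#' Write a clustered dataset as CSV with a JSON sidecar
#'
#' @param data Dataset tibble (the `"generator"` attribute, when present, is
#'   recorded in the sidecar).
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
write_clustered_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  gen <- attr(data, "generator")
  meta <- list(
    columns = as.list(map_chr(data, ~ class(.x)[1])),
    n = nrow(data),
    clusters = unique(as.character(data$cluster_id))
  )
  if (!is.null(gen)) {
    cfg <- gen$config
    meta$generator <- list(
      seed = cfg$seed, true_intercept = cfg$true_intercept,
      tau_intercept = cfg$tau_intercept, tau_slope = cfg$tau_slope,
      true_beta = as.list(cfg$true_beta),
      clusters = map(cfg$cluster_specs, function(s) s[c(
        "cluster_id", "n", "intercept_shift", "slope_multiplier",
        "outcome_scale", "missing_columns"
      )])
    )
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full clustered-validation pipeline
#'
#' Executes the end-to-end analysis on a clustered dataset (or on data
#' generated from the SAHIT-like preset): multiple imputation where needed,
#' leave-one-cluster-out cross-validation, the bootstrap optimism-corrected
#' benchmark, random-effects pooling of every metric with I-squared, and
#' per-cluster membership models with the joint transportability reading.
#' Outputs mirror the standard reporting layout: a performance table with
#' per-cluster and pooled rows, a membership/transportability table, and
#' per-cluster calibration-curve data.
#'
#' @param data Clustered dataset; `NULL` to generate from `preset`.
#' @param preset `"sahit-like"` to generate data when `data` is `NULL`.
#' @param spec A [model_spec()].
#' @param mode `"loco"` (leave-one-cluster-out) or `"external"` (validate a
#'   fixed, externally supplied `model` on every cluster).
#' @param model Required in `"external"` mode: a `fitted_model` (e.g. from
#'   [read_model_json()]).
#' @param m,iterations Imputation settings (used when data have missing
#'   values).
#' @param B Bootstrap resamples for the optimism-corrected benchmark; 0
#'   skips.
#' @param method,transform Meta-analysis settings (see [meta_pool()];
#'   c-statistics always pool on the logit scale, calibration metrics on the
#'   identity scale).
#' @param seed Seed for generation, imputation, and bootstrap.
#' @param out_dir Optional directory: writes `performance.csv`,
#'   `membership.csv`, `calibration_curves.csv`, and `provenance.json`.
#' @return A list of class `iecv_report`: `performance` (per-cluster + pooled
#'   rows), `pooled` (one row per metric with CI, tau2, I2), `membership`,
#'   `validation` (the `iecv_result`), `benchmark`, `provenance`.
#' @export
run_validation_pipeline <- function(data = NULL, preset = NULL,
                                    spec = model_spec(),
                                    mode = c("loco", "external"), model = NULL,
                                    m = 5, iterations = 5, B = 200,
                                    method = "REML", transform = "logit",
                                    seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "external" && is.null(model)) {
    abort("`mode = \"external\"` requires a fitted `model` before any computation.")
  }
  if (is.null(data)) {
    if (is.null(preset) || preset != "sahit-like") {
      abort("Provide `data` or `preset = \"sahit-like\"`.")
    }
    data <- generate_dataset(sahit_like_preset(seed = seed))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  validation <- stage("validation", {
    if (mode == "loco") {
      loco_cv(data, spec, m = m, iterations = iterations, seed = seed)
    } else {
      external_validation(data, model, m = m, iterations = iterations, seed = seed)
    }
  })
  benchmark <- if (B > 0 && mode == "loco") {
    stage("optimism", {
      bench_data <- if (validation$provenance$imputed) {
        impute_chained(data, m = 1, iterations = iterations,
                       seed = derive_seed(seed, 5L),
                       columns = c(spec$predictors, spec$outcome))$completed[[1]]
      } else {
        data
      }
      optimism_corrected_c(bench_data, spec, B = B, seed = derive_seed(seed, 9L))
    })
  } else {
    NULL
  }
  pooled <- stage("meta_pool", {
    est <- filter(validation$estimates, !is.na(.data$value), !is.na(.data$se),
                  .data$se > 0)
    list_rbind(map(setdiff(metric_names(), "c_model_based"), function(mn) {
      rows <- filter(est, .data$metric == mn)
      if (nrow(rows) < 2) return(NULL)
      mp <- meta_pool(rows, transform = if (mn == "c") "logit" else "identity",
                      method = method)
      g <- glance(mp)
      g$metric <- mn
      g
    }))
  })
  membership <- stage("membership", {
    mem_data <- if (validation$provenance$imputed) {
      impute_chained(data, m = 1, iterations = iterations,
                     seed = derive_seed(seed, 7L),
                     columns = c(spec$predictors, spec$outcome))$completed[[1]]
    } else {
      data
    }
    mem <- membership_by_cluster(mem_data, spec)
    cvals <- filter(validation$estimates, .data$metric == "c") |>
      select(all_of(c("cluster_id", "c_validation" = "value")))
    transportability_report(left_join(mem, cvals, by = "cluster_id"))
  })
  performance <- stage("report", {
    per <- validation$estimates
    pooled_rows <- pooled |>
      mutate(cluster_id = "Pooled (random effects)") |>
      select(all_of(c("metric", "value" = "pooled", "ci_low", "ci_high",
                      "cluster_id", "i2", "tau2")))
    bind_rows(mutate(per, i2 = NA_real_, tau2 = NA_real_), pooled_rows)
  })
  report <- structure(
    list(
      performance = performance, pooled = pooled, membership = membership,
      validation = validation, benchmark = benchmark,
      provenance = list(
        seed = seed, mode = mode, m = m, B = B, method = method,
        n = nrow(data), clusters = unique(as.character(data$cluster_id)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
      )
    ),
    class = "iecv_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Fixed-model analogue of loco_pass: the supplied model is evaluated on each
# cluster without refitting.
external_validation <- function(data, model, m = 5, iterations = 5, seed = 1L) {
  data <- as_tibble(data)
  spec <- model$spec
  modeled <- c(spec$predictors, spec$outcome)
  has_miss <- anyNA(data[modeled])
  completed <- if (has_miss) {
    impute_chained(data, m = m, iterations = iterations, seed = seed,
                   columns = modeled)$completed
  } else {
    list(data)
  }
  runs <- map(completed, function(d) {
    clusters <- unique(as.character(d$cluster_id))
    list(estimates = list_rbind(map(clusters, function(k) {
      evaluate_cluster(model, d[d$cluster_id == k, ], cluster_id = k)
    })))
  })
  estimates <- pool_imputation_runs(map(runs, "estimates"))
  structure(
    list(
      estimates = estimates, models = list(external = model),
      apparent = NULL, curves = NULL,
      provenance = list(seed = seed, m = length(completed), imputed = has_miss,
                        clusters = unique(as.character(data$cluster_id)),
                        n = nrow(data))
    ),
    class = "iecv_result"
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$performance, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$membership, file.path(out_dir, "membership.csv"),
                   row.names = FALSE)
  curves <- report$validation$curves
  if (!is.null(curves)) {
    curve_rows <- list_rbind(imap(curves, function(cv, k) {
      if (is.null(cv)) return(NULL)
      mutate(cv$bins, cluster_id = k)
    }))
    utils::write.csv(curve_rows, file.path(out_dir, "calibration_curves.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.iecv_report <- function(x, ...) {
  cat("Clustered validation report\n")
  cat(sprintf("  %d clusters, n = %d, mode = %s\n",
              length(x$provenance$clusters), x$provenance$n, x$provenance$mode))
  if (!is.null(x$benchmark)) {
    cat(sprintf("  optimism-corrected benchmark c = %.3f (apparent %.3f)\n",
                x$benchmark$value, x$benchmark$apparent))
  }
  cat("  pooled performance:\n")
  print(mutate(select(x$pooled, all_of(c("metric", "pooled", "ci_low",
                                         "ci_high", "tau2", "i2"))),
               across(-1, ~ round(.x, 3))))
  invisible(x)
}
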