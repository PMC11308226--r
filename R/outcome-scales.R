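#' Dichotomize functional-outcome scores into favorable/unfavorable
#'
#' Converts raw scores on the Glasgow Outcome Scale (GOS, 1--5), the extended
#' GOS (eGOS, 1--8), or the modified Rankin Scale (mRS, 0--6) into a binary
#' favorable-outcome indicator. Favorable is GOS 4--5, eGOS 4--8, or mRS 0--3;
#' unfavorable is the complement (death is always unfavorable).
#'
#' @param scale Character vector of scale names, each one of `"GOS"`, `"eGOS"`,
#'   `"mRS"` (case-insensitive). Recycled against `value`.
#' @param value Integer vector of raw scores on the corresponding scale.
#' @return Integer vector of 0/1 favorable indicators; `NA` inputs give `NA`.
#' @examples
#' dichotomize_outcome("GOS", 4) # favorable
#' dichotomize_outcome("mRS", c(3, 4)) # favorable, unfavorable
#' @export
dichotomize_outcome <- function(scale, value) {
  if (length(scale) == 1L) scale <- rep(scale, length(value))
  if (length(scale) != length(value)) {
    abort("`scale` and `value` must have equal length (or `scale` length 1).")
  }
  scale <- outcome_scale_canonical(scale)
  out <- rep(NA_integer_, length(value))
  keep <- !is.na(scale) & !is.na(value)
  rng <- outcome_scale_ranges()
  for (s in names(rng)) {
    idx <- which(keep & scale == s)
    if (!length(idx)) next
    v <- value[idx]
    bad <- v < rng[[s]][1] | v > rng[[s]][2] | v != round(v)
    if (any(bad)) {
      abort(sprintf(
        "Out-of-range %s score(s): %s (valid range %d..%d).",
        s, paste(unique(v[bad]), collapse = ", "), rng[[s]][1], rng[[s]][2]
      ))
    }
    out[idx] <- switch(s,
      GOS  = as.integer(v >= 4),
      eGOS = as.integer(v >= 4),
      mRS  = as.integer(v <= 3)
    )
  }
  unknown <- keep & is.na(match(scale, names(rng)))
  if (any(unknown)) {
    abort(sprintf(
      "Unknown outcome scale(s): %s.",
      paste(unique(scale[unknown]), collapse = ", ")
    ))
  }
  out
}

outcome_scale_ranges <- function() {
  list(GOS = c(1L, 5L), eGOS = c(1L, 8L), mRS = c(0L, 6L))
}

outcome_scale_canonical <- function(scale) {
  key <- toupper(trimws(as.character(scale)))
  canonical <- c(GOS = "GOS", EGOS = "eGOS", MRS = "mRS")
  out <- unname(canonical[key])
  out[is.na(key) | key == "" | key == "NONE"] <- NA_character_
  ifelse(is.na(out) & !is.na(key) & key != "" & key != "NONE", scale, out)
}

#' Select the preferred outcome scale when several are recorded
#'
#' When a patient has scores on more than one functional-outcome scale, one
#' scale is used with the fixed priority GOS > mRS > eGOS. The priority is
#' deterministic and recorded in the result.
#'
#' @param available Named numeric vector or list of raw scores; names are scale
#'   names (`GOS`, `mRS`, `eGOS`). `NA` entries are treated as unavailable.
#' @return A list with elements `scale` and `value`, or `NULL` when no score
#'   is available (a missing-outcome signal).
#' @examples
#' select_scale(c(GOS = 5, mRS = 0)) # uses GOS
#' @export
select_scale <- function(available) {
  if (is.null(available) || !length(available)) return(NULL)
  scales <- outcome_scale_canonical(names(available))
  values <- as.numeric(unlist(available, use.names = FALSE))
  ok <- !is.na(scales) & !is.na(values)
  if (!any(ok)) return(NULL)
  for (pref in c("GOS", "mRS", "eGOS")) {
    idx <- which(ok & scales == pref)
    if (length(idx)) return(list(scale = pref, value = values[idx[1]]))
  }
  idx <- which(ok)[1]
  list(scale = scales[idx], value = values[idx])
}

#' Add a favorable-outcome column to a clustered dataset
#'
#' Data-frame-first wrapper around [dichotomize_outcome()]: reads the columns
#' naming each row's outcome scale and raw score and appends a `y_favorable`
#' 0/1 column. Rows whose scale is missing or `"none"` get `NA`.
#'
#' @param data A data frame with one row per patient.
#' @param scale_col,value_col Column names holding the scale and raw score.
#' @return `data` as a tibble with a `y_favorable` column appended (replaced
#'   if already present).
#' @export
add_favorable_outcome <- function(data, scale_col = "outcome_scale",
                                  value_col = "outcome_raw") {
  if (!all(c(scale_col, value_col) %in% names(data))) {
    abort(sprintf("Columns `%s` and `%s` must be present.", scale_col, value_col))
  }
  data <- as_tibble(data)
  data$y_favorable <- dichotomize_outcome(data[[scale_col]], data[[value_col]])
  data
}
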