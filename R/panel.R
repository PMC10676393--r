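#' Construct a multi-wave binary symptom panel
#'
#' The panel container used throughout the package: a subjects x waves x
#' items array of 0/1 values with `NA` marking missing measurements, plus a
#' subjects x covariates matrix of binary covariates. Missingness is carried
#' explicitly as `NA`; no numeric sentinel values are used anywhere.
#'
#' @param items numeric array, subjects x waves x items, values in
#'   `{0, 1, NA}`.
#' @param covariates matrix or data frame, subjects x covariates, values in
#'   `{0, 1}`; may have zero columns.
#' @param subject_ids unique subject identifiers (default `1:n`).
#' @param item_labels,wave_labels dimension labels; waves are ordered.
#' @return An object of class `symptom_panel`.
#' @export
symptom_panel <- function(items, covariates = NULL, subject_ids = NULL,
                          item_labels = NULL, wave_labels = NULL) {
  if (length(dim(items)) != 3) stopf("items must be a 3-d array (subjects x waves x items)")
  n <- dim(items)[1]; W <- dim(items)[2]; p <- dim(items)[3]
  vals <- items[!is.na(items)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stopf("item values must be 0, 1 or missing")
  item_labels <- item_labels %||% dimnames(items)[[3]] %||% paste0("item_", seq_len(p))
  wave_labels <- wave_labels %||% dimnames(items)[[2]] %||% seq_len(W)
  subject_ids <- subject_ids %||% dimnames(items)[[1]] %||% seq_len(n)
  if (anyDuplicated(subject_ids)) stopf("subject_ids must be unique")
  if (is.null(covariates)) covariates <- matrix(0, n, 0)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stopf("covariates must have one row per subject")
  if (ncol(covariates) && !all(covariates[!is.na(covariates)] %in% c(0, 1)))
    stopf("covariates must be binary")
  dimnames(items) <- list(NULL, NULL, item_labels)
  structure(list(
    subject_ids = subject_ids,
    items = items,
    covariates = covariates,
    item_labels = as.character(item_labels),
    wave_labels = wave_labels,
    n_subjects = n, n_waves = W, n_items = p
  ), class = "symptom_panel")
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("Symptom panel: %d subjects x %d waves x %d items\n",
              x$n_subjects, x$n_waves, x$n_items))
  cat(sprintf("  items: %s\n", paste(x$item_labels, collapse = ", ")))
  if (ncol(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(colnames(x$covariates), collapse = ", ")))
  ret <- retained_per_wave(x)
  cat("  observed per wave: ", paste(ret, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of subjects with any observed item per wave
#' @param panel a `symptom_panel`.
#' @return Integer vector of length `n_waves`.
#' @export
retained_per_wave <- function(panel) {
  vapply(seq_len(panel$n_waves), function(w)
    sum(rowSums(!is.na(panel$items[, w, , drop = FALSE])) > 0), integer(1))
}

# subjects x items matrix at one wave
wave_matrix <- function(panel, wave) {
  m <- panel$items[, wave, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = panel$n_items)
  colnames(m) <- panel$item_labels
  m
}
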