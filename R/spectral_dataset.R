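#' Spectral dataset container
#'
#' A `spectral_dataset` holds one near-infrared absorbance spectrum per
#' mosquito on a common wavelength grid, together with optional binary
#' parity labels (0 = nulliparous, 1 = parous), per-sample identifiers
#' and an optional cohort tag (e.g. collection site). It is the
#' interchange object passed between every stage of the pipeline.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength (dimensionless absorbance).
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, one per column of `absorbance`.
#' @param labels optional integer vector of parity labels, one per sample;
#'   values must be 0 (nulliparous) or 1 (parous); `NULL` when unknown.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `"s1" ... "sN"`.
#' @param cohort optional single string or per-sample character vector
#'   tagging the cohort (e.g. `"Minepa-ARA"`).
#' @param allow_replicates permit duplicated `sample_ids` (replicate
#'   scans of the same mosquito, as raw spectrometer exports contain);
#'   downstream stages require replicates to be merged by
#'   [preprocess()] first.
#'
#' @return An object of class `spectral_dataset`: a list with fields
#'   `wavelengths`, `absorbance`, `labels`, `sample_ids`, `cohort`.
#'
#' @examples
#' x <- spectral_dataset(matrix(runif(6), 2, 3), wavelengths = 500:502,
#'                       labels = c(0, 1))
#' n_samples(x)
#' @export
spectral_dataset <- function(absorbance, wavelengths, labels = NULL,
                             sample_ids = NULL, cohort = NULL,
                             allow_replicates = FALSE) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
  }
  if (!is.null(cohort)) {
    cohort <- as.character(cohort)
    if (length(cohort) == 1L) cohort <- rep(cohort, n)
  }
  x <- structure(list(wavelengths = wavelengths,
                      absorbance = absorbance,
                      labels = labels,
                      sample_ids = sample_ids,
                      cohort = cohort),
                 class = "spectral_dataset")
  validate_spectral_dataset(x, allow_replicates = allow_replicates)
  x
}

#' Validate a spectral dataset's invariants
#'
#' Checks matrix/grid dimension agreement, finiteness, strictly increasing
#' wavelengths, binary labels and unique sample ids. Called by the
#' constructor; exported so readers of external files can re-check.
#'
#' @param x a `spectral_dataset`.
#' @param allow_replicates permit duplicated sample ids (see
#'   [spectral_dataset()]).
#' @return `x`, invisibly, if valid; otherwise a classed error.
#' @export
validate_spectral_dataset <- function(x, allow_replicates = FALSE) {
  np_assert(inherits(x, "spectral_dataset"), "nirparity_bad_type",
            "not a spectral_dataset")
  n <- nrow(x$absorbance)
  d <- ncol(x$absorbance)
  np_assert(length(x$wavelengths) == d, "nirparity_dim_mismatch",
            "absorbance has %d columns but %d wavelengths given",
            d, length(x$wavelengths))
  np_assert(d == 0 || all(diff(x$wavelengths) > 0),
            "nirparity_bad_grid", "wavelengths must be strictly increasing")
  np_assert(all(is.finite(x$absorbance)), "nirparity_nonfinite",
            "absorbance contains non-finite values")
  if (!is.null(x$labels)) {
    np_assert(length(x$labels) == n, "nirparity_dim_mismatch",
              "%d labels for %d samples", length(x$labels), n)
    bad <- which(!(x$labels %in% c(0L, 1L)))
    if (length(bad))
      np_stop("nirparity_bad_label",
              "labels must be 0 or 1; offending row(s): %s",
              paste(bad, collapse = ", "))
  }
  np_assert(length(x$sample_ids) == n, "nirparity_dim_mismatch",
            "%d sample ids for %d samples", length(x$sample_ids), n)
  if (!allow_replicates)
    np_assert(!anyDuplicated(x$sample_ids), "nirparity_duplicate_id",
              "sample_ids are not unique")
  if (!is.null(x$cohort))
    np_assert(length(x$cohort) == n, "nirparity_dim_mismatch",
              "%d cohort tags for %d samples", length(x$cohort), n)
  invisible(x)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset: %d samples x %d wavelengths (%s-%s nm)\n",
              nrow(x$absorbance), ncol(x$absorbance),
              format(min(x$wavelengths)), format(max(x$wavelengths))))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d nulliparous (0), %d parous (1)\n",
                sum(x$labels == 0L), sum(x$labels == 1L)))
  if (!is.null(x$cohort))
    cat(sprintf("  cohort(s): %s\n",
                paste(unique(x$cohort), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a spectral dataset
#' @param x a `spectral_dataset`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' Subset a spectral dataset by sample
#'
#' @param x a `spectral_dataset`.
#' @param i integer or logical index over samples.
#' @param ... unused.
#' @return a `spectral_dataset` with the selected rows.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$absorbance[i, , drop = FALSE], x$wavelengths,
                   labels = if (!is.null(x$labels)) x$labels[i],
                   sample_ids = x$sample_ids[i],
                   cohort = if (!is.null(x$cohort)) x$cohort[i],
                   allow_replicates = TRUE)
}

#' @noRd
ds_equal <- function(a, b) {
  identical(a$wavelengths, b$wavelengths) &&
    isTRUE(all.equal(unname(a$absorbance), unname(b$absorbance))) &&
    identical(a$labels, b$labels) &&
    identical(a$sample_ids, b$sample_ids) &&
    identical(a$cohort, b$cohort)
}
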