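#' Preprocessing specification
#'
#' Describes how raw scans are reduced to the fixed feature space the
#' models consume: a wavelength window (default 500--2350 nm inclusive,
#' i.e. 1851 features on a 1 nm grid), a policy for replicate scans of
#' the same sample, and optional per-feature min-max scaling to [0, 1]
#' (required upstream of logistic autoencoder units). Scaling statistics
#' are learned from a training partition with [fit_scaler()] and stored
#' in the spec itself.
#'
#' @param window_low_nm,window_high_nm inclusive wavelength bounds in nm.
#'   The defaults give `2350 - 500 + 1 = 1851` features.
#' @param replicate_policy `"average"` merges rows sharing a sample id by
#'   averaging; `"forbid"` raises an error when replicates are present.
#' @param scaling `"minmax"` or `"none"`.
#' @return an object of class `preprocess_spec`.
#' @seealso [preprocess()], [fit_scaler()], [apply_scaler()]
#' @export
preprocess_spec <- function(window_low_nm = 500, window_high_nm = 2350,
                            replicate_policy = c("average", "forbid"),
                            scaling = c("minmax", "none")) {
  replicate_policy <- match.arg(replicate_policy)
  scaling <- match.arg(scaling)
  np_assert(window_high_nm > window_low_nm, "nirparity_bad_window",
            "window_high_nm must exceed window_low_nm")
  structure(list(window_low_nm = window_low_nm,
                 window_high_nm = window_high_nm,
                 replicate_policy = replicate_policy,
                 scaling = scaling,
                 scaling_stats = NULL),
            class = "preprocess_spec")
}

#' Window raw scans to the model feature space
#'
#' Restricts spectra to the spec's wavelength window (inclusive bounds on
#' a 1 nm grid) and merges replicate rows per policy. With the default
#' window the output has exactly 1851 features per spectrum regardless of
#' the extent of the raw grid, matching the standard protocol's feature
#' space. Labels, ids and cohort tags are carried through unchanged
#' (replicates must agree on label and cohort). The operation is
#' idempotent.
#'
#' @param dataset a `spectral_dataset` whose grid covers the window at
#'   1 nm spacing.
#' @param spec a [preprocess_spec()].
#' @return a `spectral_dataset` with `window_high - window_low + 1`
#'   wavelengths.
#' @export
preprocess <- function(dataset, spec = preprocess_spec()) {
  validate_spectral_dataset(dataset, allow_replicates = TRUE)
  wl <- dataset$wavelengths
  want <- seq(spec$window_low_nm, spec$window_high_nm, by = 1)
  idx <- match(want, wl)
  if (anyNA(idx))
    np_stop("nirparity_window_not_covered",
            "wavelength grid does not cover %d-%d nm at 1 nm spacing (first missing: %d nm)",
            spec$window_low_nm, spec$window_high_nm, want[which(is.na(idx))[1]])
  out <- spectral_dataset(dataset$absorbance[, idx, drop = FALSE], want,
                          labels = dataset$labels,
                          sample_ids = dataset$sample_ids,
                          cohort = dataset$cohort,
                          allow_replicates = TRUE)
  merge_replicates(out, spec$replicate_policy)
}

#' @noRd
merge_replicates <- function(dataset, policy) {
  ids <- dataset$sample_ids
  if (!anyDuplicated(ids)) return(dataset)
  if (policy == "forbid")
    np_stop("nirparity_replicates_forbidden",
            "replicate rows present for id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- !duplicated(ids)
  groups <- split(seq_along(ids), factor(ids, levels = ids[keep]))
  agree <- function(v, what) {
    vapply(groups, function(g) {
      u <- unique(v[g])
      if (length(u) != 1L)
        np_stop("nirparity_replicate_conflict",
                "replicates of id %s disagree on %s", ids[g[1]], what)
      u
    }, v[[1]])
  }
  absm <- do.call(rbind, lapply(groups, function(g)
    colMeans(dataset$absorbance[g, , drop = FALSE])))
  spectral_dataset(absm, dataset$wavelengths,
                   labels = if (!is.null(dataset$labels))
                     agree(dataset$labels, "label"),
                   sample_ids = names(groups),
                   cohort = if (!is.null(dataset$cohort))
                     agree(dataset$cohort, "cohort"))
}

#' @noRd
is_replicated <- function(dataset) anyDuplicated(dataset$sample_ids) > 0

#' Learn min-max scaling statistics from a training partition
#'
#' Records each feature's training min and max in the spec so that
#' [apply_scaler()] can map features to [0, 1]. Fitting on a partition
#' flagged as a held-out test set (by [split_dataset()]) is refused
#' unless `allow_test = TRUE`, as that would leak test information into
#' the model.
#'
#' @param train a `spectral_dataset` (training partition).
#' @param spec a [preprocess_spec()] with `scaling = "minmax"`.
#' @param allow_test override the leakage guard.
#' @return the spec with `scaling_stats` filled in (`min`, `max` per
#'   feature).
#' @export
fit_scaler <- function(train, spec, allow_test = FALSE) {
  validate_spectral_dataset(train)
  np_assert(spec$scaling == "minmax", "nirparity_bad_config",
            "fit_scaler requires scaling = \"minmax\"")
  role <- attr(train, "partition_role")
  if (identical(role, "test") && !allow_test)
    np_stop("nirparity_leakage_guard",
            "refusing to fit scaling statistics on a held-out test partition (set allow_test = TRUE to override)")
  spec$scaling_stats <- list(
    wavelengths = train$wavelengths,
    min = apply(train$absorbance, 2, min),
    max = apply(train$absorbance, 2, max))
  spec
}

#' Apply fitted min-max scaling
#'
#' Maps each feature through `(x - min) / (max - min)` using the training
#' statistics stored in the spec; out-of-range values (possible on test
#' data) are clipped to [0, 1]; constant training features (min == max)
#' map to 0.
#'
#' @param dataset a `spectral_dataset` on the same wavelength grid the
#'   scaler was fitted on.
#' @param spec a [preprocess_spec()] returned by [fit_scaler()].
#' @return the scaled `spectral_dataset`.
#' @export
apply_scaler <- function(dataset, spec) {
  validate_spectral_dataset(dataset)
  st <- spec$scaling_stats
  if (is.null(st))
    np_stop("nirparity_scaler_not_fitted",
            "apply_scaler called before fit_scaler")
  if (!identical(as.numeric(st$wavelengths), as.numeric(dataset$wavelengths)))
    np_stop("nirparity_dim_mismatch",
            "dataset wavelength grid differs from the grid the scaler was fitted on")
  rng <- st$max - st$min
  rng[rng == 0] <- Inf  # constant features map to 0
  scaled <- sweep(sweep(dataset$absorbance, 2, st$min, "-"), 2, rng, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- dataset
  out$absorbance <- scaled
  out
}
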