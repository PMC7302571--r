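#' Configuration for the synthetic NIR spectra generator
#'
#' Generates plausible mosquito-like absorbance spectra: a smooth
#' low-order polynomial continuum per sample, a shared set of Gaussian
#' absorption bands with per-sample depth jitter, a parity effect that
#' deepens a small subset of those bands in the parous class, additive
#' Gaussian noise, and an optional cohort shift (baseline offset plus
#' band-center jitter) for cross-cohort experiments. Absorbance stays in
#' a realistic 0--2 range. With `effect_size = 0` the two classes are
#' exchangeable by construction.
#'
#' @param n_parous,n_nulliparous class sizes (default 50/50; e.g. 21 and
#'   119 emulate a severely imbalanced field cohort).
#' @param grid_low_nm,grid_high_nm wavelength range, 1 nm spacing
#'   (default 350--2500 nm, i.e. 2151 points, covering the default
#'   500--2350 nm analysis window).
#' @param n_bands number of shared Gaussian absorption bands.
#' @param n_class_bands how many of those bands carry the parity effect
#'   (default 3).
#' @param effect_size dimensionless multiplier on the class-dependent
#'   extra band depth; 0 = no class signal.
#' @param noise_sd standard deviation of additive Gaussian noise on each
#'   absorbance value.
#' @param baseline_shift additive offset applied to a shifted cohort.
#' @param center_jitter_nm sd of band-center displacement in a shifted
#'   cohort.
#' @param cohort cohort tag for generated samples.
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parous = 50, n_nulliparous = 50,
                             grid_low_nm = 350, grid_high_nm = 2500,
                             n_bands = 12, n_class_bands = 3,
                             effect_size = 1, noise_sd = 0.01,
                             baseline_shift = 0, center_jitter_nm = 0,
                             cohort = "synthetic", seed = 1) {
  np_assert(n_parous >= 0 && n_nulliparous >= 0 &&
              n_parous + n_nulliparous > 0, "nirparity_bad_config",
            "class sizes must be non-negative and sum to > 0")
  np_assert(grid_high_nm > grid_low_nm, "nirparity_bad_config",
            "grid_high_nm must exceed grid_low_nm")
  np_assert(n_class_bands <= n_bands, "nirparity_bad_config",
            "n_class_bands cannot exceed n_bands")
  np_assert(effect_size >= 0 && noise_sd >= 0, "nirparity_bad_config",
            "effect_size and noise_sd must be non-negative")
  structure(list(n_parous = as.integer(n_parous),
                 n_nulliparous = as.integer(n_nulliparous),
                 grid_low_nm = grid_low_nm, grid_high_nm = grid_high_nm,
                 n_bands = as.integer(n_bands),
                 n_class_bands = as.integer(n_class_bands),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_shift = baseline_shift,
                 center_jitter_nm = center_jitter_nm,
                 cohort = cohort, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Band positions/widths/depths are drawn once per config seed so that a
# cohort pair shares the same class-effect structure.
#' @noRd
draw_band_structure <- function(config) {
  wl <- seq(config$grid_low_nm, config$grid_high_nm, by = 1)
  margin <- 0.05 * (config$grid_high_nm - config$grid_low_nm)
  centers <- stats::runif(config$n_bands,
                          config$grid_low_nm + margin,
                          config$grid_high_nm - margin)
  widths <- stats::runif(config$n_bands, 30, 120)
  depths <- stats::runif(config$n_bands, 0.05, 0.25)
  class_idx <- sample(config$n_bands, config$n_class_bands)
  # extra depth added to parous spectra on the class-bearing bands,
  # scaled by effect_size; sized so that at effect_size = 2 the
  # between-class mean separation exceeds ~2.5 within-class sd along the
  # discriminant direction (centroid classifier then operates near 99%)
  delta <- stats::runif(config$n_class_bands, 0.06, 0.09)
  list(wavelengths = wl, centers = centers, widths = widths,
       depths = depths, class_idx = class_idx, delta = delta)
}

#' @noRd
band_profile <- function(wl, center, width) exp(-((wl - center)^2) /
                                                  (2 * width^2))

#' Generate a labeled synthetic spectral dataset
#'
#' @param config a [synthetic_config()].
#' @return a `spectral_dataset` with `n_parous + n_nulliparous` samples
#'   (parous rows interleaved deterministically), labels and cohort set.
#'   Byte-identical for identical config (including seed).
#' @export
generate_spectra <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  bands <- draw_band_structure(config)
  generate_from_structure(config, bands)
}

#' @noRd
generate_from_structure <- function(config, bands, id_prefix = "syn") {
  wl <- bands$wavelengths
  d <- length(wl)
  n <- config$n_parous + config$n_nulliparous
  labels <- rep(c(1L, 0L), c(config$n_parous, config$n_nulliparous))
  u <- (wl - min(wl)) / (max(wl) - min(wl))  # 0..1 for the continuum
  centers <- bands$centers
  if (config$center_jitter_nm > 0)
    centers <- centers + stats::rnorm(length(centers),
                                      sd = config$center_jitter_nm)
  profiles <- vapply(seq_along(centers), function(b)
    band_profile(wl, centers[b], bands$widths[b]), numeric(d))
  absm <- matrix(0, n, d)
  for (i in seq_len(n)) {
    coef <- c(stats::runif(1, 0.43, 0.47),   # intercept
              stats::runif(1, 0.22, 0.28),   # slope
              stats::runif(1, -0.03, 0.03))  # curvature
    baseline <- coef[1] + coef[2] * u + coef[3] * (2 * u^2 - 1)
    depth_i <- bands$depths * stats::runif(length(bands$depths),
                                           0.97, 1.03)
    if (labels[i] == 1L && config$effect_size > 0)
      depth_i[bands$class_idx] <- depth_i[bands$class_idx] +
        config$effect_size * bands$delta
    absm[i, ] <- baseline + drop(profiles %*% depth_i) +
      stats::rnorm(d, sd = config$noise_sd) + config$baseline_shift
  }
  spectral_dataset(absm, wl, labels = labels,
                   sample_ids = sprintf("%s%04d", id_prefix, seq_len(n)),
                   cohort = config$cohort)
}

#' Generate a matched pair of cohorts with a domain shift
#'
#' Both cohorts share the same absorption-band structure and class
#' effect (drawn under `config$seed`), but cohort B receives the
#' configured `baseline_shift`/`center_jitter_nm` and independent
#' per-sample noise, emulating a second collection site or instrument.
#'
#' @param config a [synthetic_config()]; its shift fields apply to
#'   cohort B only.
#' @return list with `cohort_a` and `cohort_b` `spectral_dataset`s.
#' @export
generate_cohort_pair <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  bands <- draw_band_structure(config)
  cfg_a <- config
  cfg_a$baseline_shift <- 0
  cfg_a$center_jitter_nm <- 0
  cfg_a$cohort <- paste0(config$cohort, "-A")
  a <- generate_from_structure(cfg_a, bands, id_prefix = "cohA-")
  cfg_b <- config
  cfg_b$cohort <- paste0(config$cohort, "-B")
  b <- generate_from_structure(cfg_b, bands, id_prefix = "cohB-")
  list(cohort_a = a, cohort_b = b)
}

#' Named generator presets
#'
#' * `"balanced-easy"`: 200 + 200 samples, clear class effect
#'   (`effect_size = 2`) -- the separable preset used by the end-to-end
#'   checks.
#' * `"muleba-imbalance"`: 21 parous vs 119 nulliparous, moderate
#'   effect -- the severe field imbalance profile.
#' * `"null"`: `effect_size = 0`, classes exchangeable.
#' * `"cohort-shift"`: balanced classes with a baseline offset and band
#'   jitter for cohort B (use with [generate_cohort_pair()]).
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned config.
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("balanced-easy", "muleba-imbalance",
                                      "null", "cohort-shift"),
                             seed = 1) {
  name <- match.arg(name)
  switch(name,
         "balanced-easy" = synthetic_config(n_parous = 200,
                                            n_nulliparous = 200,
                                            effect_size = 2, seed = seed),
         "muleba-imbalance" = synthetic_config(n_parous = 21,
                                               n_nulliparous = 119,
                                               effect_size = 1,
                                               seed = seed),
         "null" = synthetic_config(n_parous = 200, n_nulliparous = 200,
                                   effect_size = 0, seed = seed),
         "cohort-shift" = synthetic_config(n_parous = 100,
                                           n_nulliparous = 100,
                                           effect_size = 2,
                                           baseline_shift = 0.3,
                                           center_jitter_nm = 15,
                                           seed = seed))
}

# Distance-to-centroid reference classifier: assigns each sample to the
# class with the nearer (Euclidean) training-mean spectrum. Used as an
# independent check that a generated dataset carries (or lacks) class
# signal.
#' @noRd
centroid_holdout_accuracy <- function(dataset, train_fraction = 0.75,
                                      seed = 1) {
  parts <- split_dataset(dataset, train_fraction, seed = seed)
  tr <- parts$train; te <- parts$test
  mu1 <- colMeans(tr$absorbance[tr$labels == 1L, , drop = FALSE])
  mu0 <- colMeans(tr$absorbance[tr$labels == 0L, , drop = FALSE])
  d1 <- rowSums(sweep(te$absorbance, 2, mu1)^2)
  d0 <- rowSums(sweep(te$absorbance, 2, mu0)^2)
  mean(as.integer(d1 < d0) == te$labels)
}
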