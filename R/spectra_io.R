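#' Read a spectral dataset from CSV
#'
#' The canonical on-disk format is comma-separated text with a header
#' row: optional `id`, `label` and `cohort` columns (configurable
#' names), then one column per wavelength, named by its value in nm.
#' Wavelength columns may appear in any order on disk; they are always
#' sorted ascending in memory. Label values may be 0/1 integers or the
#' aliases `"nulliparous"`/`"parous"` (case-insensitive).
#'
#' @param path CSV file path.
#' @param id_column,label_column,cohort_column column names to route to
#'   sample ids, labels and cohort; set `label_column = NULL` for
#'   unlabeled data. Missing optional columns are skipped silently;
#'   every remaining column must have a numeric wavelength header.
#' @return a `spectral_dataset`.
#' @export
read_spectra <- function(path, id_column = "id", label_column = "label",
                         cohort_column = "cohort") {
  if (!file.exists(path))
    np_stop("nirparity_missing_file", "file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) np_stop("nirparity_ragged_rows",
                                "cannot parse %s: %s", path,
                                conditionMessage(e)))
  nm <- names(df)
  meta_cols <- c(id_column, label_column, cohort_column)
  spectral <- nm[!nm %in% meta_cols]  # keep duplicates for detection
  wl <- suppressWarnings(as.numeric(spectral))
  if (anyNA(wl))
    np_stop("nirparity_bad_header",
            "non-numeric wavelength column header(s): %s",
            paste(spectral[is.na(wl)], collapse = ", "))
  if (anyDuplicated(wl))
    np_stop("nirparity_duplicate_wavelength",
            "duplicate wavelength column(s): %s",
            paste(unique(wl[duplicated(wl)]), collapse = ", "))
  ord <- order(wl)
  abs_mat <- as.matrix(df[, spectral[ord], drop = FALSE])
  if (nrow(abs_mat) == 0) storage.mode(abs_mat) <- "double"
  if (!is.numeric(abs_mat))
    np_stop("nirparity_bad_value", "non-numeric absorbance values in %s",
            path)
  dimnames(abs_mat) <- NULL
  labels <- NULL
  if (!is.null(label_column) && label_column %in% nm)
    labels <- parse_labels(df[[label_column]])
  spectral_dataset(abs_mat, wl[ord], labels = labels,
                   allow_replicates = TRUE,
                   sample_ids = if (!is.null(id_column) &&
                                    id_column %in% nm)
                     as.character(df[[id_column]]) else NULL,
                   cohort = if (!is.null(cohort_column) &&
                                cohort_column %in% nm)
                     as.character(df[[cohort_column]]) else NULL)
}

#' @noRd
parse_labels <- function(v) {
  v0 <- tolower(trimws(as.character(v)))
  out <- ifelse(v0 %in% c("0", "nulliparous"), 0L,
                ifelse(v0 %in% c("1", "parous"), 1L, NA_integer_))
  if (anyNA(out))
    np_stop("nirparity_bad_label",
            "label value(s) outside {0, 1, nulliparous, parous} at row(s): %s",
            paste(which(is.na(out)), collapse = ", "))
  out
}

#' Write a spectral dataset to CSV
#'
#' Emits the canonical format read by [read_spectra()]: header `id`,
#' (`label`,) (`cohort`,) then wavelengths in nm ascending; one row per
#' sample. Numeric values are written with 17 significant digits, which
#' round-trips IEEE doubles exactly, so `read_spectra(write_spectra(x))`
#' reproduces `x`.
#'
#' @param dataset a valid `spectral_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(dataset, path) {
  validate_spectral_dataset(dataset, allow_replicates = TRUE)
  num <- function(x) sprintf("%.17g", x)
  header <- c("id",
              if (!is.null(dataset$labels)) "label",
              if (!is.null(dataset$cohort)) "cohort",
              num(dataset$wavelengths))
  rows <- cbind(dataset$sample_ids,
                if (!is.null(dataset$labels)) dataset$labels,
                if (!is.null(dataset$cohort)) dataset$cohort,
                if (n_samples(dataset) > 0)
                  matrix(num(dataset$absorbance), nrow(dataset$absorbance)))
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    np_stop("nirparity_unwritable",
                            "cannot open %s for writing", path))
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (!is.null(rows) && nrow(rows) > 0)
    writeLines(apply(rows, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Bundle a trained pipeline for persistence
#'
#' @param classifier a trained [ann_classifier()].
#' @param autoencoder optional `autoencoder_stack`.
#' @param preprocess the fitted [preprocess_spec()] used for training.
#' @param seed seed the pipeline was fitted under.
#' @return an object of class `model_bundle`. The classifier input
#'   dimension must equal the encoder output dimension when an
#'   autoencoder is present.
#' @export
model_bundle <- function(classifier, autoencoder = NULL,
                         preprocess = NULL, seed = NA_integer_) {
  if (!is.null(autoencoder))
    np_assert(classifier$input_dim == autoencoder$code_dim,
              "nirparity_inconsistent_bundle",
              "classifier input dim (%d) != encoder output dim (%d)",
              classifier$input_dim, autoencoder$code_dim)
  structure(list(format_version = 1L,
                 classifier = classifier,
                 autoencoder = autoencoder,
                 preprocess = preprocess,
                 seed = as.integer(seed),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC")),
            class = "model_bundle")
}

# --- bundle (de)serialization -------------------------------------------
# The on-disk container is a single self-describing JSON document: a
# manifest of dimensions/activations plus numeric arrays stored row-major
# with explicit shapes, text-encoded at 17 significant digits (exact for
# doubles). Serialization is deterministic, so save -> load -> save is
# byte-identical.

#' @noRd
mat_out <- function(m) list(shape = dim(m), data = as.vector(t(m)))

#' @noRd
mat_in <- function(x) {
  shape <- as.integer(unlist(x$shape))
  d <- as.numeric(unlist(x$data))
  if (length(d) != prod(shape))
    np_stop("nirparity_inconsistent_bundle",
            "array payload length %d does not match shape %s",
            length(d), paste(shape, collapse = "x"))
  matrix(d, shape[1], shape[2], byrow = TRUE)
}

#' Save a model bundle to disk
#'
#' @param bundle a [model_bundle()].
#' @param path output path (JSON text).
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  np_assert(inherits(bundle, "model_bundle"), "nirparity_bad_type",
            "not a model_bundle")
  cl <- bundle$classifier
  doc <- list(
    format = "nirparity-bundle",
    format_version = bundle$format_version,
    seed = bundle$seed,
    created = bundle$created,
    classifier = list(
      input_dim = cl$input_dim, hidden_units = cl$hidden_units,
      activation = cl$activation, threshold = cl$threshold,
      W1 = if (!is.null(cl$W1)) mat_out(cl$W1),
      b1 = cl$b1,
      W2 = mat_out(cl$W2), b2 = cl$b2),
    autoencoder = if (!is.null(bundle$autoencoder)) {
      st <- bundle$autoencoder
      list(input_dim = st$input_dim, code_dim = st$code_dim,
           seed = st$seed, step_mse = st$step_mse,
           config = unclass(st$config),
           steps = lapply(st$steps, function(s)
             list(input_dim = s$input_dim, code_dim = s$code_dim,
                  encoder_activation = s$encoder_activation,
                  decoder_activation = s$decoder_activation,
                  W_enc = mat_out(s$W_enc), b_enc = s$b_enc,
                  W_dec = mat_out(s$W_dec), b_dec = s$b_dec)))
    },
    preprocess = if (!is.null(bundle$preprocess)) {
      pp <- bundle$preprocess
      list(window_low_nm = pp$window_low_nm,
           window_high_nm = pp$window_high_nm,
           replicate_policy = pp$replicate_policy,
           scaling = pp$scaling,
           scaling_stats = if (!is.null(pp$scaling_stats))
             lapply(pp$scaling_stats, as.numeric))
    })
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Load a model bundle from disk
#'
#' Validates the container version and internal dimension consistency
#' (classifier input vs encoder output, per-step shapes) before
#' returning. Truncated or empty files raise a
#' `nirparity_truncated_bundle` error; unknown versions a
#' `nirparity_version_mismatch` error.
#'
#' @param path path written by [save_bundle()].
#' @return a [model_bundle()].
#' @export
load_bundle <- function(path) {
  if (!file.exists(path))
    np_stop("nirparity_missing_file", "file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    np_stop("nirparity_truncated_bundle",
                            "cannot parse bundle %s: %s", path,
                            conditionMessage(e)))
  if (!identical(doc$format, "nirparity-bundle"))
    np_stop("nirparity_truncated_bundle",
            "%s is not a nirparity model bundle", path)
  if (!identical(as.integer(doc$format_version), 1L))
    np_stop("nirparity_version_mismatch",
            "unsupported bundle version: %s", doc$format_version)
  cj <- doc$classifier
  cl <- structure(list(input_dim = as.integer(cj$input_dim),
                       hidden_units = as.integer(cj$hidden_units),
                       activation = cj$activation,
                       threshold = as.numeric(cj$threshold),
                       W1 = if (!is.null(cj$W1)) mat_in(cj$W1),
                       b1 = if (!is.null(cj$b1))
                         as.numeric(unlist(cj$b1)),
                       W2 = mat_in(cj$W2),
                       b2 = as.numeric(unlist(cj$b2))),
                  class = "ann_classifier")
  stack <- NULL
  if (!is.null(doc$autoencoder)) {
    aj <- doc$autoencoder
    steps <- lapply(aj$steps, function(s) {
      st <- new_ae_step(mat_in(s$W_enc), as.numeric(unlist(s$b_enc)),
                        mat_in(s$W_dec), as.numeric(unlist(s$b_dec)),
                        s$encoder_activation, s$decoder_activation)
      if (st$input_dim != as.integer(s$input_dim) ||
          st$code_dim != as.integer(s$code_dim))
        np_stop("nirparity_inconsistent_bundle",
                "autoencoder step shapes disagree with the manifest")
      st
    })
    cfg <- aj$config
    stack <- structure(list(steps = steps,
                            step_mse = as.numeric(unlist(aj$step_mse)),
                            input_dim = as.integer(aj$input_dim),
                            code_dim = as.integer(aj$code_dim),
                            config = structure(
                              list(epochs = as.integer(cfg$epochs),
                                   learning_rate =
                                     as.numeric(cfg$learning_rate),
                                   momentum = as.numeric(cfg$momentum),
                                   encoder_activation =
                                     cfg$encoder_activation,
                                   decoder_activation =
                                     cfg$decoder_activation),
                              class = "ae_config"),
                            seed = as.integer(aj$seed)),
                       class = "autoencoder_stack")
    for (i in seq_along(steps)[-1])
      if (steps[[i]]$input_dim != steps[[i - 1]]$code_dim)
        np_stop("nirparity_inconsistent_bundle",
                "step %d input dim != step %d code dim", i, i - 1)
  }
  pp <- NULL
  if (!is.null(doc$preprocess)) {
    pj <- doc$preprocess
    pp <- structure(list(window_low_nm = as.numeric(pj$window_low_nm),
                         window_high_nm = as.numeric(pj$window_high_nm),
                         replicate_policy = pj$replicate_policy,
                         scaling = pj$scaling,
                         scaling_stats = if (!is.null(pj$scaling_stats))
                           lapply(pj$scaling_stats,
                                  function(v) as.numeric(unlist(v)))),
                    class = "preprocess_spec")
  }
  bundle <- model_bundle(cl, stack, pp,
                         seed = if (is.null(doc$seed)) NA_integer_
                         else as.integer(doc$seed))
  bundle$created <- doc$created
  bundle
}
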