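#' Random 75/25 train/test split
#'
#' Uniformly permutes the samples under the seed and assigns the first
#' `floor(train_fraction * N)` to the training partition. The split is
#' deliberately unstratified: the two parity groups are merged,
#' randomized and divided, so class proportions in the partitions vary
#' by chance (set `stratified = TRUE` to balance them for imbalance
#' experiments). Each partition is tagged with attributes
#' `partition_role` ("train"/"test") and `split_seed`, which the scaler's
#' leakage guard inspects.
#'
#' @param dataset a labeled or unlabeled `spectral_dataset`.
#' @param train_fraction proportion in (0, 1); default 0.75.
#' @param seed integer seed.
#' @param stratified permute within each label class so both partitions
#'   keep the overall class ratio (off by default).
#' @return list with `train` and `test` `spectral_dataset`s, disjoint
#'   and exhaustive.
#' @export
split_dataset <- function(dataset, train_fraction = 0.75, seed = 1,
                          stratified = FALSE) {
  validate_spectral_dataset(dataset)
  np_assert(train_fraction > 0 && train_fraction < 1,
            "nirparity_bad_fraction", "train_fraction must be in (0, 1)")
  n <- n_samples(dataset)
  n_train <- floor(train_fraction * n)
  np_assert(n >= 2 && n_train >= 1 && n_train < n, "nirparity_too_small",
            "cannot place at least one sample in each partition (N = %d)", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (stratified && !is.null(dataset$labels)) {
    idx_train <- unlist(lapply(split(seq_len(n), dataset$labels),
                               function(ix) {
                                 ix <- sample(ix)
                                 ix[seq_len(floor(train_fraction *
                                                    length(ix)))]
                               }), use.names = FALSE)
    idx_test <- setdiff(seq_len(n), idx_train)
  } else {
    perm <- sample(n)
    idx_train <- perm[seq_len(n_train)]
    idx_test <- perm[(n_train + 1L):n]
  }
  tag <- function(d, role) {
    attr(d, "partition_role") <- role
    attr(d, "split_seed") <- as.integer(seed)
    d
  }
  list(train = tag(dataset[idx_train], "train"),
       test = tag(dataset[idx_test], "test"))
}

#' Confusion matrix for binary parity predictions
#'
#' Counts, with parous (1) as the positive class: TP = parous predicted
#' parous, FP = nulliparous predicted parous, TN = nulliparous predicted
#' nulliparous, FN = parous predicted nulliparous.
#'
#' @param predicted,actual equal-length binary 0/1 vectors.
#' @return an object of class `confusion_matrix` with fields `TP`, `FP`,
#'   `TN`, `FN` and derived totals `P = TP + FN`, `N = TN + FP`.
#' @export
confusion <- function(predicted, actual) {
  np_assert(length(predicted) == length(actual), "nirparity_dim_mismatch",
            "predicted and actual labels differ in length")
  np_assert(all(predicted %in% c(0, 1)) && all(actual %in% c(0, 1)),
            "nirparity_bad_label", "labels must be 0 or 1")
  tp <- sum(predicted == 1 & actual == 1)
  fp <- sum(predicted == 1 & actual == 0)
  tn <- sum(predicted == 0 & actual == 0)
  fn <- sum(predicted == 0 & actual == 1)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 P = tp + fn, N = tn + fp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2,
              dimnames = list(estimate = c("nulliparous", "parous"),
                              actual = c("nulliparous", "parous")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes, as proportions in [0, 1]:
#' sensitivity = TP / P (recall on the parous class),
#' specificity = TN / N (recall on the nulliparous class),
#' accuracy = (TP + TN) / (P + N), and
#' precision = TP / (TP + FP), which is `NA` (undefined, not zero) when
#' no sample was predicted parous. When per-sample scores and actual
#' labels are supplied, the ROC curve and its trapezoidal AUC are added.
#'
#' @param cm a [confusion()] matrix; both classes must be present.
#' @param scores optional numeric scores for ROC/AUC.
#' @param actual actual labels matching `scores` (required with
#'   `scores`).
#' @return an object of class `evaluation_metrics`: `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, optionally `auc` and
#'   `roc_points`, plus the source `confusion`.
#' @export
classification_metrics <- function(cm, scores = NULL, actual = NULL) {
  np_assert(inherits(cm, "confusion_matrix"), "nirparity_bad_type",
            "cm must be a confusion_matrix")
  if (cm$P == 0)
    np_stop("nirparity_degenerate_test_set",
            "test set contains no parous (positive) samples")
  if (cm$N == 0)
    np_stop("nirparity_degenerate_test_set",
            "test set contains no nulliparous (negative) samples")
  out <- list(sensitivity = cm$TP / cm$P,
              specificity = cm$TN / cm$N,
              accuracy = (cm$TP + cm$TN) / (cm$P + cm$N),
              precision = if (cm$TP + cm$FP > 0)
                cm$TP / (cm$TP + cm$FP) else NA_real_,
              auc = NULL, roc_points = NULL,
              confusion = cm)
  if (!is.null(scores)) {
    np_assert(!is.null(actual), "nirparity_bad_config",
              "actual labels are required alongside scores")
    roc <- roc_auc(scores, actual)
    out$auc <- roc$auc
    out$roc_points <- roc$roc_points
  }
  structure(out, class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  pct <- function(v) if (is.null(v) || is.na(v)) "--"
  else sprintf("%.1f%%", 100 * v)
  cat(sprintf(paste0("accuracy %s  sensitivity %s  specificity %s  ",
                     "precision %s  AUC %s\n"),
              pct(x$accuracy), pct(x$sensitivity), pct(x$specificity),
              pct(x$precision), pct(x$auc)))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold across the distinct score values
#' (predict parous when score > t), yielding ROC points from (0, 0) to
#' (1, 1); the area is computed by trapezoidal integration. Tied scores
#' contribute half a concordance, so the AUC equals the Mann-Whitney
#' pairwise-concordance statistic over all parous/nulliparous pairs.
#'
#' @param scores finite numeric scores (higher = more parous-like).
#' @param actual binary 0/1 labels; both classes must be present.
#' @return list with `auc` and `roc_points` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, actual) {
  np_assert(length(scores) == length(actual), "nirparity_dim_mismatch",
            "scores and labels differ in length")
  np_assert(all(is.finite(scores)), "nirparity_nonfinite",
            "scores must be finite")
  p <- sum(actual == 1)
  n <- sum(actual == 0)
  if (p == 0 || n == 0)
    np_stop("nirparity_degenerate_test_set",
            "ROC needs both classes; missing %s samples",
            if (p == 0) "parous" else "nulliparous")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- scores > t
    c(fpr = sum(pred & actual == 0) / n,
      tpr = sum(pred & actual == 1) / p)
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  auc <- sum(diff(pts[, 1]) * (pts[-1, 2] + pts[-nrow(pts), 2]) / 2)
  list(auc = auc,
       roc_points = data.frame(fpr = pts[, 1], tpr = pts[, 2]))
}

#' Pipeline configuration for cross-validated evaluation
#'
#' Bundles every tunable of the two workflows: `"raw-ann"` trains the
#' classifier directly on the windowed (and scaled) spectra; the default
#' `"encoded-ann"` first compresses them with the stepwise autoencoder.
#' `leakage_mode` selects where unsupervised fitting happens:
#' `"repeat-internal"` (default) fits the scaler and autoencoder inside
#' each repeat on that repeat's training partition only;
#' `"whole-dataset"` fits them once on the full dataset before
#' splitting, which mirrors encode-then-split workflows but leaks
#' unsupervised information into the test partitions.
#'
#' @param pipeline `"encoded-ann"` or `"raw-ann"`.
#' @param preprocess a [preprocess_spec()].
#' @param step_dims autoencoder code sizes (encoded pipeline).
#' @param ae an [ae_config()].
#' @param lm an [lm_config()] (its seed is overridden per repeat).
#' @param hidden_units classifier hidden width.
#' @param threshold decision cutoff.
#' @param leakage_mode `"repeat-internal"` or `"whole-dataset"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(pipeline = c("encoded-ann", "raw-ann"),
                            preprocess = preprocess_spec(),
                            step_dims = c(256, 64, 10),
                            ae = ae_config(),
                            lm = lm_config(),
                            hidden_units = 10,
                            threshold = 0.5,
                            leakage_mode = c("repeat-internal",
                                             "whole-dataset")) {
  structure(list(pipeline = match.arg(pipeline), preprocess = preprocess,
                 step_dims = step_dims, ae = ae, lm = lm,
                 hidden_units = hidden_units, threshold = threshold,
                 leakage_mode = match.arg(leakage_mode)),
            class = "pipeline_config")
}

# Fit scaler (+ autoencoder) + classifier on a training partition.
#' @noRd
fit_pipeline <- function(train, config, seed) {
  spec <- config$preprocess
  if (spec$scaling == "minmax") {
    spec <- fit_scaler(train, spec)
    train_s <- apply_scaler(train, spec)
  } else train_s <- train
  stack <- NULL
  if (config$pipeline == "encoded-ann") {
    stack <- train_autoencoder(train_s, config$step_dims, config$ae,
                               seed = seed)
    feats <- encode_spectra(stack, train_s)
    input_dim <- stack$code_dim
  } else {
    feats <- train_s
    input_dim <- ncol(train_s$absorbance)
  }
  lmc <- config$lm
  lmc$seed <- seed
  model <- ann_classifier(input_dim, hidden_units = config$hidden_units,
                          threshold = config$threshold)
  model <- lm_fit(model, feats, lmc)
  model_bundle(classifier = model, autoencoder = stack,
               preprocess = spec, seed = seed)
}

# Score a dataset through a fitted bundle.
#' @noRd
predict_pipeline <- function(bundle, dataset) {
  spec <- bundle$preprocess
  x <- if (!is.null(spec$scaling_stats)) apply_scaler(dataset, spec)
  else dataset
  feats <- if (!is.null(bundle$autoencoder))
    encode_spectra(bundle$autoencoder, x) else x
  predict(bundle$classifier, feats)
}

#' Monte-Carlo cross-validation of a parity pipeline
#'
#' Repeats (default ten times): split 75/25 under a child seed
#' (`seed + repeat - 1`); fit the configured pipeline on the training
#' partition; score the held-out quarter; record its confusion matrix
#' and metrics. The summary reports the mean and sample (n-1) standard
#' deviation of each metric across repeats.
#'
#' @param dataset a labeled, preprocessed `spectral_dataset` (apply
#'   [preprocess()] first; scaling and encoding happen inside each
#'   repeat).
#' @param config a [pipeline_config()].
#' @param repeats number of Monte-Carlo repeats (default 10).
#' @param train_fraction passed to [split_dataset()].
#' @param seed base seed; repeat r uses child seed `seed + r - 1`.
#' @return an object of class `mccv_result`: `per_repeat` (list of
#'   records with `repeat_index`, `split_seed`, `confusion`, `metrics`),
#'   `summary` (data frame of mean/sd per metric), `repeats`, `config`.
#' @export
monte_carlo_cv <- function(dataset, config = pipeline_config(),
                           repeats = 10, train_fraction = 0.75, seed = 1) {
  np_assert(repeats >= 1, "nirparity_bad_config", "repeats must be >= 1")
  np_assert(!is.null(dataset$labels), "nirparity_bad_label",
            "Monte-Carlo cross-validation needs a labeled dataset")
  whole_bundle <- NULL
  if (config$leakage_mode == "whole-dataset") {
    # encode-then-split: unsupervised stages see the full dataset once
    spec <- config$preprocess
    if (spec$scaling == "minmax") spec <- fit_scaler(dataset, spec)
    sc <- if (!is.null(spec$scaling_stats)) apply_scaler(dataset, spec)
    else dataset
    stack <- if (config$pipeline == "encoded-ann")
      train_autoencoder(sc, config$step_dims, config$ae, seed = seed)
    whole_bundle <- list(preprocess = spec, autoencoder = stack)
  }
  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    child <- as.integer(seed + r - 1L)
    rec <- tryCatch({
      parts <- split_dataset(dataset, train_fraction, seed = child)
      if (is.null(whole_bundle)) {
        bundle <- fit_pipeline(parts$train, config, seed = child)
      } else {
        tr <- parts$train
        attr(tr, "partition_role") <- NULL
        spec <- whole_bundle$preprocess
        sc_tr <- if (!is.null(spec$scaling_stats)) apply_scaler(tr, spec)
        else tr
        feats <- if (!is.null(whole_bundle$autoencoder))
          encode_spectra(whole_bundle$autoencoder, sc_tr) else sc_tr
        lmc <- config$lm; lmc$seed <- child
        model <- ann_classifier(
          if (!is.null(whole_bundle$autoencoder))
            whole_bundle$autoencoder$code_dim else ncol(sc_tr$absorbance),
          hidden_units = config$hidden_units,
          threshold = config$threshold)
        model <- lm_fit(model, feats, lmc)
        bundle <- model_bundle(classifier = model,
                               autoencoder = whole_bundle$autoencoder,
                               preprocess = spec, seed = child)
      }
      pred <- predict_pipeline(bundle, parts$test)
      cm <- confusion(pred$labels, parts$test$labels)
      met <- classification_metrics(cm, scores = pred$scores,
                                    actual = parts$test$labels)
      list(repeat_index = r, split_seed = child, confusion = cm,
           metrics = met)
    }, nirparity_error = function(e) {
      np_stop(class(e)[1], "repeat %d: %s", r, conditionMessage(e))
    })
    per_repeat[[r]] <- rec
  }
  structure(list(per_repeat = per_repeat,
                 summary = summarize_repeats(per_repeat),
                 repeats = repeats, config = config,
                 seed = as.integer(seed)),
            class = "mccv_result")
}

#' @noRd
summarize_repeats <- function(per_repeat) {
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "auc")
  vals <- sapply(metrics, function(m)
    vapply(per_repeat, function(r) {
      v <- r$metrics[[m]]
      if (is.null(v)) NA_real_ else v
    }, 0))
  vals <- matrix(vals, nrow = length(per_repeat),
                 dimnames = list(NULL, metrics))
  data.frame(metric = metrics,
             mean = apply(vals, 2, mean, na.rm = TRUE),
             sd = apply(vals, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo cross-validation: %d repeats (%s pipeline)\n",
              x$repeats, x$config$pipeline))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %5.1f +/- %.1f %%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  invisible(x)
}

#' Cross-cohort independent testing
#'
#' Fits the full pipeline (scaler, autoencoder, classifier) on one
#' entire cohort and evaluates it on a second, independently collected
#' cohort, using the training cohort's encoder throughout -- the only
#' deployable choice when a new cohort arrives unlabeled. Both cohorts
#' must share the preprocessed wavelength window. If the test cohort
#' contains a single class, AUC (and the metric undefined for the
#' missing class) is omitted and the remaining counts are still
#' reported.
#'
#' @param train_cohort,test_cohort preprocessed, labeled
#'   `spectral_dataset`s on identical wavelength grids.
#' @param config a [pipeline_config()].
#' @param seed seed for autoencoder/classifier initialization.
#' @return an `evaluation_metrics` object for the test cohort, with the
#'   fitted bundle attached as attribute `"bundle"`.
#' @export
cross_cohort_eval <- function(train_cohort, test_cohort,
                              config = pipeline_config(), seed = 1) {
  if (!identical(as.numeric(train_cohort$wavelengths),
                 as.numeric(test_cohort$wavelengths)))
    np_stop("nirparity_window_mismatch",
            "train and test cohorts are on different wavelength windows")
  bundle <- fit_pipeline(train_cohort, config, seed = seed)
  pred <- predict_pipeline(bundle, test_cohort)
  cm <- confusion(pred$labels, test_cohort$labels)
  met <- if (cm$P > 0 && cm$N > 0)
    classification_metrics(cm, scores = pred$scores,
                           actual = test_cohort$labels)
  else structure(list(
    sensitivity = if (cm$P > 0) cm$TP / cm$P else NA_real_,
    specificity = if (cm$N > 0) cm$TN / cm$N else NA_real_,
    accuracy = (cm$TP + cm$TN) / length(test_cohort$labels),
    precision = if (cm$TP + cm$FP > 0) cm$TP / (cm$TP + cm$FP)
    else NA_real_,
    auc = NULL, roc_points = NULL, confusion = cm),
    class = "evaluation_metrics")
  attr(met, "bundle") <- bundle
  met
}
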