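test_that("75/25 split obeys the floor rule and is a disjoint partition", {
  ds <- tiny_dataset(n = 100, d = 3, seed = 1)
  parts <- split_dataset(ds, 0.75, seed = 4)
  expect_equal(n_samples(parts$train), 75)
  expect_equal(n_samples(parts$test), 25)
  expect_length(intersect(parts$train$sample_ids,
                          parts$test$sample_ids), 0)
  expect_setequal(c(parts$train$sample_ids, parts$test$sample_ids),
                  ds$sample_ids)

  ds4 <- tiny_dataset(n = 4, d = 3)
  p4 <- split_dataset(ds4, 0.75, seed = 1)
  expect_equal(n_samples(p4$train), 3)  # floor(0.75 * 4)
  expect_equal(n_samples(p4$test), 1)
})

test_that("splits are seed-deterministic and unstratified by default", {
  ds <- tiny_dataset(n = 40, d = 3, seed = 2)
  a <- split_dataset(ds, 0.75, seed = 9)
  b <- split_dataset(ds, 0.75, seed = 9)
  expect_identical(a$train$sample_ids, b$train$sample_ids)
  c2 <- split_dataset(ds, 0.75, seed = 10)
  expect_false(identical(a$train$sample_ids, c2$train$sample_ids))
  # class proportions drift across seeds (no stratification)
  frac <- vapply(1:30, function(s)
    mean(split_dataset(ds, 0.75, seed = s)$test$labels), 0)
  expect_gt(length(unique(frac)), 1)
  expect_error(split_dataset(ds, 1.2), class = "nirparity_bad_fraction")
  expect_error(split_dataset(tiny_dataset(n = 1, d = 3), 0.75),
               class = "nirparity_too_small")
})

test_that("confusion counts match the published-style tally", {
  # reconstruct a prediction vector with TN=165, FN=17, FP=31, TP=61
  actual <- c(rep(0L, 165), rep(1L, 17), rep(0L, 31), rep(1L, 61))
  predicted <- c(rep(0L, 165), rep(0L, 17), rep(1L, 31), rep(1L, 61))
  cm <- confusion(predicted, actual)
  expect_equal(cm$TN, 165); expect_equal(cm$FN, 17)
  expect_equal(cm$FP, 31); expect_equal(cm$TP, 61)
  expect_equal(cm$N, 196)                       # nulliparous total
  expect_equal(cm$P, 78)                        # parous total
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 274)

  perfect <- confusion(actual, actual)
  expect_equal(perfect$FP + perfect$FN, 0)
  allpar <- confusion(rep(1L, 274), actual)
  expect_equal(allpar$FP, 196); expect_equal(allpar$TN, 0)
  expect_error(confusion(c(0, 1), c(0, 1, 1)),
               class = "nirparity_dim_mismatch")
  expect_error(confusion(c(0, 2), c(0, 1)),
               class = "nirparity_bad_label")
})

test_that("metric formulas agree with hand arithmetic on the printed matrix", {
  cm <- confusion(c(rep(0L, 182), rep(1L, 92)),
                  c(rep(0L, 165), rep(1L, 17), rep(0L, 31), rep(1L, 61)))
  m <- classification_metrics(cm)
  expect_equal(m$sensitivity, 61 / 78, tolerance = 1e-15)
  expect_equal(m$specificity, 165 / 196, tolerance = 1e-15)
  expect_equal(m$accuracy, 226 / 274, tolerance = 1e-15)
  expect_equal(m$precision, 61 / 92, tolerance = 1e-15)
  # algebraic identity: accuracy is the P/N-weighted mean of the recalls
  expect_equal(m$accuracy,
               (m$sensitivity * cm$P + m$specificity * cm$N) /
                 (cm$P + cm$N), tolerance = 1e-15)
})

test_that("metrics recompute from 1000 random confusion matrices", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    actual <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    predicted <- sample(0:1, n, replace = TRUE)
    cm <- confusion(predicted, actual)
    # independent counting oracle via table()
    expect_identical(cm$TP, sum(predicted + actual == 2L))
    expect_identical(cm$TN, sum(predicted + actual == 0L))
    m <- classification_metrics(cm)
    expect_equal(m$sensitivity, cm$TP / sum(actual == 1))
    expect_equal(m$specificity, cm$TN / sum(actual == 0))
    expect_equal(m$accuracy, mean(predicted == actual))
    if (cm$TP + cm$FP > 0)
      expect_equal(m$precision, cm$TP / (cm$TP + cm$FP))
    else
      expect_true(is.na(m$precision))
  }
})

test_that("degenerate confusion inputs are handled per contract", {
  expect_error(classification_metrics(confusion(c(0, 1), c(1, 1))),
               class = "nirparity_degenerate_test_set")
  err <- expect_error(
    classification_metrics(confusion(c(0, 0), c(0, 0))),
    class = "nirparity_degenerate_test_set")
  expect_match(conditionMessage(err), "parous")
  m <- classification_metrics(confusion(c(0, 0), c(0, 1)))
  expect_true(is.na(m$precision))  # TP + FP = 0 -> undefined, not 0
  expect_equal(m$accuracy, 0.5)
})

test_that("ROC/AUC: perfect ranking, all-tied scores, curve shape", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  pts <- r$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(runif(4), rep(1, 4)),
               class = "nirparity_degenerate_test_set")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # coarse -> frequent ties
    expect_equal(roc_auc(scores, labels)$auc,
                 concordance_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("monte_carlo_cv yields one record per repeat and a recomputable summary", {
  ds <- generate_spectra(synthetic_config(n_parous = 40,
                                          n_nulliparous = 40,
                                          grid_low_nm = 500,
                                          grid_high_nm = 650,
                                          effect_size = 2, seed = 3))
  cfg <- fast_config(window_high = 650, steps = c(16, 5), epochs = 40)
  res <- monte_carlo_cv(preprocess(ds, cfg$preprocess), cfg,
                        repeats = 10, seed = 21)
  expect_equal(res$repeats, 10)
  expect_length(res$per_repeat, 10)
  accs <- vapply(res$per_repeat, function(r) r$metrics$accuracy, 0)
  srow <- res$summary[res$summary$metric == "accuracy", ]
  expect_equal(srow$mean, mean(accs), tolerance = 1e-15)
  expect_equal(srow$sd, sd(accs), tolerance = 1e-15)
  # per-repeat child seeds follow the documented seed + r - 1 rule
  expect_equal(vapply(res$per_repeat, `[[`, 0L, "split_seed"), 21:30)
  # stored metrics recompute exactly from the stored confusion matrix
  for (r in res$per_repeat) {
    m2 <- classification_metrics(r$confusion)
    expect_identical(m2$accuracy, r$metrics$accuracy)
    expect_identical(m2$sensitivity, r$metrics$sensitivity)
  }
})

test_that("monte_carlo_cv is reproducible for identical inputs", {
  ds <- generate_spectra(synthetic_config(n_parous = 20,
                                          n_nulliparous = 20,
                                          grid_low_nm = 500,
                                          grid_high_nm = 600,
                                          effect_size = 2, seed = 5))
  cfg <- fast_config(window_high = 600, steps = c(8, 4), epochs = 30)
  pp <- preprocess(ds, cfg$preprocess)
  r1 <- monte_carlo_cv(pp, cfg, repeats = 3, seed = 2)
  r2 <- monte_carlo_cv(pp, cfg, repeats = 3, seed = 2)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$summary, r2$summary)
})

test_that("cross-cohort transfer stays close to within-cohort accuracy when there is no shift", {
  cfg <- synthetic_config(n_parous = 60, n_nulliparous = 60,
                          grid_low_nm = 500, grid_high_nm = 650,
                          effect_size = 2, seed = 13)
  pair <- generate_cohort_pair(cfg)  # zero shift configured
  pc <- fast_config(window_high = 650, steps = c(16, 6), epochs = 50)
  a <- preprocess(pair$cohort_a, pc$preprocess)
  b <- preprocess(pair$cohort_b, pc$preprocess)
  within <- monte_carlo_cv(a, pc, repeats = 3, seed = 1)
  cross <- cross_cohort_eval(a, b, pc, seed = 1)
  within_mean <- within$summary$mean[within$summary$metric == "accuracy"]
  expect_gt(cross$accuracy, within_mean - 0.10)

  # resubstitution sanity bound: testing on the training cohort itself
  resub <- cross_cohort_eval(a, a, pc, seed = 1)
  expect_gte(resub$accuracy, cross$accuracy - 0.05)
})

test_that("cross-cohort evaluation rejects mismatched wavelength windows", {
  a <- tiny_dataset(n = 10, d = 5)
  b <- spectral_dataset(matrix(runif(50), 10, 5), 600:604,
                        labels = rep_len(c(0L, 1L), 10))
  expect_error(cross_cohort_eval(a, b), class = "nirparity_window_mismatch")
})
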