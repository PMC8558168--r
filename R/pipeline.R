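#' Run the full reverse-chemical-ecology modeling pipeline
#'
#' Chains every modeling stage on one synthetic study: generate a labeled
#' descriptor table with a planted structure-activity rule; filter
#' descriptors; min-max normalize on the full dataset and take the
#' sphere-exclusion split (center initialization); re-normalize using
#' training-set min/max only; select a classifier by leave-one-out MCC on the
#' training set; train the winner on the full training set and evaluate it on
#' the held-out test set; fit the kNN-distance applicability domain on the
#' training rows; finally screen a synthetic library drawn from the same
#' geometry and test whether the planted actives are enriched among the
#' predicted agonists.
#'
#' @param preset a [receptor_preset()] list (its `spec$seed` drives the
#'   dataset draw; the library uses `spec$seed + 1000`).
#' @param search_space list of [model_spec()] candidates; defaults to
#'   [default_search_space()] seeded like the preset.
#' @param ad_distance applicability-domain distance convention, see
#'   [fit_ad()].
#' @return list with elements `split`, `selection` (the [loo_select()]
#'   result), `classifier`, `test_confusion`, `test_metrics`, `test_auroc`,
#'   `ad`, `hits`, `enrichment`, `filter_report`.
#' @export
run_qsar_pipeline <- function(preset, search_space = NULL,
                              ad_distance = "mean_knn") {
  spec <- preset$spec
  if (is.null(search_space)) search_space <- default_search_space(spec$seed)

  gen <- gen_qsar_dataset(spec)
  filt <- filter_features(gen$table, corr_cutoff = preset$corr_cutoff)
  table <- filt$table
  labels <- gen$dataset$label

  # normalize on the whole dataset only to take the split, then re-scale
  # everything with training-set statistics alone
  split_norm <- apply_minmax(table, fit_minmax(table))
  split <- sphere_exclusion_split(split_norm, radius = preset$radius,
                                  fraction = preset$fraction, init = "center")

  norm <- fit_minmax(table, split$train_ids)
  table_n <- apply_minmax(table, norm)
  train_x <- table_n[split$train_ids, , drop = FALSE]
  test_x <- table_n[split$test_ids, , drop = FALSE]
  train_y <- labels[match(split$train_ids, gen$dataset$id)]
  test_y <- labels[match(split$test_ids, gen$dataset$id)]

  selection <- loo_select(train_x, train_y, search_space)
  classifier <- train_classifier(train_x, train_y, selection$best,
                                 norm_params = norm)

  test_pred <- predict(classifier, test_x)
  test_cm <- confusion(test_y, test_pred$predicted)
  test_metrics <- classification_metrics(test_cm)
  test_auroc <- if (length(unique(test_y)) == 2) {
    auroc(test_y, test_pred$score)
  } else NA_real_

  ad <- fit_ad(train_x, k = preset$ad_k, ad_distance = ad_distance)

  lib <- gen_library(preset$library_size,
                     planted_active_fraction = spec$active_fraction,
                     spec = spec, seed = spec$seed + 1000L)
  lib_x <- apply_minmax(lib$table[, colnames(table), drop = FALSE], norm)
  hits <- screen_library(classifier, ad, lib_x)
  truth_active <- rownames(lib$table)[lib$true_labels == "active"]
  enrichment <- enrichment_test(hits, truth_active)

  list(split = split, selection = selection, classifier = classifier,
       test_confusion = test_cm, test_metrics = test_metrics,
       test_auroc = test_auroc, ad = ad, hits = hits,
       enrichment = enrichment, filter_report = filt$report)
}

#' Reference performance tables of the two receptor QSAR models
#'
#' The published confusion matrices of the two odorant-receptor agonist
#' classifiers this package re-implements the methodology of: a
#' random-forest model (receptor 24 study shape) and an inverse-distance
#' 9-NN model (receptor 25 shape), each evaluated in leave-one-out
#' cross-validation, on its training set, and on its sphere-exclusion test
#' set. These counts are inputs for worked examples — the package's metric
#' functions recompute every derived cell (accuracy, precision, recall, FPR,
#' MCC) from them. The AUROC column requires per-compound scores that the
#' source table does not carry and is therefore not recomputable.
#'
#' @return data.frame with columns `model`, `dataset`, `tp`, `tn`, `fp`,
#'   `fn`, and the published `accuracy`, `precision`, `recall`, `fpr`,
#'   `mcc`, `auroc` (two-decimal values).
#' @export
reference_confusions <- function() {
  data.frame(
    model = rep(c("or24", "or25"), each = 3),
    dataset = rep(c("LOO", "Training", "Test"), 2),
    tp = c(4, 7, 1, 15, 18, 5),
    tn = c(29, 31, 9, 34, 46, 10),
    fp = c(2, 0, 1, 12, 0, 2),
    fn = c(4, 1, 1, 3, 0, 2),
    accuracy = c(0.85, 0.97, 0.83, 0.77, 1.00, 0.79),
    precision = c(0.67, 1.00, 0.50, 0.56, 1.00, 0.71),
    recall = c(0.50, 0.88, 0.50, 0.83, 1.00, 0.71),
    fpr = c(0.06, 0.00, 0.10, 0.26, 0.00, 0.17),
    mcc = c(0.49, 0.92, 0.40, 0.52, 1.00, 0.55),
    auroc = c(0.83, 0.99, 0.80, 0.84, 1.00, 0.89),
    stringsAsFactors = FALSE
  )
}
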