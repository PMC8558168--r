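#' Confusion matrix for a binary agonist/non-agonist classification
#'
#' Counts true/false positives and negatives, with `"active"` as the positive
#' class (an agonist call).
#'
#' @param truth character vector of true labels, each `"active"` or
#'   `"inactive"`.
#' @param predicted character vector of predicted labels, same length and
#'   alphabet as `truth`.
#' @return An object of class `confusion_matrix`: a list with integer counts
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c("active", "active", "inactive"), c("active", "inactive", "inactive"))
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length (", length(truth),
         " vs ", length(predicted), ")")
  }
  ok <- c("active", "inactive")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'active' or 'inactive'")
  }
  cm <- list(
    tp = sum(truth == "active" & predicted == "active"),
    tn = sum(truth == "inactive" & predicted == "inactive"),
    fp = sum(truth == "inactive" & predicted == "active"),
    fn = sum(truth == "active" & predicted == "inactive")
  )
  cm <- lapply(cm, as.integer)
  structure(cm, class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive class = active)\n")
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall, false-positive rate and the Matthews
#' correlation coefficient (MCC). Metrics with a zero denominator are not
#' errors: they are returned as `NA` (MCC as 0) and flagged in `undefined`,
#' so that degenerate candidates remain rankable in model-selection loops.
#'
#' @param cm a `confusion_matrix`.
#' @return A list of class `metric_set` with elements `accuracy`, `precision`,
#'   `recall`, `fpr`, `mcc`, `auroc` (always `NA` here; see [auroc()]) and a
#'   character vector `undefined` naming flagged metrics.
#' @examples
#' classification_metrics(confusion_counts(tp = 4, tn = 29, fp = 2, fn = 4))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  n <- tp + tn + fp + fn
  if (n <= 0) stop("confusion matrix has zero total count")
  undefined <- character(0)

  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else { undefined <- c(undefined, "precision"); NA_real_ }
  rec  <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "recall"); NA_real_ }
  fpr  <- if (fp + tn > 0) fp / (fp + tn) else { undefined <- c(undefined, "fpr"); NA_real_ }
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else {
    undefined <- c(undefined, "mcc")
    0
  }
  structure(list(accuracy = acc, precision = prec, recall = rec, fpr = fpr,
                 mcc = mcc, auroc = NA_real_, undefined = undefined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 2, ...) {
  vals <- unlist(x[c("accuracy", "precision", "recall", "fpr", "mcc", "auroc")])
  cat(paste(sprintf("%s %.2f", names(vals), vals), collapse = "  "), "\n")
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve by pair counting
#'
#' Mann-Whitney formulation: the fraction of (active, inactive) score pairs in
#' which the active compound outscores the inactive one, ties counted one half.
#'
#' @param truth label vector over `{"active", "inactive"}`, both classes
#'   present.
#' @param scores numeric scores, higher = more active.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c("active", "active", "inactive", "inactive", "inactive"),
#'       c(0.9, 0.4, 0.8, 0.3, 0.1))  # 5/6
#' @export
auroc <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("length mismatch")
  pos <- truth == "active"
  neg <- truth == "inactive"
  if (!any(pos) || !any(neg)) stop("AUROC requires both classes present")
  # rank-sum identity of the pair-counting statistic, ties shared as 0.5
  r <- rank(scores, ties.method = "average")
  p <- sum(pos); n <- sum(neg)
  (sum(r[pos]) - p * (p + 1) / 2) / (p * n)
}

#' Round half-up for report formatting
#'
#' Report tables round half-up (0.875 -> 0.88) rather than to even as
#' [base::round()] does; internal values are kept at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a metric set as a one-row report table
#'
#' Mirrors the column layout of a standard QSAR performance table:
#' counts then metrics, rounded half-up to two decimals.
#'
#' @param cm `confusion_matrix`.
#' @param dataset name for the row (e.g. "LOO", "Training", "Test").
#' @param auroc_value optional AUROC to include.
#' @return one-row `data.frame` with columns Dataset, TP, TN, FP, FN,
#'   Accuracy, Precision, Recall, FPR, MCC, AUROC.
#' @export
metric_report_row <- function(cm, dataset = "", auroc_value = NA_real_) {
  m <- classification_metrics(cm)
  data.frame(
    Dataset = dataset, TP = cm$tp, TN = cm$tn, FP = cm$fp, FN = cm$fn,
    Accuracy = round_half_up(m$accuracy), Precision = round_half_up(m$precision),
    Recall = round_half_up(m$recall), FPR = round_half_up(m$fpr),
    MCC = round_half_up(m$mcc), AUROC = round_half_up(auroc_value),
    stringsAsFactors = FALSE
  )
}
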