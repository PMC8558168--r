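# Independent oracles, deliberately naive: each re-derives a quantity by
# enumeration or a textbook formula, never by calling the package's own path.

# AUROC by explicit enumeration of all (active, inactive) pairs.
brute_force_auroc <- function(truth, scores) {
  pos <- scores[truth == "active"]
  neg <- scores[truth == "inactive"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# AUROC by trapezoidal integration of the empirical ROC curve.
trapezoid_auroc <- function(truth, scores) {
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- truth == "active"
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Leave-one-out 1-nearest-neighbour by a plain double loop.
brute_force_1nn_loo <- function(table, labels) {
  n <- nrow(table)
  vapply(seq_len(n), function(i) {
    best_d <- Inf; best_j <- NA
    for (j in seq_len(n)[-i]) {
      d <- sqrt(sum((table[i, ] - table[j, ])^2))
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    labels[best_j]
  }, character(1))
}

# MCC straight from the definition.
mcc_formula <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) / sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# Small random descriptor table for property tests.
random_table <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              sprintf("d%02d", seq_len(p))))
  m
}
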