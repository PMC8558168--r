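#' Sphere-exclusion train/test split
#'
#' Diverse-subset test-set selection in normalized descriptor space. The test
#' set is seeded either with the compound closest to the dataset centroid
#' (`init = "center"`, the deterministic default) or with a uniformly drawn
#' compound (`init = "random"`). Each selected compound excludes every
#' remaining candidate strictly within `radius` of it (itself included); the
#' next test compound is the candidate maximizing its minimum Euclidean
#' distance to the current test set (MinMax selection). Selection stops when
#' the test set reaches `floor(fraction * N)` compounds or no candidate
#' remains; every unselected compound — excluded or not — goes to training,
#' so train and test always partition the dataset.
#'
#' Ties (initialization and MinMax) break toward the lowest row index, making
#' the split fully deterministic given `init`, `seed` and row order.
#'
#' @param table normalized descriptor matrix (rownames = compound ids).
#' @param radius exclusion radius (dissimilarity radius) in normalized
#'   descriptor space, `>= 0`.
#' @param fraction target test-set share of the dataset, in (0, 1). The stop
#'   rule `floor(fraction * N)` with the conventional `fraction = 0.24`
#'   yields test sizes 12 of 51 and 19 of 83.
#' @param init `"center"` or `"random"`.
#' @param seed integer seed for `init = "random"`; ignored otherwise.
#' @return object of class `sphere_split`: list with `train_ids`, `test_ids`,
#'   `radius`, `fraction`, `init`, `seed`, and `warning` (`NULL`, or a message
#'   when the radius exhausted the candidates before the target size).
#' @export
sphere_exclusion_split <- function(table, radius, fraction, init = c("center", "random"),
                                   seed = NULL) {
  init <- match.arg(init)
  stopifnot(is.matrix(table))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 compounds to split")
  if (radius < 0) stop("radius must be >= 0")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")

  target <- floor(fraction * n)
  d <- as.matrix(stats::dist(table))
  candidates <- rep(TRUE, n)
  test_idx <- integer(0)

  first <- if (init == "center") {
    centroid <- colMeans(table)
    d0 <- sqrt(colSums((t(table) - centroid)^2))
    which.min(d0) # ties -> lowest row index (which.min convention)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sample.int(n, 1)
  }

  sel <- first
  repeat {
    test_idx <- c(test_idx, sel)
    candidates[d[sel, ] < radius] <- FALSE # strict: exactly-at-radius survives
    candidates[sel] <- FALSE
    if (length(test_idx) >= target || !any(candidates)) break
    cand <- which(candidates)
    min_d <- apply(d[cand, test_idx, drop = FALSE], 1, min)
    sel <- cand[which.max(min_d)] # ties -> lowest row index
  }

  warn <- NULL
  if (length(test_idx) < target) {
    warn <- sprintf("exclusion radius %g exhausted candidates at test size %d (target %d)",
                    radius, length(test_idx), target)
  }
  ids <- rownames(table)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(train_ids = ids[setdiff(seq_len(n), test_idx)],
                 test_ids = ids[test_idx],
                 radius = radius, fraction = fraction, init = init,
                 seed = seed, warning = warn),
            class = "sphere_split")
}

#' @export
print.sphere_split <- function(x, ...) {
  cat(sprintf("Sphere-exclusion split: %d train / %d test (radius %g, fraction %g, init %s)\n",
              length(x$train_ids), length(x$test_ids), x$radius, x$fraction, x$init))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Alternative splits with a matched test-set class balance
#'
#' Generates random-initialization sphere-exclusion splits with consecutive
#' seeds (`seed`, `seed + 1`, ...) and keeps the first `n_splits` whose
#' test-set (actives, inactives) counts equal `reference_counts` — the
#' uncertainty-quantification procedure for the initial train/test choice.
#' Deterministic given `seed`.
#'
#' @param table normalized descriptor matrix.
#' @param labels label vector aligned to rows (`"active"`/`"inactive"`).
#' @param n_splits number of matching splits to return.
#' @param radius,fraction as in [sphere_exclusion_split()].
#' @param reference_counts integer pair `c(test_actives, test_inactives)` of
#'   the reference split.
#' @param seed first seed of the search ladder.
#' @param max_attempts search budget; exhausting it raises an error that
#'   reports how many matching splits were found.
#' @return list of `sphere_split` objects, length `n_splits`.
#' @export
alternative_splits <- function(table, labels, n_splits, radius, fraction,
                               reference_counts, seed = 1, max_attempts = 1000L) {
  stopifnot(length(labels) == nrow(table), length(reference_counts) == 2)
  if (n_splits == 0) return(list())
  out <- list()
  for (attempt in seq_len(max_attempts)) {
    sp <- sphere_exclusion_split(table, radius, fraction, init = "random",
                                 seed = seed + attempt - 1L)
    test_lab <- labels[match(sp$test_ids, rownames(table))]
    counts <- c(sum(test_lab == "active"), sum(test_lab == "inactive"))
    if (all(counts == reference_counts)) {
      out[[length(out) + 1L]] <- sp
      if (length(out) == n_splits) return(out)
    }
  }
  stop(sprintf("found only %d of %d splits matching test counts (%d, %d) in %d attempts",
               length(out), n_splits, reference_counts[1], reference_counts[2],
               max_attempts))
}

#' Write / read a split as CSV
#'
#' Two columns `id,set` with `set` in `{train, test}`; split metadata
#' (radius, fraction, init, seed) goes in `#`-prefixed header lines.
#' @param split a `sphere_split`.
#' @param path file path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "sphere_split"))
  meta <- sprintf("# radius=%g fraction=%g init=%s seed=%s",
                  split$radius, split$fraction, split$init,
                  if (is.null(split$seed)) "NA" else split$seed)
  lines <- c(meta, "id,set",
             paste(split$train_ids, "train", sep = ","),
             paste(split$test_ids, "test", sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  kv <- strsplit(sub("^#\\s*", "", meta[1]), " ")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  structure(list(train_ids = body$id[body$set == "train"],
                 test_ids = body$id[body$set == "test"],
                 radius = as.numeric(vals[["radius"]]),
                 fraction = as.numeric(vals[["fraction"]]),
                 init = vals[["init"]],
                 seed = if (vals[["seed"]] == "NA") NULL else as.integer(vals[["seed"]]),
                 warning = NULL),
            class = "sphere_split")
}
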