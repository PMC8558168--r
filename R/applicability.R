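#' Fit a k-nearest-neighbour distance applicability domain
#'
#' Similarity-distance applicability domain. The cutoff is
#' `Dc = <D> + Z * sigma`, where `<D>` and `sigma` are the mean and sample
#' standard deviation of each training compound's Euclidean distance to its
#' single nearest neighbour (self excluded) in normalized descriptor space.
#' `Z` is an empirical multiplier: starting at `z_start` it is incremented by
#' `z_step` until every training compound's own kNN distance (see
#' `ad_distance`) is `<= Dc`, so the training set is in-domain by
#' construction.
#'
#' The per-compound (and query) kNN distance has three conventions, because
#' "distance to the kNN" is ambiguous when `k > 1`:
#' `"mean_knn"` (default) — mean distance to the k nearest neighbours;
#' `"kth_nn"` — distance to the k-th nearest neighbour alone;
#' `"nn"` — distance to the single nearest neighbour regardless of `k`.
#'
#' @param train_table normalized training descriptor matrix, at least
#'   `k + 1` rows.
#' @param k number of neighbours; conventional defaults are the model's own
#'   k for a kNN model (e.g. 9) and a benchmarked value (e.g. 6) otherwise.
#' @param z_start,z_step starting value and increment of the Z ladder.
#' @param ad_distance kNN-distance convention, see above.
#' @return object of class `ad_params`: list with `k`, `z`, `mean_nn_dist`,
#'   `sd_nn_dist`, `dc`, `ad_distance` and the stored `train_table`.
#' @export
fit_ad <- function(train_table, k, z_start = 0.5, z_step = 0.5,
                   ad_distance = c("mean_knn", "kth_nn", "nn")) {
  ad_distance <- match.arg(ad_distance)
  stopifnot(is.matrix(train_table))
  n <- nrow(train_table)
  if (k < 1) stop("k must be >= 1")
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " training rows, got ", n)

  d <- as.matrix(stats::dist(train_table))
  diag(d) <- Inf
  nn1 <- apply(d, 1, min)
  mean_nn <- mean(nn1)
  sd_nn <- if (n > 1) stats::sd(nn1) else 0

  check_d <- apply(d, 1, function(row) knn_distance(sort(row)[seq_len(k)], ad_distance))

  z <- z_start
  repeat {
    dc <- mean_nn + z * sd_nn
    if (all(check_d <= dc)) break
    if (sd_nn == 0) {
      stop("degenerate training geometry: sigma = 0 but kNN distances exceed Dc")
    }
    z <- z + z_step
    if (z > 1e6) stop("Z ladder failed to converge")
  }

  structure(list(k = as.integer(k), z = z, mean_nn_dist = mean_nn,
                 sd_nn_dist = sd_nn, dc = dc, ad_distance = ad_distance,
                 train_table = train_table),
            class = "ad_params")
}

#' @export
print.ad_params <- function(x, ...) {
  cat(sprintf("Applicability domain: k=%d, Z=%g, <D>=%.4g, sigma=%.4g, Dc=%.4g (%s)\n",
              x$k, x$z, x$mean_nn_dist, x$sd_nn_dist, x$dc, x$ad_distance))
  invisible(x)
}

knn_distance <- function(sorted_k_dists, ad_distance) {
  switch(ad_distance,
         mean_knn = mean(sorted_k_dists),
         kth_nn = sorted_k_dists[length(sorted_k_dists)],
         nn = sorted_k_dists[1])
}

#' Score compounds against an applicability domain
#'
#' For each query compound the kNN distance `D` to the training set is
#' measured (same convention the domain was fitted with) and converted to
#' `reliability = 1 + (D - Dc) / Dc`, which simplifies to `D / Dc`: 0 for a
#' compound sitting on a training point, 1 exactly on the domain boundary,
#' above 1 outside. `in_domain` is `D <= Dc`.
#'
#' @param params an [fit_ad()] result.
#' @param query_table matrix of query compounds over the training columns
#'   (a single row is also accepted as a named vector).
#' @return data.frame with columns `id`, `distance`, `reliability`,
#'   `in_domain`.
#' @export
score_ad <- function(params, query_table) {
  stopifnot(inherits(params, "ad_params"))
  if (is.null(dim(query_table))) {
    query_table <- matrix(query_table, nrow = 1,
                          dimnames = list("query", names(query_table)))
  }
  if (!identical(colnames(query_table), colnames(params$train_table))) {
    if (!setequal(colnames(query_table), colnames(params$train_table))) {
      stop("query columns do not match the applicability-domain training columns")
    }
    query_table <- query_table[, colnames(params$train_table), drop = FALSE]
  }
  ids <- rownames(query_table)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(query_table)))
  if (nrow(query_table) == 0) {
    return(data.frame(id = character(0), distance = numeric(0),
                      reliability = numeric(0), in_domain = logical(0),
                      stringsAsFactors = FALSE))
  }
  tr <- params$train_table
  dist_q <- apply(query_table, 1, function(q) {
    d <- sort(sqrt(colSums((t(tr) - q)^2)))[seq_len(params$k)]
    knn_distance(d, params$ad_distance)
  })
  if (params$dc == 0 && any(dist_q > 0)) {
    stop("Dc = 0 with a nonzero query distance: reliability undefined")
  }
  reliability <- if (params$dc == 0) rep(0, length(dist_q)) else dist_q / params$dc
  data.frame(id = ids, distance = dist_q, reliability = reliability,
             in_domain = dist_q <= params$dc, stringsAsFactors = FALSE)
}
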