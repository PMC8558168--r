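#' Specify a classifier candidate
#'
#' Families mirror the classical QSAR toolbox: k-nearest neighbours
#' (`knn`: `k`, `weighting` in `{"uniform", "inverse_distance"}`), bagged
#' random forest (`random_forest`: `n_trees`, `max_depth` integer or
#' `"unlimited"`, `features_per_split` in `{"all", "sqrt", "log2"}`), support
#' vector classifier (`svc`: `cost`, RBF kernel), a single CART tree
#' (`decision_tree`) and a single randomized tree (`random_tree`).
#'
#' @param family one of `"knn"`, `"random_forest"`, `"svc"`,
#'   `"decision_tree"`, `"random_tree"`.
#' @param ... family hyperparameters (see above).
#' @param seed integer seed fixed before any stochastic family is trained.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("knn", "random_forest", "svc", "decision_tree",
                                  "random_tree"),
                       ..., seed = 1L) {
  family <- match.arg(family)
  hp <- list(...)
  allowed <- switch(family,
    knn = c("k", "weighting"),
    random_forest = c("n_trees", "max_depth", "features_per_split"),
    svc = c("cost", "gamma"),
    decision_tree = character(0),
    random_tree = character(0))
  bad <- setdiff(names(hp), allowed)
  if (length(bad)) stop("invalid hyperparameter(s) for ", family, ": ",
                        paste(bad, collapse = ", "))
  defaults <- switch(family,
    knn = list(k = 1L, weighting = "uniform"),
    random_forest = list(n_trees = 100L, max_depth = "unlimited",
                         features_per_split = "all"),
    svc = list(cost = 1, gamma = NULL),
    decision_tree = list(),
    random_tree = list())
  hp <- utils::modifyList(defaults, hp)
  if (family == "knn") {
    if (hp$k < 1) stop("knn k must be >= 1")
    if (!hp$weighting %in% c("uniform", "inverse_distance")) {
      stop("knn weighting must be 'uniform' or 'inverse_distance'")
    }
  }
  if (family == "random_forest" &&
      !hp$features_per_split %in% c("all", "sqrt", "log2")) {
    stop("features_per_split must be 'all', 'sqrt' or 'log2'")
  }
  structure(list(family = family, hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  hp <- x$hyperparameters
  hp <- hp[!vapply(hp, is.null, logical(1))]
  if (length(hp)) {
    paste0(x$family, "(", paste(names(hp), unlist(hp), sep = "=", collapse = ", "), ")")
  } else {
    x$family
  }
}

#' Default hyperparameter search space
#'
#' The grid explored by leave-one-out selection: kNN with
#' `k in {1, 3, 5, 7, 9}` crossed with uniform and inverse-distance
#' weighting, 100-tree random forests with all-features and sqrt-features
#' splits, a CART tree, and RBF support vector classifiers at three costs.
#'
#' @param seed seed stored in every candidate.
#' @return list of [model_spec()] objects.
#' @export
default_search_space <- function(seed = 1L) {
  space <- list()
  for (k in c(1L, 3L, 5L, 7L, 9L)) {
    for (w in c("uniform", "inverse_distance")) {
      space[[length(space) + 1L]] <- model_spec("knn", k = k, weighting = w, seed = seed)
    }
  }
  for (f in c("all", "sqrt")) {
    space[[length(space) + 1L]] <- model_spec("random_forest", n_trees = 100L,
                                              features_per_split = f, seed = seed)
  }
  space[[length(space) + 1L]] <- model_spec("decision_tree", seed = seed)
  for (cost in c(0.1, 1, 10)) {
    space[[length(space) + 1L]] <- model_spec("svc", cost = cost, seed = seed)
  }
  space
}

check_training_labels <- function(labels) {
  if (!all(labels %in% c("active", "inactive"))) {
    stop("training labels must be 'active' or 'inactive'")
  }
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training labels")
  }
}

#' Train a classifier
#'
#' Deterministic given `spec$seed`. Stores the training compound ids (and,
#' optionally, the normalization parameters used to scale the features) so
#' downstream screens are auditable.
#'
#' @param table normalized descriptor matrix (training rows).
#' @param labels `"active"`/`"inactive"` vector aligned to rows; both classes
#'   required.
#' @param spec a [model_spec()].
#' @param norm_params optional [fit_minmax()] parameters to carry along.
#' @return object of class `or_classifier`.
#' @export
train_classifier <- function(table, labels, spec, norm_params = NULL) {
  stopifnot(is.matrix(table), inherits(spec, "model_spec"))
  check_training_labels(labels)
  n <- nrow(table)
  if (length(labels) != n) stop("labels must match table rows")
  hp <- spec$hyperparameters
  y <- factor(labels, levels = c("active", "inactive"))

  fit <- switch(spec$family,
    knn = {
      if (hp$k > n) stop("knn k = ", hp$k, " exceeds the ", n, " training compounds")
      list(x = table, y = labels)
    },
    random_forest = {
      mtry <- switch(hp$features_per_split,
                     all = ncol(table),
                     sqrt = max(1L, floor(sqrt(ncol(table)))),
                     log2 = max(1L, floor(log2(ncol(table)))))
      nodesize <- 1L
      maxnodes <- if (identical(hp$max_depth, "unlimited")) NULL else 2L^hp$max_depth
      set.seed(spec$seed)
      randomForest::randomForest(x = table, y = y, ntree = hp$n_trees,
                                 mtry = mtry, nodesize = nodesize,
                                 maxnodes = maxnodes)
    },
    random_tree = {
      set.seed(spec$seed)
      randomForest::randomForest(x = table, y = y, ntree = 1L,
                                 mtry = max(1L, floor(sqrt(ncol(table)))))
    },
    decision_tree = {
      df <- data.frame(.y = y, table, check.names = FALSE)
      set.seed(spec$seed)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2, cp = 0.01, xval = 0))
    },
    svc = {
      set.seed(spec$seed)
      args <- list(x = table, y = y, kernel = "radial", cost = hp$cost,
                   scale = FALSE)
      if (!is.null(hp$gamma)) args$gamma <- hp$gamma
      do.call(e1071::svm, args)
    })

  structure(list(spec = spec, fit = fit, columns = colnames(table),
                 train_ids = rownames(table), norm_params = norm_params),
            class = "or_classifier")
}

#' @export
print.or_classifier <- function(x, ...) {
  cat("OR agonist classifier:", format(x$spec), "-",
      length(x$train_ids), "training compounds,", length(x$columns), "descriptors\n")
  invisible(x)
}

# kNN score: weighted active mass among the k nearest training compounds.
# Neighbour order breaks distance ties by training row index; inverse-distance
# weights use 1/(d + 1e-12) so an exact match dominates its neighbourhood.
knn_scores <- function(train_x, train_y, query_x, k, weighting) {
  if (nrow(query_x) == 0) return(numeric(0))
  apply(query_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    ord <- order(d, seq_along(d))[seq_len(k)]
    w <- if (weighting == "inverse_distance") 1 / (d[ord] + 1e-12) else rep(1, k)
    sum(w[train_y[ord] == "active"]) / sum(w)
  })
}

svc_scores <- function(fit, query_x) {
  if (nrow(query_x) == 0) return(numeric(0))
  pr <- stats::predict(fit, query_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  oriented <- if (startsWith(colnames(dv)[1], "active")) dv[, 1] else -dv[, 1]
  stats::plogis(as.numeric(oriented))
}

#' Predict activity for new compounds
#'
#' Scores are real-valued in `[0, 1]` (kNN: weighted active-neighbour mass;
#' forests/trees: fraction of trees voting active; SVC: logistic of the
#' decision value). The class call is `active` iff `score >= 0.5` — the tie
#' goes to `active`, the sensitive choice for a screening tool.
#'
#' @param object an `or_classifier`.
#' @param table descriptor matrix with exactly the training columns.
#' @param ... unused.
#' @return data.frame with columns `id`, `predicted`, `score`.
#' @export
predict.or_classifier <- function(object, table, ...) {
  stopifnot(is.matrix(table))
  missing_cols <- setdiff(object$columns, colnames(table))
  extra_cols <- setdiff(colnames(table), object$columns)
  if (length(missing_cols) || length(extra_cols)) {
    stop("query columns do not match training columns; missing: [",
         paste(missing_cols, collapse = ", "), "], extra: [",
         paste(extra_cols, collapse = ", "), "]")
  }
  table <- table[, object$columns, drop = FALSE]
  ids <- rownames(table)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(table)))
  if (nrow(table) == 0) {
    return(data.frame(id = character(0), predicted = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  hp <- object$spec$hyperparameters
  scores <- switch(object$spec$family,
    knn = knn_scores(object$fit$x, object$fit$y, table, hp$k, hp$weighting),
    random_forest = ,
    random_tree = stats::predict(object$fit, table, type = "prob")[, "active"],
    decision_tree = stats::predict(object$fit,
                                   data.frame(table, check.names = FALSE),
                                   type = "prob")[, "active"],
    svc = svc_scores(object$fit, table))
  scores <- as.numeric(scores)
  data.frame(id = ids,
             predicted = ifelse(scores >= 0.5, "active", "inactive"),
             score = scores, stringsAsFactors = FALSE)
}

# Leave-one-out predictions for one candidate spec. The kNN family reuses a
# precomputed full distance matrix; other families refit N times.
loo_predict <- function(table, labels, spec, dmat = NULL) {
  n <- nrow(table)
  if (spec$family == "knn") {
    if (is.null(dmat)) dmat <- as.matrix(stats::dist(table))
    hp <- spec$hyperparameters
    if (hp$k > n - 1) stop("knn k = ", hp$k, " too large for LOO on ", n, " rows")
    scores <- vapply(seq_len(n), function(i) {
      d <- dmat[i, -i]
      yi <- labels[-i]
      ord <- order(d, seq_along(d))[seq_len(hp$k)]
      w <- if (hp$weighting == "inverse_distance") 1 / (d[ord] + 1e-12) else rep(1, hp$k)
      sum(w[yi[ord] == "active"]) / sum(w)
    }, numeric(1))
  } else {
    scores <- vapply(seq_len(n), function(i) {
      yi <- labels[-i]
      if (length(unique(yi)) < 2) {
        # leaving out the only member of a class: the reduced problem is
        # single-class, predict that class deterministically
        return(as.numeric(yi[1] == "active"))
      }
      fit <- train_classifier(table[-i, , drop = FALSE], yi, spec)
      predict(fit, table[i, , drop = FALSE])$score
    }, numeric(1))
  }
  data.frame(id = rownames(table), truth = labels,
             predicted = ifelse(scores >= 0.5, "active", "inactive"),
             score = scores, stringsAsFactors = FALSE)
}

#' Leave-one-out model selection by MCC
#'
#' Every candidate in `search_space` is evaluated by leave-one-out
#' cross-validation on the training table: each compound is predicted by a
#' model trained on the other `N - 1`, the LOO confusion matrix is summarized
#' by the Matthews correlation coefficient, and the candidate with the
#' highest MCC wins (ties break toward the earlier candidate; a candidate
#' whose MCC is undefined ranks below all defined ones). Deterministic given
#' the seeds stored in the specs.
#'
#' @param table normalized training descriptor matrix.
#' @param labels `"active"`/`"inactive"` vector; both classes required.
#' @param search_space non-empty list of [model_spec()] candidates.
#' @return list with `best` (winning `model_spec`), `best_index`, and
#'   `metrics` — one row per candidate with LOO TP/TN/FP/FN, MCC, accuracy,
#'   recall, AUROC and an `mcc_defined` flag.
#' @export
loo_select <- function(table, labels, search_space) {
  stopifnot(is.matrix(table), nrow(table) >= 2, length(search_space) >= 1)
  check_training_labels(labels)
  dmat <- as.matrix(stats::dist(table))
  rows <- lapply(seq_along(search_space), function(j) {
    spec <- search_space[[j]]
    pred <- loo_predict(table, labels, spec, dmat)
    cm <- confusion(pred$truth, pred$predicted)
    m <- classification_metrics(cm)
    data.frame(candidate = format(spec), family = spec$family,
               tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
               mcc = m$mcc, accuracy = m$accuracy, recall = m$recall,
               auroc = auroc(pred$truth, pred$score),
               mcc_defined = !("mcc" %in% m$undefined),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  key <- ifelse(metrics$mcc_defined, metrics$mcc, -Inf)
  best_index <- which.max(key) # ties -> first in search-space order
  list(best = search_space[[best_index]], best_index = best_index,
       metrics = metrics)
}
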