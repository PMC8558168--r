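#' Virtually screen a compound library
#'
#' Runs every library compound through a trained classifier and an
#' applicability domain fitted on the same training data. All compounds are
#' reported — the agonist gate (predicted active AND in-domain) is expressed
#' by flags rather than by dropping rows, so downstream filters stay
#' auditable. Rows are sorted by (`in_domain` desc, `score` desc,
#' `reliability` asc, `id` asc); the whole operation is deterministic.
#'
#' @param classifier an [train_classifier()] result.
#' @param ad an [fit_ad()] result fitted on the classifier's training rows.
#' @param library descriptor matrix of the screening library, projected onto
#'   the training columns and normalized with the model's training min/max.
#' @return data.frame of class `screening_hits` with columns `id`,
#'   `predicted`, `score`, `reliability`, `in_domain`, `consensus_count`
#'   (1 for a single-model screen).
#' @export
screen_library <- function(classifier, ad, library) {
  stopifnot(inherits(classifier, "or_classifier"), inherits(ad, "ad_params"))
  pred <- predict(classifier, library)
  adsc <- score_ad(ad, library)
  stopifnot(identical(pred$id, adsc$id))
  hits <- data.frame(id = pred$id, predicted = pred$predicted,
                     score = pred$score, reliability = adsc$reliability,
                     in_domain = adsc$in_domain,
                     consensus_count = ifelse(pred$predicted == "active" &
                                                adsc$in_domain, 1L, 0L),
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$in_domain, -hits$score, hits$reliability, hits$id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("screening_hits", "data.frame")
  hits
}

#' Predicted agonists of a screen
#'
#' The gate used for experimental prioritization: predicted `active` and
#' inside the applicability domain.
#'
#' @param hits a [screen_library()] result.
#' @return character vector of compound ids.
#' @export
predicted_agonists <- function(hits) {
  hits$id[hits$predicted == "active" & hits$in_domain]
}

#' Consensus across screens of the same library
#'
#' Intersects the predicted-agonist gates of two or more screens (e.g. two
#' receptor models, or a current and a previously published model of the same
#' receptor): a compound is retained iff it passes the gate in every list.
#' `consensus_count` reports in how many lists each retained compound passed.
#' Intersection is taken after applicability-domain gating.
#'
#' @param hitlists list of [screen_library()] results over identical id sets.
#' @return `screening_hits` data.frame restricted to the consensus compounds,
#'   carrying the first list's prediction/score columns, sorted as in
#'   [screen_library()].
#' @export
consensus_hits <- function(hitlists) {
  if (!is.list(hitlists) || length(hitlists) < 1) {
    stop("hitlists must be a non-empty list of screening results")
  }
  ids <- lapply(hitlists, `[[`, "id")
  base <- sort(ids[[1]])
  for (j in seq_along(ids)[-1]) {
    if (!identical(sort(ids[[j]]), base)) {
      asym <- c(setdiff(ids[[j]], ids[[1]]), setdiff(ids[[1]], ids[[j]]))
      stop("screens cover different id sets; asymmetric ids: ",
           paste(unique(asym), collapse = ", "))
    }
  }
  gates <- lapply(hitlists, function(h) {
    stats::setNames(h$predicted == "active" & h$in_domain, h$id)
  })
  count <- stats::setNames(
    Reduce(`+`, lapply(gates, function(g) as.integer(g[base]))), base)
  keep <- base[count == length(hitlists)]
  out <- hitlists[[1]][hitlists[[1]]$id %in% keep, , drop = FALSE]
  out$consensus_count <- count[out$id]
  out <- out[order(-out$in_domain, -out$score, out$reliability, out$id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_hits", "data.frame")
  out
}

#' Enrichment of known actives among predicted agonists
#'
#' Hypergeometric (one-sided, over-representation) test of the overlap
#' between the predicted-agonist set and a truth set — the standard check
#' that a virtual screen retrieves planted or known actives better than a
#' random pick of the same size.
#'
#' @param hits a [screen_library()] result.
#' @param truth_active character vector of ids that are truly active.
#' @return list with `overlap`, `n_predicted`, `n_active`, `n_library`,
#'   `p_value`.
#' @export
enrichment_test <- function(hits, truth_active) {
  pred <- predicted_agonists(hits)
  n <- nrow(hits)
  k <- length(intersect(pred, truth_active))
  m <- length(intersect(truth_active, hits$id))
  p <- stats::phyper(k - 1, m, n - m, length(pred), lower.tail = FALSE)
  list(overlap = k, n_predicted = length(pred), n_active = m,
       n_library = n, p_value = p)
}

#' Write a screening report as CSV
#' @param hits a `screening_hits` data.frame.
#' @param path file path.
#' @export
write_screen_report <- function(hits, path) {
  utils::write.csv(hits, path, row.names = FALSE)
  invisible(path)
}
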