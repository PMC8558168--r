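#' Specify a synthetic QSAR dataset
#'
#' Configuration for the planted structure-activity generator used throughout
#' the test suite and examples. Descriptor geometry: `n_informative` columns
#' carry the signal — class means at `+effect_size/2` (active) and
#' `-effect_size/2` (inactive) with within-class standard deviation
#' `noise_sd` — and the remaining columns are pure `N(0, noise_sd)` noise
#' shared by both classes. After generation, `label_flip_rate` of the labels
#' are flipped (rounded count, sampled without replacement), emulating assay
#' noise. Everything is a pure function of the spec plus its seed.
#'
#' @param n_compounds number of compounds.
#' @param n_descriptors number of descriptor columns.
#' @param active_fraction fraction of actives in (0, 1); the active count is
#'   `round(active_fraction * n_compounds)` exactly.
#' @param n_informative number of signal-carrying descriptors
#'   (`<= n_descriptors`).
#' @param effect_size class-mean separation in the informative descriptors,
#'   in units of the within-class standard deviation.
#' @param noise_sd within-class standard deviation.
#' @param label_flip_rate fraction of labels flipped after generation,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_descriptors, active_fraction,
                           n_informative = 5L, effect_size = 1.5,
                           noise_sd = 1, label_flip_rate = 0.05, seed = 1L) {
  if (n_compounds < 2) stop("need at least 2 compounds")
  if (n_informative > n_descriptors) stop("n_informative exceeds n_descriptors")
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop("active_fraction must be in (0, 1)")
  }
  if (label_flip_rate < 0 || label_flip_rate >= 1) {
    stop("label_flip_rate must be in [0, 1)")
  }
  if (noise_sd < 0 || effect_size < 0) stop("noise_sd and effect_size must be >= 0")
  n_active <- round(active_fraction * n_compounds)
  if (n_active == 0 || n_active == n_compounds) {
    stop("active_fraction rounds to a single-class dataset")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 active_fraction = active_fraction,
                 n_active = as.integer(n_active),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 label_flip_rate = label_flip_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Draw one compound x descriptor block for given true labels.
synthetic_block <- function(spec, labels, id_prefix) {
  n <- length(labels)
  m <- matrix(stats::rnorm(n * spec$n_descriptors, 0, spec$noise_sd),
              nrow = n, ncol = spec$n_descriptors)
  if (spec$n_informative > 0) {
    shift <- ifelse(labels == "active", spec$effect_size / 2, -spec$effect_size / 2)
    m[, seq_len(spec$n_informative)] <- m[, seq_len(spec$n_informative)] + shift
  }
  dimnames(m) <- list(sprintf("%s%03d", id_prefix, seq_len(n)),
                      sprintf("desc_%03d", seq_len(spec$n_descriptors)))
  m
}

#' Generate a labeled synthetic QSAR dataset
#'
#' @param spec a [synthetic_spec()].
#' @param pathological optional named list requesting adversarial columns to
#'   exercise the feature filter: `constant` (count of constant columns),
#'   `correlated` (count of exact 2x duplicates of existing columns),
#'   `missing` (count of columns given one `NA` cell). These columns are
#'   appended with names `const_*`, `dup_*`, `miss_*`.
#' @return list with `dataset` (a [labeled_dataset()] with surrogate ids and
#'   placeholder SMILES) and `table` (descriptor matrix aligned to it).
#' @export
gen_qsar_dataset <- function(spec, pathological = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  labels <- rep("inactive", n)
  labels[sample.int(n, spec$n_active)] <- "active"
  table <- synthetic_block(spec, labels, "cmpd_")

  observed <- labels
  n_flip <- round(spec$label_flip_rate * n)
  if (n_flip > 0) {
    flip <- sample.int(n, n_flip)
    observed[flip] <- ifelse(observed[flip] == "active", "inactive", "active")
  }

  if (!is.null(pathological)) {
    extra <- list()
    for (j in seq_len(pathological$constant %||% 0)) {
      extra[[sprintf("const_%02d", j)]] <- rep(1, n)
    }
    for (j in seq_len(pathological$correlated %||% 0)) {
      extra[[sprintf("dup_%02d", j)]] <- 2 * table[, j]
    }
    for (j in seq_len(pathological$missing %||% 0)) {
      col <- stats::rnorm(n)
      col[1 + (j - 1) %% n] <- NA
      extra[[sprintf("miss_%02d", j)]] <- col
    }
    if (length(extra)) table <- cbind(table, do.call(cbind, extra))
  }

  dataset <- labeled_dataset(rownames(table), smiles = rep("*", n),
                             label = observed, source = "synthetic",
                             name = sprintf("synthetic_n%d_seed%d", n, spec$seed))
  list(dataset = dataset, table = table, true_labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic screening library
#'
#' Library compounds drawn from the same generative geometry as
#' [gen_qsar_dataset()], with hidden truth labels returned separately so a
#' screen's retrieval can be evaluated. `center_shift` displaces both class
#' means (in units of `noise_sd`) to emulate a library far from the training
#' chemistry — useful for applicability-domain tests.
#'
#' @param n library size.
#' @param planted_active_fraction fraction of hidden actives; the count is
#'   exact (`round(fraction * n)`).
#' @param spec the [synthetic_spec()] defining the descriptor geometry.
#' @param seed integer seed (independent of `spec$seed`).
#' @param center_shift displacement of all class means, in `noise_sd` units.
#' @return list with `table` (descriptor matrix, ids `lib_*`) and
#'   `true_labels` (hidden labels aligned to rows).
#' @export
gen_library <- function(n, planted_active_fraction, spec, seed = 1L,
                        center_shift = 0) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1)
  n_active <- round(planted_active_fraction * n)
  set.seed(as.integer(seed))
  labels <- rep("inactive", n)
  if (n_active > 0) labels[sample.int(n, n_active)] <- "active"
  table <- synthetic_block(spec, labels, "lib_")
  if (center_shift != 0) table <- table + center_shift * spec$noise_sd
  list(table = table, true_labels = labels)
}

#' Generate a synthetic bioassay (SSR panel + choice assay)
#'
#' Emulates the validation experiments: a single-sensillum panel in which
#' control stimuli elicit net responses around 0 spikes/s and active odorants
#' are shifted upward by `effect`, plus a two-arm choice assay with binomial
#' choices and paired residence times.
#'
#' @param n_odorants number of odorant stimuli (named `odor_01`...).
#' @param n_replicates replicates per stimulus (also used for the solvent
#'   control).
#' @param active_ids indices (or `odor_*` names) of the truly active
#'   odorants.
#' @param effect mean net-response shift of active odorants, spikes/s.
#' @param rate_sd replicate-to-replicate standard deviation, spikes/s.
#' @param choice_prob probability that a deciding larva picks the odorant
#'   arm.
#' @param n_larvae number of deciding larvae in the choice assay.
#' @param seed integer seed.
#' @return list with `panel` (data.frame for [activity_call()], including a
#'   `solvent_control` and the spontaneous/stimulation rate columns),
#'   `choice` (counts `odorant`/`control`) and `times` (paired residence
#'   times, seconds).
#' @export
gen_bioassay <- function(n_odorants, n_replicates, active_ids = integer(0),
                         effect = 100, rate_sd = 10, choice_prob = 0.5,
                         n_larvae = 30L, seed = 1L) {
  stopifnot(effect >= 0, rate_sd >= 0, choice_prob >= 0, choice_prob <= 1)
  set.seed(as.integer(seed))
  odor_names <- sprintf("odor_%02d", seq_len(n_odorants))
  if (is.numeric(active_ids)) active_ids <- odor_names[active_ids]

  spont <- 20 # typical spontaneous rate, spikes/s
  mk_rows <- function(stimulus, role, shift) {
    net <- stats::rnorm(n_replicates, shift, rate_sd)
    stim <- pmax(spont + net, 0) # a neuron cannot fire negatively
    data.frame(stimulus = stimulus, role = role,
               replicate = seq_len(n_replicates),
               stim_rate = stim, spont_rate = spont,
               stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, c(
    list(mk_rows("solvent", "solvent_control", 0)),
    lapply(odor_names, function(s) {
      mk_rows(s, "odorant", if (s %in% active_ids) effect else 0)
    })))

  n_od <- stats::rbinom(1, n_larvae, choice_prob)
  base <- pmax(stats::rnorm(n_larvae, 120, 40), 0)
  pref <- stats::rnorm(n_larvae, 60 * (choice_prob - 0.5) * 2, 30)
  times <- data.frame(larva_id = sprintf("larva_%02d", seq_len(n_larvae)),
                      time_odorant = pmax(base + pref, 0),
                      time_control = base,
                      stringsAsFactors = FALSE)
  list(panel = panel,
       choice = c(odorant = n_od, control = n_larvae - n_od),
       times = times)
}

#' Random fragment-grammar SMILES
#'
#' Tiny generative grammar producing valid, occasionally multi-fragment and
#' charged SMILES strings — used to property-test the standardization
#' contract (idempotence, fragment selection), not to emulate real volatile
#' chemistry.
#'
#' @param n number of SMILES to generate.
#' @param seed integer seed.
#' @return character vector of SMILES.
#' @export
gen_random_smiles <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  cores <- c("CCO", "CC(C)O", "CCC=O", "CC(=O)C", "c1ccccc1", "Cc1ccccc1",
             "OCc1ccccc1", "CC(=O)OCC", "CCCCCC", "CC(=O)O", "CCN", "C1CCCCC1",
             "CCOC(=O)C", "CC=CC", "N#CCc1ccccc1", "COc1ccccc1")
  salts <- c("", ".[Na+].[Cl-]", ".[K+].[Br-]", ".O", ".[Na+].[O-]C(=O)C")
  paste0(sample(cores, n, replace = TRUE), sample(salts, n, replace = TRUE))
}

#' Dataset-shape presets mirroring the two receptor studies
#'
#' Bundled configurations for the two study shapes used across examples and
#' tests: `"or24"` — 51 compounds (10 actives), exclusion radius 4.8,
#' correlation cutoff 0.90, 288 descriptors, applicability-domain k = 6;
#' `"or25"` — 83 compounds (25 actives), radius 4.0, cutoff 0.95, 493
#' descriptors, k = 9. Both use the 24% sphere-exclusion stop rule and a
#' 158-compound screening library. Descriptor counts equal the surviving
#' descriptor library sizes of the corresponding published models, which is
#' also the dimensionality at which the quoted radii are geometrically
#' meaningful in [0,1]-normalized space.
#'
#' @param which `"or24"` or `"or25"`.
#' @param seed seed stored in the returned [synthetic_spec()].
#' @return list with `spec` (a `synthetic_spec`), `radius`, `fraction`,
#'   `corr_cutoff`, `ad_k`, `library_size`, `test_counts` (reference test-set
#'   actives/inactives).
#' @export
receptor_preset <- function(which = c("or24", "or25"), seed = 1L) {
  which <- match.arg(which)
  if (which == "or24") {
    list(spec = synthetic_spec(51, 288, 10 / 51, seed = seed),
         radius = 4.8, fraction = 0.24, corr_cutoff = 0.90, ad_k = 6L,
         library_size = 158L, test_counts = c(active = 2L, inactive = 10L))
  } else {
    list(spec = synthetic_spec(83, 493, 25 / 83, seed = seed),
         radius = 4.0, fraction = 0.24, corr_cutoff = 0.95, ad_k = 9L,
         library_size = 158L, test_counts = c(active = 7L, inactive = 12L))
  }
}
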