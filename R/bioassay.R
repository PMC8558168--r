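#' Net single-sensillum response
#'
#' Response of an olfactory sensory neuron to a stimulus, in spikes per
#' second: firing rate during stimulation minus the spontaneous firing rate.
#' Negative values are meaningful (inhibition) and returned as-is.
#'
#' @param stim_rate firing rate during stimulation (spikes/s, `>= 0`).
#' @param spont_rate spontaneous firing rate (spikes/s, `>= 0`).
#' @return net response in spikes/s (vectorized).
#' @examples
#' ssr_response(120, 20)  # 100
#' @export
ssr_response <- function(stim_rate, spont_rate) {
  if (any(stim_rate < 0) || any(spont_rate < 0)) {
    stop("firing rates must be non-negative")
  }
  stim_rate - spont_rate
}

#' Activity calls from a single-sensillum recording panel
#'
#' Tests every odorant against the solvent control. A global Kruskal-Wallis
#' test (tie-corrected) is computed across all stimuli; each odorant is then
#' compared to the solvent by a two-sample Wilcoxon rank-sum test with
#' step-down Holm adjustment across odorants. This rank-based many-to-one
#' scheme is a documented stand-in for the Dunnett-type nonparametric
#' multiple-contrast procedure: it preserves the inferential intent (each
#' odorant vs solvent, familywise error controlled at `alpha`).
#'
#' @param panel data.frame with columns `stimulus`, `role` (one of
#'   `odorant`, `solvent_control`, `positive_control`, `blank`) and either
#'   `response` or the pair `stim_rate`, `spont_rate` (net response is then
#'   computed by [ssr_response()]). One row per replicate.
#' @param alpha familywise significance level for the active flag.
#' @return data.frame with one row per tested odorant: `stimulus`, `n`,
#'   `median_response`, `statistic` (Wilcoxon W vs solvent), `p`, `p_adj`,
#'   `active`. The global Kruskal-Wallis result is attached as attributes
#'   `kw_statistic`, `kw_df`, `kw_p`; odorants with fewer than 2 replicates
#'   are excluded with a warning.
#' @export
activity_call <- function(panel, alpha = 0.05) {
  stopifnot(is.data.frame(panel), all(c("stimulus", "role") %in% names(panel)))
  if (!"response" %in% names(panel)) {
    if (!all(c("stim_rate", "spont_rate") %in% names(panel))) {
      stop("panel needs a 'response' column or 'stim_rate' + 'spont_rate'")
    }
    panel$response <- ssr_response(panel$stim_rate, panel$spont_rate)
  }
  ctrl <- panel$response[panel$role == "solvent_control"]
  if (length(ctrl) < 2) stop("solvent_control needs at least 2 replicates")

  odorants <- unique(panel$stimulus[panel$role == "odorant"])
  n_rep <- vapply(odorants, function(s) sum(panel$stimulus == s), integer(1))
  if (any(n_rep < 2)) {
    warning("excluding odorant(s) with < 2 replicates: ",
            paste(odorants[n_rep < 2], collapse = ", "))
    odorants <- odorants[n_rep >= 2]
  }

  if (length(unique(panel$response)) == 1) {
    # fully tied panel: tie-corrected H is 0/0, defined here as 0
    kw <- list(statistic = c(H = 0), parameter = c(df = length(unique(panel$stimulus)) - 1),
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(panel$response, factor(panel$stimulus))
  }

  res <- lapply(odorants, function(s) {
    x <- panel$response[panel$stimulus == s]
    if (length(unique(c(x, ctrl))) == 1) {
      # all values tied with control: no evidence by convention
      return(data.frame(stimulus = s, n = length(x), median_response = stats::median(x),
                        statistic = NA_real_, p = 1, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, ctrl, exact = NULL))
    data.frame(stimulus = s, n = length(x), median_response = stats::median(x),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(stimulus = character(0), n = integer(0),
                      median_response = numeric(0), statistic = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out$active <- out$p_adj < alpha
  attr(out, "kw_statistic") <- unname(kw$statistic)
  attr(out, "kw_df") <- unname(kw$parameter)
  attr(out, "kw_p") <- kw$p.value
  out
}

#' Chi-squared test for a two-arm choice assay
#'
#' Goodness-of-fit test of the deciding animals' counts against equal
#' probabilities (0.5, 0.5) — the standard analysis of a Y-tube olfactometer
#' choice. Animals that made no choice must be excluded before calling this.
#'
#' @param n_odorant number choosing the odorant arm.
#' @param n_control number choosing the control arm.
#' @return list with `chi2`, `df` (= 1) and `p`.
#' @examples
#' choice_test(20, 10)  # chi2 = 3.33, p ~ 0.068
#' @export
choice_test <- function(n_odorant, n_control) {
  if (n_odorant < 0 || n_control < 0) stop("counts must be non-negative")
  if (n_odorant + n_control == 0) stop("no deciding animals: both counts zero")
  ct <- stats::chisq.test(c(n_odorant, n_control), p = c(0.5, 0.5))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Paired t-test on arm residence times
#'
#' Compares the time each animal spent in the odorant arm with the time in
#' the control arm (paired Student's t on the within-animal differences,
#' two-sided).
#'
#' @param time_odorant,time_control non-negative times in seconds, one pair
#'   per animal (at least 2 pairs).
#' @return list with `t`, `df` (= n - 1), `p` and `mean_diff`
#'   (odorant - control).
#' @export
arm_time_test <- function(time_odorant, time_control) {
  if (length(time_odorant) != length(time_control)) stop("unpaired times")
  if (length(time_odorant) < 2) stop("need at least 2 pairs")
  if (any(time_odorant < 0) || any(time_control < 0)) stop("times must be non-negative")
  diffs <- time_odorant - time_control
  if (stats::sd(diffs) == 0) stop("degenerate pairs: zero variance in differences")
  tt <- stats::t.test(time_odorant, time_control, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate))
}

#' Read single-sensillum / behavior CSV files
#'
#' SSR dialect: `stimulus,role,replicate,stim_rate,spont_rate`. Behavior
#' dialect: `larva_id,choice,time_odorant,time_control` with `choice` in
#' `{odorant, control, none}`; `none` rows (no decision within the assay
#' window) are dropped from the counts but reported in `n_no_choice`.
#'
#' @param path CSV file path.
#' @return for `read_ssr_panel`, a panel data.frame usable by
#'   [activity_call()]; for `read_choice_assay`, a list with `counts`
#'   (odorant, control), `times` data.frame and `n_no_choice`.
#' @export
read_ssr_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "role", "replicate", "stim_rate", "spont_rate")
  if (!all(need %in% names(d))) {
    stop("SSR csv must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_ssr_panel
#' @export
read_choice_assay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "choice", "time_odorant", "time_control")
  if (!all(need %in% names(d))) {
    stop("behavior csv must have columns: ", paste(need, collapse = ", "))
  }
  decided <- d[d$choice %in% c("odorant", "control"), , drop = FALSE]
  list(counts = c(odorant = sum(decided$choice == "odorant"),
                  control = sum(decided$choice == "control")),
       times = decided[, c("larva_id", "time_odorant", "time_control")],
       n_no_choice = sum(d$choice == "none"))
}
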