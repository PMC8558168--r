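#' Compute a descriptor matrix for a dataset
#'
#' One row per compound in dataset order. A backend failure on a molecule
#' yields a row of missing (`NA`) cells, never silent zeros; such compounds
#' are removed later by the missing-value filter.
#'
#' Backends:
#' \describe{
#'   \item{`toy`}{four hand-coded descriptors read off the SMILES string
#'     (heavy atoms, carbons, ring closures, heteroatoms). Used as an exactly
#'     checkable oracle in tests and examples.}
#'   \item{`openbabel`}{physicochemical properties from OpenBabel via
#'     \pkg{ChemmineR} (logP, molar refractivity, molecular weight, TPSA,
#'     H-bond donors/acceptors, fluorine count). A small open descriptor set;
#'     commercial descriptor engines are not emulated.}
#' }
#'
#' @param dataset a [labeled_dataset()] with standardized SMILES.
#' @param backend `"toy"` or `"openbabel"`.
#' @return numeric matrix, rownames = compound ids, colnames = descriptor
#'   names; `NA` marks missing cells.
#' @export
compute_descriptors <- function(dataset, backend = c("toy", "openbabel")) {
  backend <- match.arg(backend)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (nrow(dataset) == 0) {
    cols <- if (backend == "toy") toy_descriptor_names() else openbabel_descriptor_names()
    return(matrix(numeric(0), nrow = 0, ncol = length(cols),
                  dimnames = list(character(0), cols)))
  }
  rows <- if (backend == "toy") {
    lapply(dataset$smiles, function(s) {
      tryCatch(toy_descriptors(s),
               error = function(e) rep(NA_real_, length(toy_descriptor_names())))
    })
  } else {
    openbabel_descriptor_rows(dataset$smiles)
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(dataset$id,
                      if (backend == "toy") toy_descriptor_names() else openbabel_descriptor_names())
  m
}

toy_descriptor_names <- function() c("heavy_atoms", "carbons", "rings", "heteroatoms")

# Descriptors computable by eye from a SMILES string; ring count = number of
# ring-closure bond pairs (digits and %nn labels), which for the simple
# molecules used in tests equals SSSR ring count.
toy_descriptors <- function(smiles) {
  if (!nzchar(trimws(smiles))) stop("empty SMILES")
  heavy <- count_heavy_atoms(smiles)
  carbons <- count_carbon_atoms(smiles)
  s <- gsub("\\[[^]]*\\]", "A", smiles)
  closures <- lengths(regmatches(s, gregexpr("%[0-9]{2}|[0-9]", s)))
  c(heavy_atoms = heavy, carbons = carbons, rings = closures / 2,
    heteroatoms = heavy - carbons)
}

openbabel_descriptor_names <- function() {
  c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
}

openbabel_descriptor_rows <- function(smiles) {
  cols <- openbabel_descriptor_names()
  lapply(smiles, function(s) {
    row <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(s))
      p <- suppressWarnings(ChemmineR::propOB(sdf))
      as.numeric(p[1, cols])
    }, error = function(e) rep(NA_real_, length(cols)))
    if (length(row) != length(cols)) row <- rep(NA_real_, length(cols))
    row
  })
}

#' Filter descriptors: missing, constant, near-constant, correlated
#'
#' Removal proceeds in a fixed order so the report is deterministic:
#' (1) any column with at least one missing value; (2) constant columns;
#' (3) near-constant columns (most frequent value covering more than
#' `near_const_frac` of rows, or standard deviation below `near_const_tol`);
#' (4) a greedy left-to-right correlation scan in column order — when a pair
#' reaches `|r| >= corr_cutoff` the later column is removed, so the earlier
#' column always survives. After filtering, all surviving pairs satisfy
#' `|r| < corr_cutoff` and no cell is missing.
#'
#' @param table descriptor matrix (rownames = ids).
#' @param corr_cutoff absolute Pearson correlation threshold in (0, 1];
#'   conventional per-receptor defaults are 0.90 and 0.95.
#' @param near_const_tol standard-deviation floor below which a column counts
#'   as near-constant.
#' @param near_const_frac dominant-value row fraction above which a column
#'   counts as near-constant.
#' @return list with `table` (filtered matrix) and `report` (data.frame with
#'   columns `descriptor`, `reason`; reasons are `missing`, `constant`,
#'   `near_constant`, `correlated_with:<name>`).
#' @export
filter_features <- function(table, corr_cutoff = 0.95, near_const_tol = 1e-8,
                            near_const_frac = 0.95) {
  if (!is.matrix(table) || nrow(table) == 0 || ncol(table) == 0) {
    stop("descriptor table must be a non-empty matrix")
  }
  if (corr_cutoff <= 0 || corr_cutoff > 1) stop("corr_cutoff must be in (0, 1]")
  removed <- data.frame(descriptor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(cols, reason) {
    if (length(cols)) {
      removed <<- rbind(removed, data.frame(descriptor = cols, reason = reason,
                                            stringsAsFactors = FALSE))
      table <<- table[, setdiff(colnames(table), cols), drop = FALSE]
    }
  }

  miss <- colnames(table)[colSums(is.na(table)) > 0]
  drop(miss, "missing")

  if (ncol(table)) {
    const <- colnames(table)[apply(table, 2, function(x) max(x) == min(x))]
    drop(const, "constant")
  }
  if (ncol(table)) {
    nearc <- colnames(table)[apply(table, 2, function(x) {
      stats::sd(x) < near_const_tol ||
        max(tabulate(match(x, unique(x)))) > near_const_frac * length(x)
    })]
    drop(nearc, "near_constant")
  }

  if (ncol(table) > 1) {
    cm <- abs(suppressWarnings(stats::cor(table)))
    keep <- rep(TRUE, ncol(table))
    partner <- character(ncol(table))
    for (j in seq_len(ncol(table))) {
      if (!keep[j]) next
      later <- which(keep & seq_len(ncol(table)) > j & cm[j, ] >= corr_cutoff)
      keep[later] <- FALSE
      partner[later] <- colnames(table)[j]
    }
    corr_cols <- colnames(table)[!keep]
    if (length(corr_cols)) {
      removed <- rbind(removed, data.frame(
        descriptor = corr_cols,
        reason = paste0("correlated_with:", partner[!keep]),
        stringsAsFactors = FALSE))
      table <- table[, keep, drop = FALSE]
    }
  }

  if (ncol(table) == 0) stop("no descriptors survive filtering")
  attr(removed, "corr_cutoff") <- corr_cutoff
  list(table = table, report = removed)
}

#' Fit min-max normalization parameters on training rows only
#'
#' @param table descriptor matrix with no missing cells.
#' @param train_ids ids of the training compounds (subset of rownames).
#' @return object of class `minmax_params`: list with named numeric vectors
#'   `min` and `max`.
#' @export
fit_minmax <- function(table, train_ids = rownames(table)) {
  stopifnot(is.matrix(table))
  if (anyNA(table)) stop("descriptor table has missing cells; filter first")
  if (!all(train_ids %in% rownames(table))) {
    stop("train_ids not all present in table: ",
         paste(setdiff(train_ids, rownames(table)), collapse = ", "))
  }
  tr <- table[train_ids, , drop = FALSE]
  mins <- apply(tr, 2, min)
  maxs <- apply(tr, 2, max)
  if (any(maxs == mins)) {
    stop("constant training column(s): ",
         paste(colnames(tr)[maxs == mins], collapse = ", "),
         " (should have been filtered)")
  }
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' Apply min-max normalization
#'
#' Maps each value to `(value - min) / (max - min)` using training-set
#' statistics. Training rows land in `[0, 1]`; external rows may fall outside
#' and are deliberately not clipped (the applicability domain handles
#' extrapolation, not the scaler).
#'
#' @param table descriptor matrix whose columns are all covered by `params`.
#' @param params a [fit_minmax()] result.
#' @return normalized matrix, same shape and dimnames.
#' @export
apply_minmax <- function(table, params) {
  stopifnot(is.matrix(table), inherits(params, "minmax_params"))
  absent <- setdiff(colnames(table), names(params$min))
  if (length(absent)) stop("columns absent from params: ", paste(absent, collapse = ", "))
  mins <- params$min[colnames(table)]
  maxs <- params$max[colnames(table)]
  sweep(sweep(table, 2, mins, "-"), 2, maxs - mins, "/")
}

#' Invert min-max normalization
#' @param table normalized matrix.
#' @param params the `minmax_params` used to normalize.
#' @return matrix on the original descriptor scale.
#' @export
invert_minmax <- function(table, params) {
  stopifnot(is.matrix(table), inherits(params, "minmax_params"))
  mins <- params$min[colnames(table)]
  maxs <- params$max[colnames(table)]
  sweep(sweep(table, 2, maxs - mins, "*"), 2, mins, "+")
}

#' Write / read a descriptor table as CSV
#'
#' First column `id`, remaining columns named descriptors; empty cell =
#' missing value.
#' @param table descriptor matrix.
#' @param path file path.
#' @export
write_descriptors <- function(table, path) {
  d <- data.frame(id = rownames(table), table, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$id
  m
}
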