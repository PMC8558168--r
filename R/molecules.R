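#' Standardize a SMILES string
#'
#' Deterministic standardization contract applied to every compound before
#' descriptor computation: parse, keep the largest organic fragment (salt and
#' solvent removal), neutralize charges where chemically valid, and emit the
#' canonical SMILES. The operation is idempotent. Chemistry is handled by
#' OpenBabel (via \pkg{ChemmineOB}); fragment selection and ordering are fixed
#' here so results do not depend on input fragment order.
#'
#' No tautomer enumeration is performed: pH-specific major-tautomer selection
#' is not reproducible across toolkits. A caller-supplied canonical-tautomer
#' pass can be plugged in through `tautomer_hook`.
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize logical; neutralize formal charges where a valence-legal
#'   neutral form exists (default `TRUE`).
#' @param tautomer_hook optional function `character -> character` applied to
#'   each fragment-reduced SMILES before canonicalization.
#' @return character vector of canonical SMILES, same length as input.
#' @examples
#' \dontrun{
#' standardize_smiles("OCc1ccccc1.[Na+].[Cl-]")  # -> canonical benzyl alcohol
#' }
#' @export
standardize_smiles <- function(smiles, neutralize = TRUE, tautomer_hook = NULL) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) stop("empty SMILES input")
    s <- trimws(s)
    if (!nzchar(ob_canonical(s))) stop("unparseable SMILES: '", s, "'")
    frag <- largest_organic_fragment(s)
    if (neutralize) frag <- ob_neutralize(frag)
    if (!is.null(tautomer_hook)) frag <- tautomer_hook(frag)
    out <- ob_canonical(frag)
    if (!nzchar(out)) stop("unparseable SMILES: '", s, "'")
    out
  }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES via OpenBabel; returns "" for unparseable input.
ob_canonical <- function(s) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
  trimws(out)
}

# OpenBabel's neutralize transform (adds/removes H to cancel formal charges
# where valence allows); quaternary N and the like are left charged.
ob_neutralize <- function(s) {
  out <- trimws(suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "SMI", s,
    options = data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE))))
  if (nzchar(out)) out else s
}

# Pick the fragment with the most heavy atoms among carbon-containing
# fragments (all fragments if none contains carbon). Ties break toward more
# carbons, then first in input order.
largest_organic_fragment <- function(s) {
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1) return(frags)
  heavy <- vapply(frags, count_heavy_atoms, numeric(1))
  carbons <- vapply(frags, count_carbon_atoms, numeric(1))
  pool <- if (any(carbons > 0)) which(carbons > 0) else seq_along(frags)
  best <- pool[order(-heavy[pool], -carbons[pool], pool)][1]
  frags[best]
}

# Heavy (non-hydrogen) atom count read directly off a SMILES string:
# each bracket atom is one atom unless it is [H]; outside brackets count
# organic-subset element symbols (two-letter Cl/Br first).
count_heavy_atoms <- function(s) {
  brackets <- gregexpr("\\[[^]]*\\]", s)[[1]]
  n_bracket <- 0L
  if (brackets[1] != -1) {
    atoms <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    n_bracket <- sum(!grepl("^\\[[0-9]*H[0-9]*[+-]?\\]$", atoms))
    s <- gsub("\\[[^]]*\\]", "", s)
  }
  n_two <- lengths(regmatches(s, gregexpr("Cl|Br", s)))
  s <- gsub("Cl|Br", "", s)
  n_one <- lengths(regmatches(s, gregexpr("[BCNOPSFI]|[bcnops]", s)))
  n_bracket + n_two + n_one
}

count_carbon_atoms <- function(s) {
  atoms <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  n_bracket <- sum(grepl("\\[[0-9]*[Cc](?![lda-z])", atoms, perl = TRUE))
  s <- gsub("\\[[^]]*\\]", "", s)
  s <- gsub("Cl", "", s, fixed = TRUE)
  n_bracket + lengths(regmatches(s, gregexpr("[Cc]", s)))
}

#' Create a labeled compound dataset
#'
#' @param id character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings.
#' @param label activity labels, each one of `"active"`, `"inactive"`,
#'   `"unknown"` (case-insensitive on input; stored lowercase). `NA` or a
#'   missing argument means `"unknown"` (unlabeled screening library).
#' @param source optional provenance tag(s).
#' @param name dataset name.
#' @return a `labeled_dataset`: a data.frame with columns `id`, `smiles`,
#'   `label`, `source` whose row order is the canonical compound order used
#'   by every downstream matrix.
#' @export
labeled_dataset <- function(id, smiles, label = NULL, source = "", name = "dataset") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate compound ids: ", paste(dup, collapse = ", "))
  }
  if (is.null(label)) label <- rep(NA_character_, length(id))
  label <- tolower(as.character(label))
  label[is.na(label) | label == ""] <- "unknown"
  bad <- setdiff(unique(label), c("active", "inactive", "unknown"))
  if (length(bad)) stop("unknown label token(s): ", paste(bad, collapse = ", "))
  if (length(smiles) != length(id) || length(label) != length(id)) {
    stop("id, smiles and label must have equal lengths")
  }
  d <- data.frame(id = id, smiles = as.character(smiles), label = label,
                  source = rep_len(as.character(source), length(id)),
                  stringsAsFactors = FALSE)
  attr(d, "name") <- name
  class(d) <- c("labeled_dataset", "data.frame")
  d
}

#' Count actives/inactives in a dataset
#' @param dataset a `labeled_dataset`.
#' @return named integer vector with elements `active`, `inactive`, `unknown`.
#' @export
label_counts <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  vapply(c(active = "active", inactive = "inactive", unknown = "unknown"),
         function(l) sum(dataset$label == l), integer(1))
}

#' Read a compound dataset from disk
#'
#' Two dialects: `csv` with header `id,smiles,label` (the `label` column is
#' optional — screening libraries omit it and all compounds become
#' `"unknown"`), and `smi` with one `SMILES<TAB>id` pair per line.
#'
#' @param path file path.
#' @param format `"csv"` or `"smi"`.
#' @param name dataset name (defaults to the file name).
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(path, format = c("csv", "smi"), name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "smiles") %in% names(d))) {
      stop("csv must have columns 'id' and 'smiles'")
    }
    lab <- if ("label" %in% names(d)) d$label else NULL
    src <- if ("source" %in% names(d)) d$source else ""
    labeled_dataset(d$id, d$smiles, lab, src, name = name)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2)) stop("smi lines must be 'SMILES<TAB>id'")
    labeled_dataset(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1),
                    name = name)
  }
}

#' Write a compound dataset to disk
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(d, p), p)`
#' reproduces `d` record for record. `"unknown"` labels are written as empty
#' cells.
#'
#' @param dataset a `labeled_dataset`.
#' @param path destination file.
#' @param format `"csv"` or `"smi"`.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "smi")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (format == "csv") {
    out <- data.frame(id = dataset$id, smiles = dataset$smiles,
                      label = ifelse(dataset$label == "unknown", "", dataset$label),
                      stringsAsFactors = FALSE)
    ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE, quote = FALSE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write to: ", path)
  } else {
    writeLines(paste(dataset$smiles, dataset$id, sep = "\t"), path)
  }
  invisible(path)
}
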