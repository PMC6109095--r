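#' Amino-acid physico-chemical property tables
#'
#' Loads the seven scalar property scales used to describe an amino-acid
#' substitution: average residue mass (Da), percentage of buried residues,
#' van der Waals volume (cubic Angstrom), polarity ranking, charge
#' (elementary units; D/E = -1, K/R = +1, H = 0), hydrophobicity ranking and
#' alpha-helix propensity (kcal/mol, lower = stronger helix former). Each
#' scale covers all 20 standard residues; the loader verifies completeness.
#'
#' @param path optional path to an alternative property TSV (column `aa`
#'   plus one column per scale).
#' @return Named list of numeric vectors, each of length 20 with residue
#'   one-letter names.
#' @export
load_aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "navvar")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  aas <- amino_acids()
  if (!setequal(tab$aa, aas) || nrow(tab) != 20L) {
    stop("property table must contain exactly the 20 standard residues")
  }
  scales <- setdiff(names(tab), "aa")
  out <- lapply(scales, function(s) {
    v <- tab[[s]]
    if (anyNA(v)) stop("property '", s, "' has missing entries")
    stats::setNames(as.numeric(v), tab$aa)[aas]
  })
  names(out) <- scales
  out
}

load_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           row.names = 1L)
  m <- as.matrix(tab)
  aas <- amino_acids()
  if (!setequal(rownames(m), aas) || !setequal(colnames(m), aas)) {
    stop("matrix file '", path, "' must be 20x20 over the standard residues")
  }
  m[aas, aas]
}

#' Grantham distance matrix
#'
#' The 20x20 physico-chemical dissimilarity between amino-acid pairs based
#' on composition, polarity and molecular volume, mean-normalised so the
#' average pair distance is 100. Symmetric with zero diagonal; the loader
#' enforces both.
#'
#' @param path optional alternative matrix TSV.
#' @return 20x20 numeric matrix.
#' @export
load_grantham <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grantham.tsv", package = "navvar")
  }
  m <- load_matrix_tsv(path)
  if (any(diag(m) != 0)) stop("Grantham matrix must have a zero diagonal")
  if (any(m != t(m))) stop("Grantham matrix must be symmetric")
  m
}

#' Gonnet-250 substitution matrix
#'
#' The published log-odds substitution-likelihood matrix estimated from
#' exhaustively aligned protein pairs at 250 PAM, used both as an alignment
#' scoring matrix and as a per-substitution likelihood feature.
#'
#' @param path optional alternative matrix TSV.
#' @return 20x20 numeric matrix (symmetric log-odds scores).
#' @export
load_gonnet <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gonnet250.tsv", package = "navvar")
  }
  load_matrix_tsv(path)
}

check_residues <- function(...) {
  aas <- amino_acids()
  for (x in list(...)) {
    bad <- !x %in% aas
    if (any(bad)) {
      stop("nonstandard residue code: '", x[bad][1L], "'")
    }
  }
  invisible(TRUE)
}

#' Signed property change of a substitution
#'
#' The difference in a scalar property between the replacement and the
#' original residue (new minus old), the sign convention used throughout.
#'
#' @param table named numeric vector over the 20 residues (one element of
#'   [load_aa_properties()]).
#' @param from_aa,to_aa one-letter residue codes (vectorised).
#' @return Signed numeric vector `table[to] - table[from]`.
#' @export
property_delta <- function(table, from_aa, to_aa) {
  check_residues(from_aa, to_aa)
  unname(table[to_aa] - table[from_aa])
}

#' Pairwise matrix lookup for a substitution
#'
#' @param matrix 20x20 matrix from [load_grantham()] or [load_gonnet()].
#' @param from_aa,to_aa one-letter residue codes (vectorised).
#' @return Numeric vector of matrix entries.
#' @export
pairwise_score <- function(matrix, from_aa, to_aa) {
  check_residues(from_aa, to_aa)
  unname(matrix[cbind(from_aa, to_aa)])
}

#' Grouped distribution summary for property changes
#'
#' Box-plot statistics (quartiles, median, mean, whiskers at 1.5 IQR) of a
#' numeric property delta within outcome groups, as used to compare property
#' changes between variants affecting different aspects of the current.
#'
#' @param values numeric vector of property deltas.
#' @param groups factor or character vector of the same length.
#' @return data.frame with one row per group: `n`, `q1`, `median`, `q3`,
#'   `mean`, `whisker_low`, `whisker_high`.
#' @export
property_group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  res <- lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3L] - q[1L]
    lo <- v[v >= q[1L] - 1.5 * iqr]
    hi <- v[v <= q[3L] + 1.5 * iqr]
    data.frame(group = g, n = length(v), q1 = q[1L], median = q[2L],
               q3 = q[3L], mean = mean(v),
               whisker_low = if (length(lo)) min(lo) else NA_real_,
               whisker_high = if (length(hi)) max(hi) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
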