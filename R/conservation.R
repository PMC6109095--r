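#' Multiple alignment container for conservation scoring
#'
#' Wraps a set of aligned homolog sequences (rows of equal length, `-` for
#' gaps) with the name of the reference row. The degapped reference must
#' have one residue per protein position.
#'
#' @param sequences named character vector of aligned rows.
#' @param reference_name name of the reference row.
#' @return Object of class `msa_alignment`.
#' @export
msa_alignment <- function(sequences, reference_name) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all alignment rows must be named")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate alignment row names")
  if (!reference_name %in% names(sequences)) {
    stop("reference row '", reference_name, "' not present in alignment")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  structure(list(sequences = toupper(sequences),
                 reference_name = reference_name),
            class = "msa_alignment")
}

#' Read an aligned FASTA file as an alignment
#'
#' @param path aligned FASTA file.
#' @param reference_name reference row; defaults to the first record.
#' @return An `msa_alignment`.
#' @export
read_alignment_fasta <- function(path, reference_name = NULL) {
  seqs <- read_fasta(path)
  if (is.null(reference_name)) reference_name <- names(seqs)[1L]
  msa_alignment(seqs, reference_name)
}

#' Read a Clustal (.aln) alignment
#'
#' Parses the blocked Clustal format: a header line, then blocks of
#' `name  sequence` rows (optionally followed by per-column conservation
#' marks), with each sequence split across blocks.
#'
#' @param path Clustal-format alignment file.
#' @param reference_name reference row; defaults to the first sequence.
#' @return An `msa_alignment`.
#' @export
read_alignment_clustal <- function(path, reference_name = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L])) {
    stop("not a Clustal alignment file: ", path)
  }
  chunks <- regmatches(lines[-1L],
                       regexec("^(\\S+)\\s+([A-Za-z.*~-]+)\\s*[0-9]*\\s*$",
                               lines[-1L]))
  seqs <- list()
  for (m in chunks) {
    if (length(m) != 3L) next
    nm <- m[2L]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], m[3L])
  }
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  seqs <- unlist(seqs)
  if (is.null(reference_name)) reference_name <- names(seqs)[1L]
  msa_alignment(seqs, reference_name)
}

alignment_rows <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$sequences), ""))
}

#' Map alignment columns to reference positions
#'
#' @param alignment an `msa_alignment`.
#' @return Integer vector, one entry per alignment column: the 1-based
#'   reference position, or `NA` for columns where the reference is gapped.
#'   Non-`NA` entries are strictly increasing.
#' @export
map_columns_to_reference <- function(alignment) {
  ref <- strsplit(alignment$sequences[[alignment$reference_name]], "")[[1L]]
  pos <- rep(NA_integer_, length(ref))
  resid <- ref != "-"
  pos[resid] <- seq_len(sum(resid))
  pos
}

#' Per-position conservedness from an alignment
#'
#' For each reference position, the conservedness score is the mean over
#' non-reference rows of the Gonnet-250 log-odds score between the reference
#' residue and that row's residue in the same column; gap (or nonstandard)
#' characters score a fixed penalty. Higher scores mean the position is
#' occupied by the same or similar residues across homologs.
#'
#' @param alignment an `msa_alignment` whose degapped reference covers the
#'   positions of interest.
#' @param positions reference positions to score; default all.
#' @param gonnet substitution matrix; default [load_gonnet()].
#' @param gap_penalty score for a gap row; default one less than the matrix
#'   minimum, so a deletion is always worse than the worst substitution.
#' @return Named numeric vector of scores, one per requested position.
#' @export
conservedness <- function(alignment, positions = NULL,
                          gonnet = load_gonnet(),
                          gap_penalty = min(gonnet) - 1) {
  stopifnot(inherits(alignment, "msa_alignment"))
  colmap <- map_columns_to_reference(alignment)
  n_ref <- max(colmap, na.rm = TRUE)
  if (is.null(positions)) positions <- seq_len(n_ref)
  bad <- positions < 1L | positions > n_ref
  if (any(bad)) {
    stop("position(s) not mapped to an alignment column: ",
         paste(utils::head(positions[bad], 5L), collapse = ", "))
  }
  rows <- alignment_rows(alignment)
  ref_i <- match(alignment$reference_name, names(alignment$sequences))
  others <- rows[-ref_i, , drop = FALSE]
  refrow <- rows[ref_i, ]
  cols <- match(positions, colmap)
  aas <- amino_acids()
  vapply(seq_along(cols), function(k) {
    ci <- cols[k]
    r <- refrow[ci]
    obs <- others[, ci]
    scores <- ifelse(obs %in% aas, gonnet[cbind(rep(r, length(obs)),
                                                ifelse(obs %in% aas, obs, "A"))],
                     gap_penalty)
    mean(scores)
  }, numeric(1)) -> out
  names(out) <- positions
  out
}
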