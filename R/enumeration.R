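#' Enumerate missense substitutions reachable by one nucleotide change
#'
#' Walks every codon of a coding sequence and classifies all nine possible
#' single-nucleotide variants of that codon under the standard genetic code.
#' Synonymous changes and stop gains are excluded; what remains is the set
#' of amino-acid substitutions a single point mutation can produce. Both the
#' with-duplicates total (each nucleotide route counted separately) and the
#' unique total (distinct position/target pairs, i.e. distinct mutant gene
#' products) are reported, together with the 20x20 census of x-to-y
#' transitions.
#'
#' @param cds coding nucleotide sequence: a single character string, a
#'   character vector of single bases, or a `Biostrings::DNAString`. Length
#'   must be a multiple of 3; stop codons (including a trailing one) encode
#'   no residue and contribute no substitutions. Internal stop codons
#'   trigger a warning, not an error, so toy sequences are fine.
#' @return A `substitution_census`: list with `substitutions` (data.frame
#'   `position`, `from_aa`, `to_aa`, `n_routes`), `protein` (reference
#'   residues), `total_with_duplicates`, `total_unique`, `n_positions`,
#'   and `transition_matrix` (20x20 with-duplicates counts, rows = original
#'   residue, columns = replacement).
#' @examples
#' cen <- enumerate_missense("AAA")  # lysine codon
#' cen$total_with_duplicates         # 7
#' cen$total_unique                  # 6
#' @export
enumerate_missense <- function(cds) {
  cds <- as_base_vector(cds)
  n <- length(cds)
  if (n == 0L) stop("empty coding sequence")
  if (n %% 3L != 0L) {
    stop("coding sequence length (", n, ") is not a multiple of 3")
  }
  bad <- which(!cds %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("non-ACGT character '", cds[bad[1L]], "' at nucleotide position ",
         bad[1L])
  }
  code <- Biostrings::GENETIC_CODE
  n_codons <- n %/% 3L
  codons <- paste0(cds[seq(1L, n, 3L)], cds[seq(2L, n, 3L)], cds[seq(3L, n, 3L)])
  protein <- unname(code[codons])
  internal_stops <- which(protein == "*")
  internal_stops <- internal_stops[internal_stops < n_codons]
  if (length(internal_stops) > 0L) {
    warning("internal stop codon(s) at protein position(s) ",
            paste(utils::head(internal_stops, 5L), collapse = ", "))
  }

  bases <- c("A", "C", "G", "T")
  # All 9 single-nucleotide neighbours of each distinct codon, precomputed.
  neighbour_aa <- lapply(stats::setNames(nm = unique(codons)), function(cod) {
    split <- strsplit(cod, "")[[1L]]
    out <- character(0)
    for (i in 1:3) {
      for (b in setdiff(bases, split[i])) {
        mut <- split
        mut[i] <- b
        out <- c(out, unname(code[paste(mut, collapse = "")]))
      }
    }
    out
  })

  subs <- vector("list", n_codons)
  for (p in seq_len(n_codons)) {
    from <- protein[p]
    if (from == "*") next  # stop codons encode no residue to substitute
    targets <- neighbour_aa[[codons[p]]]
    targets <- targets[targets != "*" & targets != from]
    if (length(targets) == 0L) next
    tab <- table(targets)
    subs[[p]] <- data.frame(
      position = p,
      from_aa = from,
      to_aa = names(tab),
      n_routes = as.integer(tab),
      stringsAsFactors = FALSE
    )
  }
  subs <- subs[!vapply(subs, is.null, logical(1))]
  if (length(subs) == 0L) {
    substitutions <- data.frame(position = integer(0), from_aa = character(0),
                                to_aa = character(0), n_routes = integer(0))
  } else {
    substitutions <- do.call(rbind, subs)
    rownames(substitutions) <- NULL
  }

  aas <- amino_acids()
  tm <- matrix(0L, 20L, 20L, dimnames = list(from = aas, to = aas))
  if (nrow(substitutions) > 0L) {
    agg <- stats::aggregate(n_routes ~ from_aa + to_aa,
                            data = substitutions, FUN = sum)
    tm[cbind(agg$from_aa, agg$to_aa)] <- agg$n_routes
  }

  structure(
    list(
      substitutions = substitutions,
      protein = protein,
      n_positions = n_codons,
      total_with_duplicates = sum(substitutions$n_routes),
      total_unique = nrow(substitutions),
      transition_matrix = tm
    ),
    class = "substitution_census"
  )
}

#' @export
print.substitution_census <- function(x, ...) {
  cat(sprintf(
    "substitution_census: %d positions; %d possible substitutions (%d with duplicates)\n",
    x$n_positions, x$total_unique, x$total_with_duplicates))
  invisible(x)
}

amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

as_base_vector <- function(cds) {
  if (inherits(cds, "DNAString") || inherits(cds, "DNAStringSet")) {
    cds <- as.character(cds)
  }
  if (is.character(cds) && length(cds) == 1L) {
    cds <- strsplit(cds, "")[[1L]]
  }
  toupper(as.character(cds))
}

#' Expected transition frequencies under unbiased point mutation
#'
#' Normalises the with-duplicates transition census into the 20x20
#' distribution of x-to-y substitutions that unbiased single-nucleotide
#' changes would produce on this coding sequence.
#'
#' @param census a `substitution_census`.
#' @return 20x20 matrix of proportions summing to 1.
#' @export
expected_transition_frequencies <- function(census) {
  stopifnot(inherits(census, "substitution_census"))
  total <- sum(census$transition_matrix)
  if (total == 0L) stop("census contains no substitutions")
  census$transition_matrix / total
}

#' Observed/expected ratio of amino-acid transitions
#'
#' Compares the transitions seen in a set of observed substitutions with the
#' frequencies expected from unbiased single-nucleotide changes on the same
#' coding sequence. Cells where the expected frequency is zero (transitions
#' needing two or more nucleotide changes) are undefined and returned as
#' `NA`; observing such a transition raises a warning since it cannot arise
#' from a single point mutation on this CDS.
#'
#' @param observed data.frame with columns `position`, `from_aa`, `to_aa`.
#'   Each `from_aa` must match the census reference residue at `position`.
#' @param census a `substitution_census` for the reference CDS.
#' @return 20x20 matrix of observed/expected ratios (`NA` where expected is
#'   zero), with the observed and expected proportion matrices attached as
#'   attributes `observed` and `expected`.
#' @export
observed_expected_ratio <- function(observed, census) {
  stopifnot(inherits(census, "substitution_census"))
  aas <- amino_acids()
  expected <- expected_transition_frequencies(census)
  obs <- matrix(0, 20L, 20L, dimnames = dimnames(expected))
  if (nrow(observed) > 0L) {
    ref <- census$protein[observed$position]
    mismatch <- ref != observed$from_aa
    if (any(mismatch)) {
      i <- which(mismatch)[1L]
      stop("reference mismatch at position ", observed$position[i],
           ": observed from '", observed$from_aa[i],
           "', reference has '", ref[i], "'")
    }
    unreachable <- expected[cbind(observed$from_aa, observed$to_aa)] == 0
    if (any(unreachable)) {
      warning(sum(unreachable), " observed substitution(s) not reachable by ",
              "a single nucleotide change on this CDS")
    }
    tab <- table(factor(observed$from_aa, aas), factor(observed$to_aa, aas))
    obs <- unclass(tab) / nrow(observed)
    dimnames(obs) <- dimnames(expected)
  }
  ratio <- obs / expected
  ratio[expected == 0] <- NA_real_
  attr(ratio, "observed") <- obs
  attr(ratio, "expected") <- expected
  ratio
}
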