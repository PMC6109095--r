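#' Default distance-feature region classes
#'
#' Nearest instance of each segment class S1..S6, the pore-forming S5-S6
#' linker, each inter-domain linker and the two termini.
#'
#' @return Character vector of region-class selectors.
#' @export
default_distance_classes <- function() {
  c("S1", "S2", "S3", "S4", "S5", "S6", "L56", "L12", "L23", "L34", "N", "C")
}

#' Assemble per-variant feature vectors
#'
#' Builds the feature table used for classification: positional features
#' from the topology (membrane side, region kind, region name, residue-count
#' distance to each configured region class), signed physico-chemical
#' property deltas (new minus old) for every scalar property scale, the
#' Grantham distance and Gonnet-250 score of the substitution, and, if
#' provided, the per-position conservedness score.
#'
#' @param variants data.frame with columns `position`, `from_aa`, `to_aa`.
#' @param topology a `protein_topology`.
#' @param properties scalar property list from [load_aa_properties()].
#' @param grantham,gonnet pairwise matrices; defaults load the shipped data.
#' @param conservation optional numeric vector of per-position scores
#'   (length = protein length), e.g. from [conservedness()].
#' @param reference optional reference residue vector; when given, each
#'   `from_aa` is checked against it.
#' @param distance_classes region classes to compute distances for.
#' @return data.frame: identity columns, `side`, `segment_type`,
#'   `region_type` (factors), `dist_*` integer columns, `d_*` property
#'   deltas, `grantham`, `gonnet` and optionally `conservedness`.
#' @export
featurize <- function(variants, topology,
                      properties = load_aa_properties(),
                      grantham = load_grantham(),
                      gonnet = load_gonnet(),
                      conservation = NULL,
                      reference = NULL,
                      distance_classes = default_distance_classes()) {
  pos <- check_positions(topology, variants$position)
  check_residues(variants$from_aa, variants$to_aa)
  if (!is.null(reference)) {
    ref <- reference[pos]
    bad <- ref != variants$from_aa
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("reference mismatch at position ", pos[i], ": variant says '",
           variants$from_aa[i], "', reference has '", ref[i], "'")
    }
  }
  reg <- region_of(topology, pos)
  out <- data.frame(
    position = pos,
    from_aa = variants$from_aa,
    to_aa = variants$to_aa,
    side = factor(reg$side, c("cytoplasmic", "transmembrane", "extracellular")),
    segment_type = factor(reg$kind, c("terminus", "segment", "segment-linker",
                                      "domain-linker")),
    region_type = factor(reg$name, topology$regions$name),
    stringsAsFactors = FALSE)
  for (cls in distance_classes) {
    out[[paste0("dist_", cls)]] <- distance_to(topology, pos, cls)
  }
  for (p in names(properties)) {
    out[[paste0("d_", p)]] <- property_delta(properties[[p]],
                                             variants$from_aa, variants$to_aa)
  }
  out$grantham <- pairwise_score(grantham, variants$from_aa, variants$to_aa)
  out$gonnet <- pairwise_score(gonnet, variants$from_aa, variants$to_aa)
  if (!is.null(conservation)) {
    out$conservedness <- as.numeric(conservation[pos])
  }
  out
}

#' Names of the model-input columns of a feature table
#'
#' Everything except the identifier columns (`position`, `from_aa`,
#' `to_aa`, `variant`) and the `label`.
#'
#' @param features feature data.frame.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features),
          c("position", "from_aa", "to_aa", "variant", "label"))
}

#' One-hot encode categorical feature columns
#'
#' Expands factor/character columns into 0/1 indicator columns for learners
#' that only accept numeric input (k-nearest-neighbour, SVM, MLP).
#'
#' @param features feature data.frame.
#' @return Numeric matrix with one column per indicator or numeric feature.
#' @export
one_hot <- function(features) {
  cols <- lapply(names(features), function(nm) {
    v <- features[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    } else {
      v <- as.factor(v)
      m <- outer(v, levels(v), "==") * 1
      colnames(m) <- paste0(nm, "=", levels(v))
    }
    m
  })
  do.call(cbind, cols)
}
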