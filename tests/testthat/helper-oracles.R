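# Independent brute-force oracles and small fixtures shared across tests.

# Binary MCC straight from the textbook formula.
oracle_mcc_binary <- function(tp, tn, fp, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

# AUC by exhaustive concordant-pair counting (ties get half credit).
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Information gain for a categorical feature by direct entropy arithmetic.
oracle_info_gain <- function(feature, labels) {
  ent <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h <- ent(labels)
  cond <- 0
  for (v in unique(feature)) {
    sel <- feature == v
    cond <- cond + mean(sel) * ent(labels[sel])
  }
  h - cond
}

# All nine single-nucleotide neighbours of a codon, classified one by one.
oracle_codon_substitutions <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  from <- unname(code[codon])
  split <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), split[i])) {
      mut <- split
      mut[i] <- b
      aa <- unname(code[paste(mut, collapse = "")])
      if (aa != "*" && aa != from) out <- c(out, aa)
    }
  }
  out
}

# A small hand-buildable topology (no full-channel invariants).
toy_topology <- function() {
  protein_topology(data.frame(
    name = c("N", "R1", "MID", "R2", "C"),
    kind = c("terminus", "segment", "domain-linker", "segment", "terminus"),
    domain = c(0L, 1L, 0L, 2L, 0L),
    segment = c(0L, 1L, 0L, 1L, 0L),
    start = c(1L, 11L, 21L, 31L, 41L),
    end = c(10L, 20L, 30L, 40L, 50L),
    side = c("cytoplasmic", "transmembrane", "cytoplasmic",
             "transmembrane", "cytoplasmic"),
    stringsAsFactors = FALSE))
}

# Minimal valid EP report rows for constructed scenarios.
make_report <- function(variant = "A10V", position = 10L, from_aa = "A",
                        to_aa = "V", study_id = "s1", year = 2005L,
                        cell_type = "HEK", alpha_subunit = "a",
                        beta1 = "no", zero_current = "unaffected",
                        activation = "not_measured",
                        inactivation = "not_measured",
                        late = "not_measured",
                        act_shift_mV = NA_real_,
                        inact_shift_mV = NA_real_) {
  data.frame(variant = variant, position = position, from_aa = from_aa,
             to_aa = to_aa, study_id = study_id, year = year,
             cell_type = cell_type, alpha_subunit = alpha_subunit,
             beta1 = beta1, zero_current = zero_current,
             activation = activation, inactivation = inactivation,
             late = late, act_shift_mV = act_shift_mV,
             inact_shift_mV = inact_shift_mV, stringsAsFactors = FALSE)
}
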