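test_that("single-codon censuses match hand enumeration", {
  # AAA (Lys): TAA stop and AAG synonym excluded from the 9 neighbours
  cen <- enumerate_missense("AAA")
  expect_identical(cen$total_with_duplicates, 7L)
  expect_identical(cen$total_unique, 6L)
  expect_setequal(cen$substitutions$to_aa, c("Q", "E", "T", "R", "I", "N"))
  # ATG (Met): no stops or synonyms among the 9 neighbours
  cen <- enumerate_missense("ATG")
  expect_identical(cen$total_with_duplicates, 9L)
  expect_identical(cen$total_unique, 6L)
  expect_setequal(cen$substitutions$to_aa, c("L", "V", "K", "T", "R", "I"))
})

test_that("vectorised census agrees with the 9-way brute force per codon", {
  set.seed(7)
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), 150, TRUE), ncol = 3),
                  1, paste, collapse = "")
  codons <- codons[Biostrings::GENETIC_CODE[codons] != "*"]
  for (cod in codons[1:40]) {
    cen <- enumerate_missense(cod)
    expected <- oracle_codon_substitutions(cod)
    expect_identical(cen$total_with_duplicates, length(expected))
    expect_setequal(cen$substitutions$to_aa, unique(expected))
  }
  # totals over a multi-codon CDS are the per-codon sums
  cds <- paste(codons[1:30], collapse = "")
  cen <- enumerate_missense(cds)
  per_codon <- vapply(codons[1:30],
                      function(c) length(oracle_codon_substitutions(c)),
                      integer(1))
  expect_identical(cen$total_with_duplicates, sum(per_codon))
  expect_identical(cen$n_positions, 30L)
  expect_true(cen$total_unique <= cen$total_with_duplicates)
})

test_that("census depends on the codons, not only on the protein", {
  # leucine encoded as TTA vs CTC reaches different neighbour sets
  a <- enumerate_missense("TTA")
  b <- enumerate_missense("CTC")
  expect_false(identical(sort(a$substitutions$to_aa),
                         sort(b$substitutions$to_aa)) &&
                 a$total_with_duplicates == b$total_with_duplicates)
})

test_that("input validation names the offending position", {
  expect_error(enumerate_missense("AAXAAA"), "position 3")
  expect_error(enumerate_missense("AAAA"), "multiple of 3")
  expect_warning(enumerate_missense("AAATAAAAA"), "internal stop")
})

test_that("expected frequencies normalise the with-duplicates census", {
  cen <- enumerate_missense("AAA")
  freq <- expected_transition_frequencies(cen)
  expect_equal(sum(freq), 1)
  expect_equal(freq["K", "N"], 2 / 7)     # AAC and AAT both give Asn
  expect_equal(freq["K", "Q"], 1 / 7)
  expect_true(all(freq[setdiff(rownames(freq), "K"), ] == 0))
  # transitions needing two nucleotide changes have zero mass
  expect_equal(freq["K", "W"], 0)
})

test_that("observed/expected ratios match hand arithmetic on a toy census", {
  # CGT (Arg) reaches S,G,C,H,P,L once each: expected 1/6 per target
  cen <- enumerate_missense("CGT")
  obs <- data.frame(position = 1L,
                    from_aa = "R",
                    to_aa = c(rep("H", 5), rep("C", 5)),
                    stringsAsFactors = FALSE)
  ratio <- observed_expected_ratio(obs, cen)
  expect_equal(ratio["R", "H"], 0.5 / (1 / 6))
  expect_equal(ratio["R", "C"], 3)
  expect_equal(ratio["R", "G"], 0)
  expect_true(is.na(ratio["A", "V"]))  # not reachable on this CDS

  # observed drawn exactly proportional to expected: defined ratios are 1
  cds <- "ATGCGTAAATTC"
  cen <- enumerate_missense(cds)
  subs <- cen$substitutions
  obs <- subs[rep(seq_len(nrow(subs)), subs$n_routes),
              c("position", "from_aa", "to_aa")]
  ratio <- observed_expected_ratio(obs, cen)
  defined <- !is.na(ratio)
  expect_equal(unname(ratio[defined & attr(ratio, "observed") > 0]),
               rep(1, sum(defined & attr(ratio, "observed") > 0)))

  # empty observation set: zero ratios where defined
  ratio0 <- observed_expected_ratio(obs[0, ], cen)
  expect_true(all(ratio0[!is.na(ratio0)] == 0))
})

test_that("reference mismatches and unreachable observations are flagged", {
  cen <- enumerate_missense("CGT")
  expect_error(
    observed_expected_ratio(
      data.frame(position = 1L, from_aa = "K", to_aa = "H"), cen),
    "reference mismatch")
  expect_warning(
    observed_expected_ratio(
      data.frame(position = 1L, from_aa = "R", to_aa = "W"), cen),
    "not reachable")
})
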