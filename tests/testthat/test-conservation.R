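gonnet <- load_gonnet()

test_that("column-to-reference mapping handles gaps", {
  aln <- msa_alignment(c(ref = "ACD", h1 = "AGD"), "ref")
  expect_identical(map_columns_to_reference(aln), 1:3)
  aln <- msa_alignment(c(ref = "A-C", h1 = "AGC"), "ref")
  expect_identical(map_columns_to_reference(aln), c(1L, NA, 2L))
  # mapped positions strictly increasing regardless of row order
  aln2 <- msa_alignment(c(h1 = "AGC", ref = "A-C"), "ref")
  expect_identical(map_columns_to_reference(aln2),
                   map_columns_to_reference(aln))
})

test_that("alignment construction rejects malformed input", {
  expect_error(msa_alignment(c(a = "AC", b = "ACG"), "a"), "unequal")
  expect_error(msa_alignment(c(a = "AC", b = "AC"), "zz"), "not present")
  expect_error(msa_alignment(c("AC", "AC"), "a"), "named")
})

test_that("conservedness is the mean Gonnet score against the reference", {
  aln <- msa_alignment(c(ref = "R", h1 = "R", h2 = "R"), "ref")
  expect_equal(unname(conservedness(aln, 1, gonnet)), gonnet["R", "R"])
  aln <- msa_alignment(c(ref = "R", h1 = "H", h2 = "K"), "ref")
  expect_equal(unname(conservedness(aln, 1, gonnet)),
               (gonnet["R", "H"] + gonnet["R", "K"]) / 2)
  gp <- min(gonnet) - 1
  aln <- msa_alignment(c(ref = "R", h1 = "-", h2 = "-"), "ref")
  expect_equal(unname(conservedness(aln, 1, gonnet)), gp)
})

test_that("scores are invariant to row order and to renaming", {
  aln1 <- msa_alignment(c(ref = "RKD", h1 = "HK-", h2 = "RAD"), "ref")
  aln2 <- msa_alignment(c(h2 = "RAD", ref = "RKD", h1 = "HK-"), "ref")
  aln3 <- msa_alignment(c(ref = "RKD", zz = "HK-", qq = "RAD"), "ref")
  expect_equal(conservedness(aln1, gonnet = gonnet),
               conservedness(aln2, gonnet = gonnet))
  expect_equal(conservedness(aln1, gonnet = gonnet),
               conservedness(aln3, gonnet = gonnet))
})

test_that("adding a reference-identical row never lowers the score", {
  # holds because each Gonnet row attains its maximum on the diagonal
  expect_true(all(diag(gonnet) == apply(gonnet, 1, max)))
  aln <- msa_alignment(c(ref = "RKDW", h1 = "HADW", h2 = "R-EW"), "ref")
  base <- conservedness(aln, gonnet = gonnet)
  more <- conservedness(
    msa_alignment(c(ref = "RKDW", h1 = "HADW", h2 = "R-EW", h3 = "RKDW"),
                  "ref"), gonnet = gonnet)
  expect_true(all(more >= base))
})

test_that("aligned FASTA and Clustal readers produce the same alignment", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ref", "RK-D", ">hom1", "RKAD"), fa)
  a_fa <- read_alignment_fasta(fa)
  expect_identical(unname(a_fa$sequences["ref"]), "RK-D")
  expect_identical(a_fa$reference_name, "ref")
  aln <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL 2.1 multiple sequence alignment", "",
               "ref             RK",
               "hom1            RK",
               "                **", "",
               "ref             -D",
               "hom1            AD",
               "                 *", ""), aln)
  a_cl <- read_alignment_clustal(aln)
  expect_identical(a_cl$sequences, a_fa$sequences)
  expect_error(read_alignment_clustal(fa), "not a Clustal")
})

test_that("unmapped positions are rejected", {
  aln <- msa_alignment(c(ref = "A-C", h1 = "AGC"), "ref")
  expect_error(conservedness(aln, 3, gonnet), "not mapped")
})
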