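topo <- load_topology()

test_that("shipped Nav1.5 topology validates and tiles the protein", {
  expect_length(validate_topology(topo), 0)
  expect_identical(topo$length, 2016L)
  lens <- topo$regions$end - topo$regions$start + 1L
  expect_identical(sum(lens), topo$length)
  # every residue belongs to exactly one region
  counts <- integer(topo$length)
  for (i in seq_len(nrow(topo$regions))) {
    idx <- topo$regions$start[i]:topo$regions$end[i]
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(counts == 1L))
})

test_that("region and side lookups match known landmarks", {
  expect_identical(region_of(topo, 1)$name, "N")
  expect_identical(region_of(topo, 2016)$name, "C")
  # the common polymorphism H558R lies in the DI-DII linker
  expect_identical(region_of(topo, 558)$name, "L12")
  # Q1077 (the isoform-2 deletion site) lies in the DII-DIII linker
  expect_identical(region_of(topo, 1077)$name, "L23")
  expect_identical(side_of(topo, 1), "cytoplasmic")
  seg <- topo$regions[topo$regions$kind == "segment", ]
  expect_true(all(side_of(topo, seg$start) == "transmembrane"))
  pore <- topo$regions[grepl("L56$", topo$regions$name), ]
  expect_true(all(side_of(topo, pore$start) == "extracellular"))
  expect_true(all(topo$regions$voltage_sensing ==
                    grepl("S4$", topo$regions$name)))
})

test_that("position bounds are enforced with the offending value", {
  expect_error(region_of(topo, 0), "0")
  expect_error(region_of(topo, 2017), "2017")
  expect_error(side_of(topo, -5), "-5")
})

test_that("distances count residues to the nearest matching region", {
  d1s4 <- topo$regions[topo$regions$name == "D1S4", ]
  expect_identical(distance_to(topo, d1s4$start + 2L, "S4"), 0L)
  expect_identical(distance_to(topo, d1s4$start - 1L, "S4"), 1L)
  # brute-force scan over every residue of every matching region
  l34 <- topo$regions[topo$regions$name == "L34", ]
  brute <- min(abs(558 - c(l34$start, l34$end)))
  expect_identical(distance_to(topo, 558, "L34"), as.integer(brute))
  expect_error(distance_to(topo, 100, "S9"), "unknown region class")
})

test_that("distance is zero exactly on containment and is 1-Lipschitz", {
  set.seed(11)
  classes <- c("S4", "L56", "L12", "N", "C", "domain-linker")
  for (cls in classes) {
    pos <- sample(topo$length, 60)
    d <- distance_to(topo, pos, cls)
    idx <- navvar:::match_region_class(topo, cls)
    inside <- vapply(pos, function(p) {
      any(p >= topo$regions$start[idx] & p <= topo$regions$end[idx])
    }, logical(1))
    expect_identical(d == 0L, inside)
  }
  pos <- sample(topo$length - 1L, 200)
  for (cls in c("S4", "L34", "C")) {
    step <- abs(distance_to(topo, pos + 1L, cls) - distance_to(topo, pos, cls))
    expect_true(all(step <= 1L))
  }
})

test_that("validator reports gaps, overlaps and structural defects", {
  r <- toy_topology()$regions
  gap <- r
  gap$start[3] <- 22L
  v <- validate_topology(protein_topology(gap, length = 50L))
  expect_true(any(grepl("gap", v)))
  ovl <- r
  ovl$end[2] <- 25L
  v <- validate_topology(protein_topology(ovl, length = 50L))
  expect_true(any(grepl("overlap", v)))
  # toy topology is not a full channel: domain/segment census must fail
  expect_true(any(grepl("segments 1..6|4 domains|domain",
                        validate_topology(toy_topology()))))
})
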