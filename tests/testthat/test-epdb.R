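test_that("majority vote follows the published resolution rule", {
  expect_identical(majority_vote(c("affected", "affected", "unaffected")),
                   "affected")
  expect_identical(majority_vote(c("affected", "unaffected")), "excluded_tie")
  expect_identical(majority_vote(c("not_measured", "not_measured")), "unknown")
  expect_identical(majority_vote(character(0)), "unknown")
  expect_error(majority_vote("maybe"), "unknown finding")
})

test_that("majority vote agrees with a brute-force counter on all small cases", {
  lv <- c("affected", "unaffected", "not_measured")
  cases <- expand.grid(a = lv, b = lv, c = lv, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    v <- unlist(cases[i, ])
    na <- sum(v == "affected")
    nu <- sum(v == "unaffected")
    want <- if (na == 0 && nu == 0) "unknown"
            else if (na > nu) "affected"
            else if (nu > na) "unaffected" else "excluded_tie"
    expect_identical(majority_vote(v), want)
    # permutation invariance
    expect_identical(majority_vote(rev(v)), want)
  }
})

test_that("shift discretisation uses closed [-3, 3] middle interval", {
  expect_identical(as.character(discretize_shift(c(-3, 3, 3.01, 0, -3.01))),
                   c("mid", "mid", "pos", "mid", "neg"))
  expect_error(discretize_shift(NaN), "finite")
  expect_error(discretize_shift(Inf), "finite")
  # every finite value lands in exactly one bin
  set.seed(5)
  x <- c(rnorm(200, 0, 10), -3, 3)
  bins <- discretize_shift(x)
  expect_false(anyNA(bins))
  expect_identical(as.character(bins),
                   ifelse(x < -3, "neg", ifelse(x > 3, "pos", "mid")))
})

test_that("preferred-report cascade follows beta1 > subunit b > HEK > year", {
  r <- rbind(make_report(study_id = "s1", beta1 = "no", year = 2010L),
             make_report(study_id = "s2", beta1 = "yes", year = 2001L))
  expect_identical(select_preferred_report(r)$study_id, "s2")

  r <- rbind(make_report(study_id = "s1", beta1 = "yes", alpha_subunit = "a"),
             make_report(study_id = "s2", beta1 = "yes", alpha_subunit = "b"))
  expect_identical(select_preferred_report(r)$study_id, "s2")

  r <- rbind(make_report(study_id = "s1", year = 2004L),
             make_report(study_id = "s2", year = 2012L))
  expect_identical(select_preferred_report(r)$study_id, "s2")

  # each filter only applies when it leaves at least one report
  r <- rbind(make_report(study_id = "s1", beta1 = "no", cell_type = "oocyte",
                         year = 2003L),
             make_report(study_id = "s2", beta1 = "no", cell_type = "CHO",
                         year = 2007L))
  expect_identical(select_preferred_report(r)$study_id, "s2")
  expect_error(select_preferred_report(make_report()[0, ]), "no reports")
})

test_that("selected report is always one of the inputs", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    r <- do.call(rbind, lapply(seq_len(n), function(j) {
      make_report(study_id = paste0("s", j),
                  year = sample(1995:2017, 1),
                  cell_type = sample(c("HEK", "oocyte", "CHO"), 1),
                  alpha_subunit = sample(c("a", "b", "unknown"), 1),
                  beta1 = sample(c("yes", "no", "unknown"), 1))
    }))
    expect_true(select_preferred_report(r)$study_id %in% r$study_id)
  }
})

test_that("variant resolution derives changed/unchanged from any outcome", {
  r <- rbind(
    make_report(variant = "A10V", inactivation = "affected"),
    make_report(variant = "G20R", position = 20L, from_aa = "G", to_aa = "R",
                study_id = "s2", activation = "unaffected",
                inactivation = "unaffected"),
    make_report(variant = "P30L", position = 30L, from_aa = "P", to_aa = "L",
                study_id = "s3", zero_current = "not_measured"))
  res <- resolve_variants(r)
  expect_identical(res$changed_unchanged[res$variant == "A10V"], "affected")
  expect_identical(res$changed_unchanged[res$variant == "G20R"], "unaffected")
  expect_identical(res$changed_unchanged[res$variant == "P30L"], "unknown")
})

test_that("problem datasets drop ties and count the excluded fraction", {
  r <- rbind(
    make_report(variant = "A10V", activation = "affected"),
    make_report(variant = "G20R", position = 20L, from_aa = "G", to_aa = "R",
                study_id = "s2", activation = "affected"),
    make_report(variant = "G20R", position = 20L, from_aa = "G", to_aa = "R",
                study_id = "s3", activation = "unaffected"),
    make_report(variant = "P30L", position = 30L, from_aa = "P", to_aa = "L",
                study_id = "s4"))
  res <- resolve_variants(r)
  ds <- build_problem_dataset(res, "activation")
  expect_identical(ds$variant, "A10V")
  expect_equal(attr(ds, "tie_fraction"), 0.5)
  expect_error(build_problem_dataset(res, "nonsense"))
})

test_that("stratified split is disjoint, exhaustive and reproducible", {
  set.seed(2)
  ds <- data.frame(id = 1:243,
                   label = factor(rep(c("affected", "unaffected"),
                                      c(175, 68))))
  sp <- train_test_split(ds, seed = 10)
  expect_identical(sort(c(sp$train$id, sp$test$id)), 1:243)
  expect_true(abs(nrow(sp$train) - 162) <= 1)
  # class balance preserved on both sides
  expect_equal(mean(sp$train$label == "affected"), 175 / 243,
               tolerance = 0.02)
  sp2 <- train_test_split(ds, seed = 10)
  expect_identical(sp$train$id, sp2$train$id)
  sp3 <- train_test_split(ds, seed = 11)
  expect_false(identical(sp$train$id, sp3$train$id))
})
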