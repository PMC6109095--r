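test_that("Zero-R predicts the training majority with its prior as score", {
  m <- zero_r(rep(c("affected", "unaffected"), c(90, 10)))
  pred <- predict(m, 20)
  expect_true(all(pred == "affected"))
  expect_equal(mean(predict(m, 100) ==
                      rep(c("affected", "unaffected"), c(90, 10))), 0.9)
  prob <- predict(m, 5, type = "prob")
  expect_equal(unname(prob[1, "affected"]), 0.9)
  # deterministic tie-break towards the first factor level
  tie <- zero_r(factor(c("a", "b"), levels = c("b", "a")))
  expect_identical(tie$majority, "b")
  expect_error(zero_r(character(0)), "zero labels")
})

test_that("MCC matches the direct binary formula and its conventions", {
  conf <- matrix(c(45, 10, 20, 25), 2, 2,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  # rows = truth: TP=45, FN=10 is NOT this layout; build explicitly
  conf <- rbind(pos = c(pos = 45, neg = 20), neg = c(pos = 10, neg = 25))
  expect_equal(mcc(conf), oracle_mcc_binary(45, 25, 10, 20))
  expect_equal(mcc(diag(c(7, 9))), 1)
  # all-one-class prediction: denominator factor zero, conventional 0
  expect_equal(mcc(rbind(c(30, 0), c(13, 0))), 0)
  expect_error(mcc(rbind(c(-1, 0), c(0, 1))), "negative")
})

test_that("MCC equals the brute-force formula on 1000 random instances", {
  set.seed(41)
  for (i in 1:1000) {
    counts <- rmultinom(1, sample(4:30, 1), rep(0.25, 4))
    conf <- matrix(counts, 2, 2)
    expect_equal(mcc(conf),
                 oracle_mcc_binary(conf[1, 1], conf[2, 2],
                                   conf[2, 1], conf[1, 2]))
  }
})

test_that("AUC equals exhaustive pair counting and known hand cases", {
  # two positive-negative pairs, exactly one concordant: 0.9 beats the
  # negative 0.5, while 0.4 does not
  expect_equal(roc_auc(c(0.9, 0.4, 0.5), c("pos", "pos", "neg"),
                       positive = "pos"), 0.5)
  # half credit for exact ties
  expect_equal(roc_auc(c(0.9, 0.5, 0.5), c("pos", "pos", "neg"),
                       positive = "pos"), 0.75)
  expect_equal(roc_auc(1:10, rep(c("neg", "pos"), each = 5),
                       positive = "pos"), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c("neg", "pos"), 5),
                       positive = "pos"), 0.5)
  expect_warning(a <- roc_auc(1:3, rep("pos", 3), positive = "pos"),
                 "one class")
  expect_true(is.na(a))
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    labels <- c("pos", "neg", sample(c("pos", "neg"), n - 2, TRUE))
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # ties likely
    expect_equal(roc_auc(scores, labels, positive = "pos"),
                 oracle_auc(scores, labels, "pos"))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- rnorm(40)
  labels <- sample(c("pos", "neg"), 40, TRUE)
  base <- roc_auc(scores, labels, positive = "pos")
  expect_equal(roc_auc(exp(scores), labels, positive = "pos"), base)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels, positive = "pos"), base)
})

test_that("ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(6)
  scores <- rnorm(30)
  labels <- sample(c("pos", "neg"), 30, TRUE, prob = c(0.4, 0.6))
  rc <- roc_curve(scores, labels, positive = "pos")
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
})

test_that("information gain matches hand entropy computations", {
  # feature identical to balanced binary labels: one full bit
  expect_equal(information_gain(c("a", "a", "b", "b"), c("+", "+", "-", "-")),
               1)
  expect_equal(information_gain(rep("a", 10),
                                rep(c("+", "-"), 5)), 0)
  expect_equal(information_gain(c("a", "b", "a", "b"), rep("+", 4)), 0)
})

test_that("information gain agrees with a brute-force oracle on random data", {
  set.seed(43)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    feature <- sample(letters[1:3], n, TRUE)
    labels <- sample(c("+", "-"), n, TRUE)
    expect_equal(information_gain(feature, labels),
                 max(oracle_info_gain(feature, labels), 0))
  }
})

test_that("information gain is invariant to categorical relabeling", {
  set.seed(44)
  feature <- sample(c("x", "y", "z"), 60, TRUE)
  labels <- sample(c("+", "-"), 60, TRUE)
  relabeled <- c(x = "q", y = "r", z = "s")[feature]
  expect_equal(information_gain(feature, labels),
               information_gain(relabeled, labels))
})

test_that("MDL discretisation cuts separable features and not noise", {
  set.seed(45)
  x <- c(rnorm(50, 0), rnorm(50, 10))
  y <- rep(c("a", "b"), each = 50)
  cuts <- mdl_discretize(x, y)
  expect_true(length(cuts) >= 1)
  expect_true(any(cuts > 2 & cuts < 8))
  # label-independent feature: no cut survives the MDL criterion,
  # so the numeric information gain collapses to zero
  x0 <- rnorm(100)
  y0 <- sample(c("a", "b"), 100, TRUE)
  expect_equal(information_gain(x0, y0), 0)
  # the separable feature carries about one bit
  expect_gt(information_gain(x, y), 0.9)
})
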