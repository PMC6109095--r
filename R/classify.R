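#' Classifier families available for the prediction problems
#'
#' @return Character vector of method names.
#' @export
classifier_methods <- function() {
  c("naive_bayes", "random_forest", "knn", "svm", "mlp")
}

default_grid <- function(method, p) {
  switch(method,
    naive_bayes = expand.grid(laplace = c(0, 0.5, 1),
                              discretize = c(FALSE, TRUE)),
    random_forest = expand.grid(
      mtry = sort(unique(pmax(1L, c(2L, floor(sqrt(p)), floor(p / 3)))))),
    knn = expand.grid(k = c(1L, 3L, 5L, 7L, 11L)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(1 / p, 0.1)),
    mlp = expand.grid(size = c(3L, 5L), decay = c(0.01, 0.1)),
    stop("unknown method: '", method, "'"))
}

needs_numeric_input <- function(method) method %in% c("knn", "svm", "mlp")

encode_numeric <- function(features, center = NULL, scale = NULL) {
  m <- one_hot(features)
  if (is.null(center)) {
    center <- colMeans(m)
    scale <- apply(m, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(m, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

fit_classifier <- function(method, features, labels, params) {
  labels <- droplevels(as.factor(labels))
  fit <- list(method = method, levels = levels(labels), params = params)
  if (needs_numeric_input(method)) {
    enc <- encode_numeric(features)
    fit$center <- enc$center
    fit$scale <- enc$scale
    x <- enc$x
  }
  fit$model <- switch(method,
    naive_bayes = {
      if (isTRUE(params$discretize)) {
        # supervised MDL binning of numeric features before fitting; the
        # same cut points are applied at prediction time
        num <- names(features)[vapply(features, is.numeric, logical(1))]
        cuts <- lapply(features[num], mdl_discretize, labels = labels)
        for (nm in num) {
          features[[nm]] <- cut(features[[nm]], c(-Inf, cuts[[nm]], Inf))
        }
        fit$cuts <- cuts
      }
      m <- e1071::naiveBayes(features, labels, laplace = params$laplace)
      # floor the within-class sd of numeric features: a zero spread would
      # otherwise yield NaN densities at prediction time
      for (nm in names(m$tables)) {
        tab <- m$tables[[nm]]
        if (is.matrix(tab) && !is.table(tab) && ncol(tab) == 2L) {
          tab[, 2L][tab[, 2L] < 1e-6] <- 1e-3
          m$tables[[nm]] <- tab
        }
      }
      m
    },
    random_forest = randomForest::randomForest(
      features, labels, ntree = 300L, mtry = params$mtry),
    knn = list(x = x, y = labels),
    svm = e1071::svm(x, labels, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = TRUE,
                     scale = FALSE),
    mlp = nnet::nnet(x, nnet_targets(labels), size = params$size,
                     decay = params$decay, maxit = 200L, softmax = TRUE,
                     trace = FALSE, MaxNWts = 10000L))
  class(fit) <- "navvar_classifier"
  fit
}

nnet_targets <- function(labels) {
  out <- outer(labels, levels(labels), "==") * 1
  colnames(out) <- levels(labels)
  out
}

# Probability matrix (rows = instances, columns = class levels).
predict_classifier <- function(fit, features) {
  lev <- fit$levels
  if (needs_numeric_input(fit$method)) {
    x <- encode_numeric(features, fit$center, fit$scale)$x
  }
  prob <- switch(fit$method,
    naive_bayes = {
      if (!is.null(fit$cuts)) {
        for (nm in names(fit$cuts)) {
          features[[nm]] <- cut(features[[nm]], c(-Inf, fit$cuts[[nm]], Inf))
        }
      }
      stats::predict(fit$model, features, type = "raw")
    },
    random_forest = stats::predict(fit$model, features, type = "prob"),
    knn = {
      pred <- class::knn(fit$model$x, x, fit$model$y, k = fit$params$k,
                         prob = TRUE)
      p_win <- attr(pred, "prob")
      k <- length(lev)
      m <- matrix((1 - p_win) / max(k - 1, 1), nrow = length(pred), ncol = k,
                  dimnames = list(NULL, lev))
      m[cbind(seq_along(pred), match(as.character(pred), lev))] <- p_win
      m
    },
    svm = {
      pred <- stats::predict(fit$model, x, probability = TRUE)
      attr(pred, "probabilities")
    },
    mlp = {
      m <- stats::predict(fit$model, x)
      colnames(m) <- colnames(fit$model$fitted.values)
      m
    })
  prob <- as.matrix(prob)
  prob[, lev, drop = FALSE]
}

# Best achievable MCC over all decision thresholds on a score vector,
# found by sweeping the sorted scores (predict-none included).
best_mcc_threshold <- function(score, labels, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  pos <- labels[ord] == positive
  P <- sum(pos)
  N <- sum(!pos)
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # only cut between distinct score values
  valid <- c(s[-1] != s[-length(s)], TRUE)
  m <- vapply(which(valid), function(k) {
    oracle <- matrix(c(tp[k], P - tp[k], fp[k], N - fp[k]), 2, 2, byrow = TRUE)
    mcc(oracle)
  }, numeric(1))
  ks <- which(valid)
  best <- which.max(c(0, m))  # leading 0: predicting nobody positive
  if (best == 1L) {
    list(mcc = 0, threshold = Inf)
  } else {
    k <- ks[best - 1L]
    thr <- if (k == length(s)) s[k] else (s[k] + s[k + 1L]) / 2
    list(mcc = m[best - 1L], threshold = thr)
  }
}

make_folds <- function(labels, k = 10L) {
  n <- length(labels)
  if (n < 2L * k) {
    k_new <- max(2L, n %/% 2L)
    warning("dataset too small for ", k, "-fold CV; using ", k_new, " folds")
    k <- k_new
  }
  fold <- integer(n)
  for (idx in split(seq_len(n), labels)) {
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune a classifier by cross-validated MCC and evaluate on a held-out test
#' set
#'
#' Implements the full evaluation protocol for one classification problem:
#' the labelled dataset is split into a stratified training set (2/3) and an
#' independent test set (1/3); hyperparameters are chosen by k-fold
#' cross-validation on the training set only, maximising the Matthews
#' correlation of the pooled out-of-fold predictions; the winning model is
#' refit on the whole training set and scored once on the untouched test
#' set. A Zero-R baseline trained on the same training set is evaluated
#' alongside, and every feature's information gain is computed on the
#' training set. All randomness (split, folds, model fitting) derives from
#' `seed`.
#'
#' @param data data.frame with a `label` factor column and feature columns;
#'   any of `position`, `from_aa`, `to_aa`, `variant` are carried as
#'   identifiers and not used as features.
#' @param method one of [classifier_methods()].
#' @param seed integer seed.
#' @param train_fraction training fraction of the stratified split.
#' @param folds cross-validation folds (reduced with a warning when the
#'   training set is too small).
#' @param grid data.frame of hyperparameter combinations; a small default
#'   grid per method is used when `NULL`.
#' @param positive label treated as positive for the binary AUC; default
#'   `"affected"` when present, else the last factor level.
#' @return An `eval_result`: confusion matrix, accuracy, AUC (macro
#'   one-vs-rest for 3+ classes), MCC, the Zero-R baseline metrics, the
#'   chosen hyperparameters, per-feature information gain and the test-set
#'   ROC points (binary problems).
#' @export
tune_and_evaluate <- function(data, method, seed = 1L,
                              train_fraction = 2 / 3, folds = 10L,
                              grid = NULL, positive = NULL) {
  method <- match.arg(method, classifier_methods())
  stopifnot("label" %in% names(data))
  data$label <- droplevels(as.factor(data$label))
  feats <- feature_columns(data)
  if (is.null(grid)) grid <- default_grid(method, length(feats))
  if (is.null(positive)) {
    positive <- if ("affected" %in% levels(data$label)) "affected"
                else levels(data$label)[nlevels(data$label)]
  }

  split <- train_test_split(data, train_fraction, seed = seed)
  train <- split$train
  test <- split$test
  if (!all(levels(data$label) %in% unique(train$label))) {
    warning("a label class is absent from the training set")
  }

  binary <- nlevels(train$label) == 2L
  set.seed(seed)
  fold <- make_folds(train$label, folds)
  cv_mcc <- numeric(nrow(grid))
  thresholds <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pred <- factor(rep(NA_character_, nrow(train)), levels(train$label))
    score <- numeric(nrow(train))
    for (f in sort(unique(fold))) {
      tr <- train[fold != f, , drop = FALSE]
      va <- train[fold == f, , drop = FALSE]
      fit <- fit_classifier(method, tr[, feats, drop = FALSE], tr$label,
                            as.list(grid[g, , drop = FALSE]))
      prob <- predict_classifier(fit, va[, feats, drop = FALSE])
      pred[fold == f] <- colnames(prob)[max.col(prob, ties.method = "first")]
      if (binary) score[fold == f] <- prob[, positive]
    }
    if (binary) {
      # tuning targets the MCC, so the decision threshold on the positive-
      # class score is selected on the pooled out-of-fold predictions too
      sel <- best_mcc_threshold(score, train$label, positive)
      cv_mcc[g] <- sel$mcc
      thresholds[g] <- sel$threshold
    } else {
      cv_mcc[g] <- mcc(truth = train$label, prediction = pred)
    }
  }
  best <- which.max(cv_mcc)
  params <- as.list(grid[best, , drop = FALSE])
  threshold <- thresholds[best]

  fit <- fit_classifier(method, train[, feats, drop = FALSE], train$label,
                        params)
  prob <- predict_classifier(fit, test[, feats, drop = FALSE])
  if (binary) {
    negative <- setdiff(levels(test$label), positive)
    pred <- factor(ifelse(prob[, positive] >= threshold, positive, negative),
                   levels(test$label))
  } else {
    pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                   levels(test$label))
  }
  lev <- levels(test$label)
  confusion <- table(truth = factor(test$label, lev), prediction = pred)

  auc <- if (length(lev) == 2L) {
    roc_auc(prob[, positive], test$label, positive)
  } else {
    mean(vapply(lev, function(l) {
      roc_auc(prob[, l], factor(ifelse(test$label == l, l, "rest"),
                                c("rest", l)), positive = l)
    }, numeric(1)), na.rm = TRUE)
  }

  base <- zero_r(train$label)
  base_pred <- predict(base, test, type = "class")
  baseline <- list(
    accuracy = mean(base_pred == test$label),
    auc = roc_auc(rep(0, nrow(test)), test$label,
                  positive = if (positive %in% lev) positive else lev[1L]),
    mcc = mcc(truth = test$label, prediction = base_pred))

  ig <- vapply(feats, function(f) information_gain(train[[f]], train$label),
               numeric(1))

  structure(list(
    method = method, seed = seed, params = params, threshold = threshold,
    cv_mcc = stats::setNames(cv_mcc, apply(grid, 1L, paste, collapse = "/")),
    n_train = nrow(train), n_test = nrow(test),
    confusion = confusion,
    accuracy = mean(pred == test$label),
    auc = auc,
    mcc = mcc(confusion),
    baseline = baseline,
    info_gain = sort(ig, decreasing = TRUE),
    roc = if (length(lev) == 2L) roc_curve(prob[, positive], test$label,
                                           positive)
  ), class = "eval_result")
}

#' Pooled cross-validated MCC of one method on a full dataset
#'
#' Fits the method with fixed hyperparameters on k-fold splits of the whole
#' dataset and computes the Matthews correlation of the pooled out-of-fold
#' predictions, so the coefficient is estimated at the full dataset size.
#' This is the permutation-null diagnostic: on data with no feature-outcome
#' association the value concentrates on zero.
#'
#' @inheritParams tune_and_evaluate
#' @param params named list of hyperparameters; default the first row of
#'   the method's default grid.
#' @return A single MCC value.
#' @export
cross_validated_mcc <- function(data, method, seed = 1L, folds = 10L,
                                params = NULL) {
  method <- match.arg(method, classifier_methods())
  data$label <- droplevels(as.factor(data$label))
  feats <- feature_columns(data)
  if (is.null(params)) {
    params <- as.list(default_grid(method, length(feats))[1L, , drop = FALSE])
  }
  set.seed(seed)
  fold <- make_folds(data$label, folds)
  pred <- factor(rep(NA_character_, nrow(data)), levels(data$label))
  for (f in sort(unique(fold))) {
    tr <- data[fold != f, , drop = FALSE]
    fit <- fit_classifier(method, tr[, feats, drop = FALSE], tr$label, params)
    prob <- predict_classifier(fit, data[fold == f, feats, drop = FALSE])
    pred[fold == f] <- colnames(prob)[max.col(prob, ties.method = "first")]
  }
  mcc(truth = data$label, prediction = pred)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: %s (seed %d)\n", x$method, x$seed))
  cat(sprintf("  accuracy %.3f (Zero-R %.3f)   AUC %.3f (0.5)   MCC %.3f (0)\n",
              x$accuracy, x$baseline$accuracy, x$auc, x$mcc))
  cat("  top features by information gain:\n")
  top <- utils::head(x$info_gain, 5L)
  for (i in seq_along(top)) {
    cat(sprintf("    %-20s %.3f bits\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' Evaluate prediction of discretised midpoint shifts
#'
#' Three-class variant of [tune_and_evaluate()] for the `neg`/`mid`/`pos`
#' voltage-shift bins: reports accuracy, macro one-vs-rest AUC and the
#' generalised multiclass MCC, against the Zero-R baseline.
#'
#' @param data data.frame with a 3-level `label` column (`neg`, `mid`,
#'   `pos`) and feature columns.
#' @inheritParams tune_and_evaluate
#' @return An `eval_result`.
#' @export
evaluate_shift_problem <- function(data, method, seed = 1L, folds = 10L,
                                   grid = NULL) {
  stopifnot(all(levels(as.factor(data$label)) %in% c("neg", "mid", "pos")))
  data$label <- factor(data$label, c("neg", "mid", "pos"))
  tune_and_evaluate(data, method, seed = seed, folds = folds, grid = grid)
}
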