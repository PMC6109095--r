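#' Zero-R baseline classifier
#'
#' The reference point for every evaluation: predicts the most common
#' training class for every instance, with a constant score. Its accuracy
#' equals the majority-class prevalence of the evaluation set, its AUC is
#' 0.5 and its MCC is 0 by construction. Ties on the class counts are broken
#' deterministically towards the first factor level.
#'
#' @param labels training labels (factor or character).
#' @return Object of class `zero_r` with the majority class and the
#'   training class distribution.
#' @export
zero_r <- function(labels) {
  labels <- as.factor(labels)
  if (length(labels) == 0L) stop("cannot fit Zero-R on zero labels")
  counts <- table(labels)
  structure(
    list(majority = names(counts)[which.max(counts)],
         levels = levels(labels),
         prior = counts / sum(counts)),
    class = "zero_r")
}

#' @param object a `zero_r` model.
#' @param newdata anything with a length/row count, or an integer count.
#' @param type `"class"` for labels, `"prob"` for the constant probability
#'   matrix (the training prior).
#' @param ... unused.
#' @rdname zero_r
#' @export
predict.zero_r <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  n <- if (is.numeric(newdata) && length(newdata) == 1L) newdata
       else if (is.data.frame(newdata)) nrow(newdata)
       else length(newdata)
  if (type == "class") {
    factor(rep(object$majority, n), levels = object$levels)
  } else {
    matrix(rep(as.numeric(object$prior), each = n), nrow = n,
           dimnames = list(NULL, names(object$prior)))
  }
}

#' Matthews correlation coefficient
#'
#' Computes the MCC from a confusion matrix (rows = truth, columns =
#' prediction). For a 2x2 matrix this is the standard binary MCC; for K
#' classes the generalised multiclass form is used. When any factor of the
#' denominator is zero (e.g. the classifier predicts a single class) the
#' coefficient is undefined and the conventional value 0 is returned.
#'
#' @param confusion square numeric matrix of non-negative counts, or `NULL`
#'   if `truth`/`prediction` are given.
#' @param truth,prediction alternative interface: two label vectors.
#' @return Number in `[-1, 1]`.
#' @export
mcc <- function(confusion = NULL, truth = NULL, prediction = NULL) {
  if (is.null(confusion)) {
    lev <- union(levels(as.factor(truth)), levels(as.factor(prediction)))
    confusion <- table(factor(truth, lev), factor(prediction, lev))
  }
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("negative counts in confusion matrix")
  s <- sum(confusion)
  if (s == 0) stop("empty confusion matrix")
  c_ <- sum(diag(confusion))
  t_k <- rowSums(confusion)   # true occurrences per class
  p_k <- colSums(confusion)   # predicted occurrences per class
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney rank statistic: the probability
#' that a randomly chosen positive scores above a randomly chosen negative,
#' with ties receiving half credit. Invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels.
#' @param positive which label value is the positive class; default the
#'   last factor level.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  stopifnot(length(scores) == length(labels))
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   the strictest threshold to the most permissive.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- (labels == positive)[ord]
  # step only at distinct score values
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / max(sum(!pos), 1L)),
             tpr = c(0, tp / max(sum(pos), 1L)))
}

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Supervised MDL discretisation of a numeric feature
#'
#' Recursive entropy-based binary partitioning with the minimum description
#' length stopping criterion: a cut is accepted only when the information
#' gained on the labels exceeds the cost of encoding the partition. Features
#' carrying no label information receive no cut points and collapse to a
#' single bin.
#'
#' @param x numeric feature.
#' @param labels class labels.
#' @return Numeric vector of cut points (possibly empty), suitable for
#'   `cut(x, c(-Inf, cuts, Inf))`.
#' @export
mdl_discretize <- function(x, labels) {
  labels <- as.factor(labels)
  keep <- !is.na(x)
  x <- x[keep]
  y <- labels[keep]
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]

  yk <- as.integer(y)
  K <- nlevels(y)
  row_entropy <- function(m) {
    # entropy in bits of each row of a count matrix
    rs <- rowSums(m)
    p <- m / ifelse(rs == 0, 1, rs)
    -rowSums(ifelse(m > 0, p * log2(p), 0))
  }

  split_interval <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(numeric(0))
    xs <- x[lo:hi]
    cum <- vapply(seq_len(K), function(k) cumsum(yk[lo:hi] == k),
                  numeric(n))
    if (n == 1L) cum <- matrix(cum, nrow = 1L)
    tot <- cum[n, ]
    ent_s <- entropy_bits(tot)
    if (ent_s == 0) return(numeric(0))
    cand <- which(xs[-1] != xs[-n])
    if (length(cand) == 0L) return(numeric(0))
    left <- cum[cand, , drop = FALSE]
    right <- rep(tot, each = length(cand)) - left
    dim(right) <- dim(left)
    e1 <- row_entropy(left)
    e2 <- row_entropy(right)
    e <- (cand / n) * e1 + ((n - cand) / n) * e2
    b <- which.min(e)
    i <- cand[b]
    gain <- ent_s - e[b]
    k <- sum(tot > 0)
    k1 <- sum(left[b, ] > 0)
    k2 <- sum(right[b, ] > 0)
    delta <- log2(3^k - 2) - (k * ent_s - k1 * e1[b] - k2 * e2[b])
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xs[i] + xs[i + 1L]) / 2
    c(split_interval(lo, lo + i - 1L), cut, split_interval(lo + i, hi))
  }

  if (length(x) == 0L) return(numeric(0))
  split_interval(1L, length(x))
}

#' Information gain of a feature about the labels
#'
#' Entropy reduction `H(labels) - sum_v p(v) H(labels | v)` in bits.
#' Numeric features are first discretised with the supervised MDL criterion
#' ([mdl_discretize()]); categorical features are used as-is. Missing values
#' form their own category. A feature independent of the labels (or
#' collapsing to a single bin) has gain 0.
#'
#' @param feature numeric, character or factor vector.
#' @param labels class labels.
#' @return Non-negative number (bits).
#' @export
information_gain <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  labels <- as.factor(labels)
  if (length(labels) < 2L || nlevels(droplevels(labels)) < 2L) return(0)
  if (is.numeric(feature)) {
    cuts <- mdl_discretize(feature, labels)
    feature <- cut(feature, c(-Inf, cuts, Inf))
  }
  feature <- addNA(as.factor(feature), ifany = TRUE)
  h <- entropy_bits(table(labels))
  cond <- 0
  n <- length(labels)
  for (v in levels(feature)) {
    sel <- feature == v
    sel[is.na(sel)] <- FALSE
    nv <- sum(sel)
    if (nv == 0L) next
    cond <- cond + (nv / n) * entropy_bits(table(labels[sel]))
  }
  max(h - cond, 0)
}
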