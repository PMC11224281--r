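#' Confusion matrix
#'
#' Builds a k x k count table with true classes in rows and predicted
#' classes in columns. All classification metrics in the package are
#' computed from this object. For binary problems the positive class (for
#' TP/FP/FN/TN decomposition) is recorded as an attribute; by default it is
#' the last class level, matching the convention that `"leukemic"` is the
#' positive class of the `normal`/`leukemic` labeling.
#'
#' @param truth,predicted Factors (or vectors coercible to factors over the
#'   same classes) of equal length.
#' @param classes Optional explicit class levels (row/column order).
#' @param positive Positive class for the binary decomposition; default the
#'   last level.
#' @return Integer matrix of class `confusion_matrix` with `positive`
#'   attribute.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL,
                             positive = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth)
               else sort(unique(c(as.character(truth), as.character(predicted))))
  }
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  stopifnot(length(truth) == length(predicted), !anyNA(truth), !anyNA(predicted))
  m <- table(truth = truth, predicted = predicted)
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  as_confusion_matrix(m, positive = positive)
}

#' @rdname confusion_matrix
#' @param m A square non-negative integer count matrix (rows = truth).
#' @export
as_confusion_matrix <- function(m, positive = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), nrow(m) >= 2, all(m >= 0),
            all(m == round(m)))
  if (is.null(rownames(m))) {
    dimnames(m) <- list(truth = as.character(seq_len(nrow(m))),
                        predicted = as.character(seq_len(nrow(m))))
  }
  if (is.null(positive)) positive <- rownames(m)[nrow(m)]
  stopifnot(positive %in% rownames(m))
  structure(m, class = c("confusion_matrix", "matrix"),
            positive = positive)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> positive class:", attr(x, "positive"), "\n")
  print(matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

# TP/FP/FN/TN for the positive class of a binary (or binarized) matrix.
.binary_counts <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- attr(cm, "positive")
  p <- which(rownames(cm) == pos)
  tp <- cm[p, p]
  fn <- sum(cm[p, -p])
  fp <- sum(cm[-p, p])
  tn <- sum(cm[-p, -p])
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

.metric_guard <- function(denom, what) {
  if (denom <= 0) stop("undefined metric: ", what, " has a zero denominator")
}

#' Classification metrics from a confusion matrix
#'
#' Precision, recall (sensitivity), accuracy, specificity and F1 score,
#' each as a percentage in \[0, 100\], computed from the positive-class
#' TP/FP/FN/TN decomposition. A zero denominator raises an error rather
#' than returning a sentinel.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar percentage.
#' @examples
#' cm <- as_confusion_matrix(matrix(c(50, 10, 5, 35), 2, byrow = TRUE),
#'                           positive = "1")
#' metric_precision(cm)
#' @name classification-metrics
NULL

#' @rdname classification-metrics
#' @export
metric_precision <- function(cm) {
  b <- .binary_counts(cm)
  .metric_guard(b$tp + b$fp, "precision (TP + FP)")
  100 * b$tp / (b$tp + b$fp)
}

#' @rdname classification-metrics
#' @export
metric_recall <- function(cm) {
  b <- .binary_counts(cm)
  .metric_guard(b$tp + b$fn, "recall (TP + FN)")
  100 * b$tp / (b$tp + b$fn)
}

#' @rdname classification-metrics
#' @export
metric_accuracy <- function(cm) {
  b <- .binary_counts(cm)
  n <- b$tp + b$tn + b$fp + b$fn
  .metric_guard(n, "accuracy (total count)")
  100 * (b$tp + b$tn) / n
}

#' @rdname classification-metrics
#' @export
metric_specificity <- function(cm) {
  b <- .binary_counts(cm)
  .metric_guard(b$tn + b$fp, "specificity (TN + FP)")
  100 * b$tn / (b$tn + b$fp)
}

#' @rdname classification-metrics
#' @export
metric_f1 <- function(cm) {
  b <- .binary_counts(cm)
  .metric_guard(2 * b$tp + b$fp + b$fn, "F1 (2TP + FP + FN)")
  100 * 2 * b$tp / (2 * b$tp + b$fp + b$fn)
}

#' F-beta score
#'
#' The recall-weighted F score with `beta = 2` by default. The `"standard"`
#' variant is `(1 + beta^2) TP / ((1 + beta^2) TP + beta^2 FN + FP)`, a
#' proportion in \[0, 1\]. The `"as_printed"` variant retains an extra
#' `(1 + beta^2)` factor sometimes seen in print, which pushes values above
#' 1; it is kept only to document that form and is not the default.
#'
#' @param cm A [confusion_matrix()].
#' @param beta Recall weight; default 2.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return Scalar score.
#' @export
metric_fbeta <- function(cm, beta = 2, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  b <- .binary_counts(cm)
  b2 <- beta^2
  denom <- (1 + b2) * b$tp + b2 * b$fn + b$fp
  .metric_guard(denom, "F-beta")
  core <- (1 + b2) * b$tp / denom
  if (variant == "as_printed") (1 + b2) * core else core
}

#' Linearly weighted Cohen's kappa
#'
#' Chance-corrected agreement with linear disagreement weights
#' `w_ij = 1 - |i - j| / (k - 1)`: observed weighted agreement
#' `Po = sum(w * f) / N` against the chance expectation
#' `Pe = sum(w * r_i * c_j) / N^2` from the row and column margins, giving
#' `kappa = (Po - Pe) / (1 - Pe)`. For two classes the weights reduce to the
#' identity and this equals plain Cohen's kappa.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar kappa in \[-1, 1\].
#' @examples
#' weighted_kappa(as_confusion_matrix(matrix(c(40, 10, 20, 30), 2, byrow = TRUE)))
#' @export
weighted_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- nrow(cm)
  n <- sum(cm)
  .metric_guard(n, "kappa (total count)")
  idx <- seq_len(k)
  w <- 1 - abs(outer(idx, idx, "-")) / (k - 1)
  po <- sum(w * cm) / n
  pe <- sum(w * outer(rowSums(cm), colSums(cm))) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("undefined metric: degenerate margins give Pe = 1")
  }
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive sample outscores a randomly chosen negative one, with ties
#' credited 0.5.
#'
#' @param scores Numeric scores, higher meaning more positive (e.g. the
#'   positive-class capsule length).
#' @param labels True labels.
#' @param positive Positive class; default the last factor level.
#' @return Scalar AUC in \[0, 1\].
#' @export
metric_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes to be present")
  }
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Jaccard index of two sets
#'
#' `|intersection| / |union|` of two sets of identifiers.
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return Scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) stop("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / length(u)
}

#' Full metric report for a set of predictions
#'
#' Computes all evaluation indexes — precision, recall, accuracy,
#' specificity, F1, F-beta (beta = 2), linearly weighted kappa and (when
#' scores are given) AUC — as a one-row tibble.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param scores Optional positive-class scores for AUC.
#' @param positive Positive class; default the last level.
#' @return One-row tibble of metrics (percentages for precision, recall,
#'   accuracy, specificity and F1; proportions for F-beta, kappa, AUC).
#' @export
metric_report <- function(truth, predicted, scores = NULL, positive = NULL) {
  cm <- confusion_matrix(truth, predicted, positive = positive)
  tibble::tibble(
    precision = metric_precision(cm),
    recall = metric_recall(cm),
    accuracy = metric_accuracy(cm),
    specificity = metric_specificity(cm),
    f1 = metric_f1(cm),
    f_beta = metric_fbeta(cm),
    kappa = weighted_kappa(cm),
    auc = if (is.null(scores)) NA_real_
          else metric_auc(scores, truth, positive = attr(cm, "positive"))
  )
}
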