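cm_from_counts <- function(tp, fp, fn, tn) {
  # positive class in the second row/level
  as_confusion_matrix(
    matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
           dimnames = list(truth = c("neg", "pos"),
                           predicted = c("neg", "pos"))),
    positive = "pos"
  )
}

test_that("hand-evaluated percentage metrics match", {
  cm <- cm_from_counts(tp = 50, fp = 10, fn = 5, tn = 35)
  expect_equal(metric_precision(cm), 100 * 50 / 60, tolerance = 1e-12)
  expect_equal(round(metric_precision(cm), 3), 83.333)
  expect_equal(round(metric_recall(cm), 3), 90.909)
  expect_equal(metric_specificity(cm), 100 * 35 / 45)
  perfect <- cm_from_counts(tp = 50, fp = 0, fn = 0, tn = 50)
  expect_equal(metric_accuracy(perfect), 100)
  expect_equal(metric_f1(perfect), 100)
})

test_that("F-beta has the standard and as-printed variants", {
  cm <- cm_from_counts(tp = 50, fp = 10, fn = 5, tn = 0)
  expect_equal(metric_fbeta(cm, beta = 2), 250 / 280, tolerance = 1e-12)
  expect_equal(metric_fbeta(cm, beta = 2, variant = "as_printed"),
               5 * 250 / 280, tolerance = 1e-12)
  expect_gt(metric_fbeta(cm, variant = "as_printed"), 1)  # documents the anomaly
  expect_equal(metric_fbeta(cm_from_counts(50, 0, 0, 10)), 1)
})

test_that("undefined metrics raise errors instead of returning sentinels", {
  no_pred_pos <- cm_from_counts(tp = 0, fp = 0, fn = 10, tn = 10)
  expect_error(metric_precision(no_pred_pos), "undefined")
  no_true_pos <- cm_from_counts(tp = 0, fp = 10, fn = 0, tn = 10)
  expect_error(metric_recall(no_true_pos), "undefined")
  no_neg <- cm_from_counts(tp = 10, fp = 0, fn = 0, tn = 0)
  expect_error(metric_specificity(no_neg), "undefined")
})

test_that("metrics agree with brute-force recomputation on random predictions", {
  set.seed(33)
  for (rep in 1:1000) {
    n <- sample(8:40, 1)
    truth <- sample(c("neg", "pos"), n, replace = TRUE)
    pred <- sample(c("neg", "pos"), n, replace = TRUE)
    bf <- brute_force_metrics(truth, pred, "pos")
    if (bf$tp + bf$fp == 0 || bf$tp + bf$fn == 0 || bf$tn + bf$fp == 0 ||
        2 * bf$tp + bf$fp + bf$fn == 0) next
    cm <- confusion_matrix(factor(truth, c("neg", "pos")),
                           factor(pred, c("neg", "pos")), positive = "pos")
    expect_equal(metric_precision(cm), bf$precision, tolerance = 1e-12)
    expect_equal(metric_recall(cm), bf$recall, tolerance = 1e-12)
    expect_equal(metric_accuracy(cm), bf$accuracy, tolerance = 1e-12)
    expect_equal(metric_specificity(cm), bf$specificity, tolerance = 1e-12)
    expect_equal(metric_f1(cm), bf$f1, tolerance = 1e-12)
    expect_equal(metric_fbeta(cm), bf$fbeta2, tolerance = 1e-12)
  }
})

test_that("weighted kappa matches the hand-worked example and edge cases", {
  cm <- as_confusion_matrix(matrix(c(40, 10, 20, 30), 2, 2, byrow = TRUE))
  expect_equal(weighted_kappa(cm), 0.4, tolerance = 1e-12)
  # perfect diagonal
  expect_equal(weighted_kappa(as_confusion_matrix(diag(c(30, 20)))), 1)
  # identical rows: prediction independent of truth -> kappa 0
  ind <- as_confusion_matrix(matrix(c(30, 10, 30, 10), 2, 2, byrow = TRUE))
  expect_equal(weighted_kappa(ind), 0)
  # binary relabeling invariance
  swapped <- as_confusion_matrix(matrix(c(30, 20, 10, 40), 2, 2, byrow = TRUE))
  expect_equal(weighted_kappa(swapped), 0.4, tolerance = 1e-12)
  # degenerate margins
  degen <- as_confusion_matrix(matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_error(weighted_kappa(degen), "Pe = 1")
})

test_that("binary weighted kappa equals plain Cohen's kappa (e1071 cross-check)", {
  skip_if_not_installed("e1071")
  set.seed(44)
  for (rep in 1:25) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    expect_equal(weighted_kappa(as_confusion_matrix(m)),
                 e1071::classAgreement(m)$kappa, tolerance = 1e-10)
  }
})

test_that("linear-weighted kappa on k > 2 matrices follows the weight formula", {
  set.seed(45)
  m <- matrix(sample(0:20, 9, replace = TRUE), 3, 3)
  m[1, 1] <- m[1, 1] + 5
  cm <- as_confusion_matrix(m)
  w <- 1 - abs(outer(1:3, 1:3, "-")) / 2
  po <- sum(w * m) / sum(m)
  pe <- sum(w * outer(rowSums(m), colSums(m))) / sum(m)^2
  expect_equal(weighted_kappa(cm), (po - pe) / (1 - pe), tolerance = 1e-12)
})

test_that("AUC matches pairwise brute force, pROC, and edge conventions", {
  expect_equal(metric_auc(c(0.8, 0.6, 0.7, 0.1),
                          c("pos", "pos", "neg", "neg"), positive = "pos"),
               0.75)
  expect_equal(metric_auc(c(0.9, 0.8, 0.2, 0.1),
                          c("pos", "pos", "neg", "neg"), positive = "pos"), 1)
  expect_error(metric_auc(c(0.4, 0.6), c("pos", "pos"), positive = "pos"),
               "both classes")
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    labels <- c("neg", "pos", sample(c("neg", "pos"), n - 2, replace = TRUE))
    scores <- round(runif(n), 1)   # coarse scores force ties
    expect_equal(metric_auc(scores, labels, positive = "pos"),
                 brute_force_auc(scores, labels, "pos"), tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal ROC area computed by pROC", {
  skip_if_not_installed("pROC")
  set.seed(56)
  labels <- sample(c("neg", "pos"), 200, replace = TRUE)
  scores <- runif(200) + 0.5 * (labels == "pos")
  independent <- as.numeric(pROC::auc(pROC::roc(
    labels, scores, levels = c("neg", "pos"), direction = "<", quiet = TRUE)))
  expect_equal(metric_auc(scores, labels, positive = "pos"), independent,
               tolerance = 1e-10)
})

test_that("Jaccard index is intersection over union", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_error(jaccard_index(character(0), character(0)), "empty")
})

test_that("random labels give chance-level kappa and AUC on average", {
  set.seed(66)
  ks <- replicate(200, {
    truth <- sample(c("a", "b"), 60, replace = TRUE)
    pred <- sample(c("a", "b"), 60, replace = TRUE)
    weighted_kappa(confusion_matrix(truth, pred))
  })
  expect_lt(abs(mean(ks)), 0.05)
  aucs <- replicate(200, {
    labels <- rep(c("neg", "pos"), each = 30)
    metric_auc(runif(60), labels, positive = "pos")
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("metric_report assembles all indexes consistently", {
  set.seed(77)
  truth <- factor(sample(c("normal", "leukemic"), 80, replace = TRUE),
                  levels = c("normal", "leukemic"))
  pred <- factor(ifelse(runif(80) < 0.8, as.character(truth),
                        sample(c("normal", "leukemic"), 80, replace = TRUE)),
                 levels = c("normal", "leukemic"))
  scores <- runif(80) + (truth == "leukemic")
  rep1 <- metric_report(truth, pred, scores)
  cm <- confusion_matrix(truth, pred)
  expect_equal(rep1$precision, metric_precision(cm))
  expect_equal(rep1$kappa, weighted_kappa(cm))
  expect_equal(rep1$auc, metric_auc(scores, truth, positive = "leukemic"))
  expect_true(all(c("recall", "specificity", "f1", "f_beta") %in% names(rep1)))
})
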