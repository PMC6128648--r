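# Classification boundaries, metric formulas (checked against exhaustive
# enumeration), ROC/AUC (checked against concordant-pair counting), the
# cross-validation protocol and the bootstrap comparator.

test_that("dTm stability classes follow the 1-degree boundaries", {
  expect_equal(classify_stability(2.5), "stabilizing")
  expect_equal(classify_stability(2.5, "three_class"), "stabilizing")
  ## 0 is destabilizing two-class but neutral three-class
  expect_equal(classify_stability(0), "destabilizing")
  expect_equal(classify_stability(0, "three_class"), "neutral")
  ## the boundary itself: dTm = 1 is NOT stabilizing
  expect_equal(classify_stability(1), "destabilizing")
  expect_equal(classify_stability(1, "three_class"), "neutral")
  expect_equal(classify_stability(-1, "three_class"), "neutral")
  expect_equal(classify_stability(-1.01, "three_class"), "destabilizing")
})

test_that("ddG classes follow the -1 kcal/mol boundary", {
  expect_equal(classify_ddg(-2), "stabilizing")
  expect_equal(classify_ddg(-1), "destabilizing")
  expect_equal(classify_ddg(0), "destabilizing")
})

test_that("perfect prediction yields perfect metrics", {
  v <- c(-3, 0, 2, 5)
  m <- compute_metrics(v, v)
  expect_equal(unname(m[c("MAE", "r2", "rho2", "Q", "MCC", "AUC")]),
               c(0, 1, 1, 1, 1, 1))
})

test_that("accuracy and FPR match direct substitution on small counts", {
  ## TP=1, TN=2, FP=1, FN=0
  pred <- c(5, 5, -5, -5)
  obs <- c(5, -5, -5, -5)
  cm <- confusion_matrix(classify_stability(pred), classify_stability(obs))
  expect_equal(cm, list(TP = 1L, TN = 2L, FP = 1L, FN = 0L))
  met <- confusion_metrics(cm)
  expect_equal(unname(met["Q"]), 0.75)
  expect_equal(unname(met["FPR"]), 1 / 3)
  expect_equal(unname(met["TPR"]), 1)
})

test_that("Q and FPR equal their formulas for every confusion matrix up to n = 6", {
  for (n in 1:6) {
    parts <- expand.grid(TP = 0:n, TN = 0:n, FP = 0:n, FN = 0:n)
    parts <- parts[rowSums(parts) == n, ]
    for (r in seq_len(nrow(parts))) {
      cm <- as.list(parts[r, ])
      ## reconstruct label vectors and recompute via the package
      pred <- c(rep("stabilizing", cm$TP), rep("destabilizing", cm$TN),
                rep("stabilizing", cm$FP), rep("destabilizing", cm$FN))
      obs <- c(rep("stabilizing", cm$TP), rep("destabilizing", cm$TN),
               rep("destabilizing", cm$FP), rep("stabilizing", cm$FN))
      cm2 <- confusion_matrix(pred, obs)
      expect_equal(cm2[c("TP", "TN", "FP", "FN")],
                   lapply(cm[c("TP", "TN", "FP", "FN")], as.integer))
      met <- confusion_metrics(cm2)
      expect_equal(unname(met["Q"]), (cm$TP + cm$TN) / n)
      if (cm$FP + cm$TN > 0) {
        expect_equal(unname(met["FPR"]), cm$FP / (cm$FP + cm$TN))
      }
      if (cm$TP + cm$FN > 0) {
        expect_equal(unname(met["TPR"]), cm$TP / (cm$TP + cm$FN))
      }
    }
  }
})

test_that("AUC equals the concordant-pair count on small sets, ties included", {
  auc_pairs <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    conc <- 0
    for (p in pos) for (q in neg) {
      conc <- conc + (p > q) + 0.5 * (p == q)
    }
    conc / (length(pos) * length(neg))
  }
  set.seed(5)
  for (k in 1:5) {
    scores <- round(rnorm(20), 1)   # rounding forces some ties
    labels <- rnorm(20) + scores > 0
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc, auc_pairs(scores, labels))
  }
  ## perfectly separating scores
  expect_equal(roc_curve(c(1, 2, 3, 11, 12), c(F, F, F, T, T))$auc, 1)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(8)
  scores <- c(rnorm(60), round(rnorm(40), 1))   # include ties
  labels <- scores + rnorm(100) > 0.2
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  scores <- rnorm(100)
  labels <- scores + rnorm(100) > 0
  a <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, a)
  expect_equal(roc_curve(atan(scores) * 100 + 7, labels)$auc, a)
})

test_that("shuffled labels give AUC ~ 0.5 and MCC ~ 0 at n = 2000", {
  set.seed(7)
  obs <- rnorm(2000, mean = 0, sd = 3)
  pred <- sample(obs)   # predictions independent of observations
  m <- compute_metrics(pred, obs)
  expect_lt(abs(m[["AUC"]] - 0.5), 0.03)
  expect_lt(abs(m[["MCC"]]), 0.05)
})

test_that("constant vectors and one-class AUC degrade with warnings", {
  expect_warning(m <- compute_metrics(rep(1, 5), c(1, 2, 3, 4, 5)), "constant")
  expect_true(is.na(m[["r2"]]))
  expect_warning(m2 <- compute_metrics(c(1, 2, 3), c(2, 3, 4) + 10), "single")
  expect_true(is.na(m2[["AUC"]]))
})

test_that("cross-validation partitions every mutant once per round", {
  dm <- signal_dm()
  cv <- cross_validate(dm, forest_params(seed = 1), rounds = 2, folds = 5,
                       seed = 9)
  expect_false(anyNA(cv$predictions))
  for (r in 1:2) {
    expect_equal(sort(unique(cv$folds[, r])), 1:5)
    expect_true(all(table(cv$folds[, r]) == 80))
  }
  ## different seeds give different partitions; same seed reproduces
  cv2 <- cross_validate(dm, forest_params(seed = 1), rounds = 2, folds = 5,
                        seed = 9)
  expect_identical(cv$predictions, cv2$predictions)
  cv3 <- cross_validate(dm, forest_params(seed = 1), rounds = 2, folds = 5,
                        seed = 10)
  expect_false(identical(cv$folds[, 1], cv3$folds[, 1]))
})

test_that("CV r2 lands within 0.1 of the generator's attainable ceiling", {
  dm <- signal_dm()
  cv <- cross_validate(dm, forest_params(seed = 1), rounds = 3, folds = 5,
                       seed = 13)
  expect_lt(abs(mean(cv$metrics[, "r2"]) - attr(dm, "attainable_r2")), 0.1)
})

test_that("bootstrap comparison is symmetric, dominant and matches enumeration", {
  a <- c(0.5, 0.52, 0.48, 0.51, 0.49, 0.5, 0.53, 0.47, 0.5, 0.51)
  r <- bootstrap_compare(a, a, trials = 2000, seed = 3)
  expect_lt(abs(r$probability - 0.5), 0.05)
  expect_false(r$significant)

  r2 <- bootstrap_compare(a + 10, a, trials = 500, seed = 3)
  expect_equal(r2$probability, 1)
  expect_true(r2$significant)

  ## exhaustive oracle on 3-value vectors: all 3^3 x 3^3 resample pairs
  a3 <- c(1, 2, 4); b3 <- c(2, 3, 3)
  idx <- expand.grid(1:3, 1:3, 1:3)
  ma <- rowMeans(matrix(a3[as.matrix(idx)], ncol = 3))
  mb <- rowMeans(matrix(b3[as.matrix(idx)], ncol = 3))
  grid <- expand.grid(ia = seq_along(ma), ib = seq_along(mb))
  exact <- mean((ma[grid$ia] > mb[grid$ib]) + 0.5 * (ma[grid$ia] == mb[grid$ib]))
  est <- bootstrap_compare(a3, b3, trials = 4000, seed = 5)$probability
  expect_lt(abs(est - exact), 0.03)

  ## complementarity under the tie convention
  p_ab <- bootstrap_compare(a3, b3, trials = 4000, seed = 11)$probability
  p_ba <- bootstrap_compare(b3, a3, trials = 4000, seed = 12)$probability
  expect_lt(abs(p_ab + p_ba - 1), 0.04)

  ## lower-is-better metrics flip the direction
  p_mae <- bootstrap_compare(a3, b3, trials = 1000, higher_is_better = FALSE,
                             seed = 6)$probability
  expect_lt(abs(p_mae - (1 - exact)), 0.05)
})
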