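## Stability classification, performance metrics, the repeated
## cross-validation protocol and bootstrap model comparison.

#' Classify a dTm value as stabilizing/destabilizing (or three-class)
#'
#' Two-class: stabilizing iff dTm > 1 degree C, destabilizing otherwise
#' (dTm <= 1).  Three-class: stabilizing (dTm > 1), destabilizing
#' (dTm < -1), neutral (-1 <= dTm <= 1).
#'
#' @param dTm numeric vector of melting-temperature changes (degrees C).
#' @param scheme `"two_class"` or `"three_class"`.
#' @return character vector of class labels.
#' @export
classify_stability <- function(dTm, scheme = c("two_class", "three_class")) {
  scheme <- match.arg(scheme)
  stopifnot(all(is.finite(dTm)))
  if (scheme == "two_class") {
    ifelse(dTm > 1, "stabilizing", "destabilizing")
  } else {
    ifelse(dTm > 1, "stabilizing",
           ifelse(dTm < -1, "destabilizing", "neutral"))
  }
}

#' Classify a calculated ddG value
#'
#' Stabilizing iff ddG < -1 kcal/mol, destabilizing otherwise
#' (ddG >= -1); negative ddG of unfolding is stabilizing under the sign
#' convention used throughout.
#'
#' @param ddG numeric vector (kcal/mol).
#' @return character vector of class labels.
#' @export
classify_ddg <- function(ddG) {
  stopifnot(all(is.finite(ddG)))
  ifelse(ddG < -1, "stabilizing", "destabilizing")
}

#' Confusion matrix for two-class stability labels
#'
#' @param predicted,observed character vectors of `"stabilizing"` /
#'   `"destabilizing"` labels; `"stabilizing"` is the positive class.
#' @return list with counts TP, TN, FP, FN.
#' @export
confusion_matrix <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  p <- predicted == "stabilizing"
  o <- observed == "stabilizing"
  list(TP = sum(p & o), TN = sum(!p & !o),
       FP = sum(p & !o), FN = sum(!p & o))
}

#' Classification metrics from a confusion matrix
#'
#' Q = (TP+TN)/(TP+TN+FP+FN); TPR = TP/(TP+FN); FPR = FP/(FP+TN);
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as
#' 0 when any marginal is empty.
#'
#' @param cm a [confusion_matrix()] list.
#' @return named numeric vector with Q, TPR, FPR, MCC.
#' @export
confusion_metrics <- function(cm) {
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  q <- (cm$TP + cm$TN) / n
  tpr <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_
  fpr <- if (cm$FP + cm$TN > 0) cm$FP / (cm$FP + cm$TN) else NA_real_
  denom <- prod(as.numeric(c(cm$TP + cm$FP, cm$TP + cm$FN,
                             cm$TN + cm$FP, cm$TN + cm$FN)))
  mcc <- if (denom > 0) {
    (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(denom)
  } else 0
  c(Q = q, TPR = tpr, FPR = fpr, MCC = mcc)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (predict positive when
#' score > threshold); AUC by trapezoidal integration, which handles tied
#' scores by rank-averaging and therefore equals the Mann-Whitney
#' concordance probability.
#'
#' @param scores numeric ranking scores (higher = more likely positive).
#' @param labels logical (or coercible) vector, TRUE = positive class.
#' @return list with `points` (data frame of FPR/TPR, one row per
#'   threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("roc_curve needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), FPR = c(0, fpr), TPR = c(0, tpr))
  auc <- sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) +
                                utils::tail(pts$TPR, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Regression and classification metrics for predicted vs observed dTm
#'
#' MAE = mean(|predicted - observed|); r2 and rho2 are the squared
#' Pearson and Spearman correlations; the two-class confusion matrix of
#' the 1-degree threshold gives Q, TPR, FPR and MCC; AUC uses the
#' predicted dTm directly as the ranking score against the observed
#' two-class labels.
#'
#' @param predicted,observed numeric dTm vectors of equal length >= 2.
#' @return named numeric vector: MAE, r2, rho2, Q, TPR, FPR, MCC, AUC.
#'   Correlations are `NA` (with a warning) when either vector is
#'   constant; AUC is `NA` (with a warning) when only one observed class
#'   is present.
#' @export
compute_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  mae <- mean(abs(predicted - observed))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant vector: correlation metrics undefined")
    r2 <- rho2 <- NA_real_
  } else {
    r2 <- stats::cor(predicted, observed)^2
    rho2 <- stats::cor(predicted, observed, method = "spearman")^2
  }
  cm <- confusion_matrix(classify_stability(predicted),
                         classify_stability(observed))
  cls <- confusion_metrics(cm)
  obs_pos <- observed > 1
  auc <- if (length(unique(obs_pos)) < 2) {
    warning("single observed class: AUC undefined")
    NA_real_
  } else {
    roc_curve(predicted, obs_pos)$auc
  }
  c(MAE = mae, r2 = r2, rho2 = rho2, cls, AUC = auc)
}

## ---- cross-validation -----------------------------------------------------

#' Repeated k-fold cross-validation of the forest model
#'
#' For each round the mutants are randomly partitioned into `folds` folds
#' (an 80/20 train/test split at the default 5); a forest is trained on
#' the training folds and the held-out fold is predicted, so every mutant
#' is held out exactly once per round.  Round metrics are computed on the
#' pooled held-out predictions of that round, giving one value of each
#' metric per round.
#'
#' @param X a `descriptor_matrix`.
#' @param params [forest_params()].
#' @param rounds,folds protocol size (defaults 10 and 5).
#' @param seed integer; round r derives its partition and model seeds
#'   from `seed + r`.
#' @return a `cv_result`: list with `metrics` (rounds x metric matrix),
#'   `predictions` (n x rounds held-out predictions), `folds` (n x rounds
#'   fold assignments), `observed`, `seed`.
#' @export
cross_validate <- function(X, params = forest_params(), rounds = 10,
                           folds = 5, seed = 1L) {
  stopifnot(inherits(X, "descriptor_matrix"))
  n <- nrow(X$x)
  if (n < folds * params$min_node_size) {
    stop("too few rows (", n, ") for ", folds, "-fold cross-validation")
  }
  pred <- matrix(NA_real_, n, rounds)
  fold_id <- matrix(NA_integer_, n, rounds)
  met <- NULL
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    f <- sample(rep_len(seq_len(folds), n))
    fold_id[, r] <- f
    for (k in seq_len(folds)) {
      train_idx <- which(f != k)
      test_idx <- which(f == k)
      p <- params
      p$seed <- as.integer(seed + 1000L * r + k)
      m <- train_forest(subset_descriptor_matrix(X, train_idx), p)
      pred[test_idx, r] <- predict_forest(m, X$x[test_idx, , drop = FALSE])$mean
    }
    met <- rbind(met, compute_metrics(pred[, r], X$response))
  }
  rownames(met) <- paste0("round", seq_len(rounds))
  structure(list(metrics = met, predictions = pred, folds = fold_id,
                 observed = X$response, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d rounds x %d-fold, n = %d\n",
              nrow(x$metrics), max(x$folds[, 1]), length(x$observed)))
  print(round(colMeans(x$metrics), 3))
  invisible(x)
}

#' Bootstrap comparison of two models' per-round metrics
#'
#' Each trial independently resamples each model's per-round metric values
#' with replacement (as many draws as values) and averages them; the
#' returned probability is the fraction of trials in which model A's
#' average is better than model B's, counting exact ties as 1/2.  A is
#' conventionally called significantly better when the probability
#' exceeds 0.95.
#'
#' @param metrics_a,metrics_b equal-length numeric vectors (one value per
#'   cross-validation round).
#' @param trials number of bootstrap trials (default 1000).
#' @param higher_is_better TRUE for metrics like r2/Q/AUC, FALSE for MAE.
#' @param seed integer seed.
#' @return list with `probability`, `significant` (probability > 0.95)
#'   and `trials`.
#' @export
bootstrap_compare <- function(metrics_a, metrics_b, trials = 1000,
                              higher_is_better = TRUE, seed = 1L) {
  stopifnot(length(metrics_a) == length(metrics_b))
  n <- length(metrics_a)
  set.seed(seed)
  wins <- 0
  for (t in seq_len(trials)) {
    ma <- mean(sample(metrics_a, n, replace = TRUE))
    mb <- mean(sample(metrics_b, n, replace = TRUE))
    if (ma == mb) {
      wins <- wins + 0.5
    } else if ((ma > mb) == higher_is_better) {
      wins <- wins + 1
    }
  }
  p <- wins / trials
  list(probability = p, significant = p > 0.95, trials = trials)
}
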