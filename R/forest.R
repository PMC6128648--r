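## Random-forest regression of dTm on descriptor blocks.
##
## The ensemble is the classic bagged-tree regression forest (CRAN
## randomForest) with the settings used throughout this package: 100
## trees, unlimited depth, a third of the descriptors tried at each split
## and at least five samples per node.  Splits minimise node variance, the
## regression criterion.  The wrapper pins the descriptor column set,
## seeds every stochastic step, and exposes per-tree predictions (needed
## by the applicability-domain criterion) and out-of-bag permutation
## importance (needed by the y-scramble significance screen).

#' Forest hyper-parameters
#'
#' @param n_trees number of trees (default 100).
#' @param mtry_fraction fraction of descriptors tried at each split
#'   (default 1/3; the actual count is `ceiling(p * mtry_fraction)`).
#' @param min_node_size minimum number of samples in a terminal node
#'   (default 5).
#' @param seed integer seed controlling bootstrap and split sampling.
#' @return a `forest_params` list.
#' @export
forest_params <- function(n_trees = 100, mtry_fraction = 1 / 3,
                          min_node_size = 5, seed = 1L) {
  stopifnot(n_trees >= 1, mtry_fraction > 0, mtry_fraction <= 1,
            min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry_fraction = mtry_fraction,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Train a random-forest dTm model
#'
#' @param X a `descriptor_matrix` (or plain numeric matrix with
#'   `response` supplied).
#' @param params a [forest_params()] object.
#' @param response response vector, only when `X` is a plain matrix.
#' @return a `forest_model`.
#' @export
train_forest <- function(X, params = forest_params(), response = NULL) {
  xy <- as_xy(X, response)
  x <- xy$x; y <- xy$y
  if (nrow(x) < 2 * params$min_node_size) {
    stop("need at least ", 2 * params$min_node_size, " rows to train")
  }
  mtry <- max(1, ceiling(ncol(x) * params$mtry_fraction))
  set.seed(params$seed)
  rf <- randomForest::randomForest(
    x = x, y = y,
    ntree = params$n_trees,
    mtry = mtry,
    nodesize = params$min_node_size,
    importance = TRUE,
    keep.inbag = TRUE
  )
  structure(list(rf = rf, columns = colnames(x), params = params,
                 y_range = range(y)),
            class = "forest_model")
}

as_xy <- function(X, response = NULL) {
  if (inherits(X, "descriptor_matrix")) {
    list(x = X$x, y = X$response)
  } else {
    if (is.null(response)) stop("response required with a plain matrix")
    list(x = as.matrix(X), y = response)
  }
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, %d descriptors, mtry %d\n",
              x$rf$ntree, length(x$columns), x$rf$mtry))
  invisible(x)
}

#' Predict with a forest model
#'
#' @param model a `forest_model`.
#' @param X query `descriptor_matrix` or numeric matrix whose columns
#'   match the training descriptors.
#' @return list with `mean` (ensemble prediction, the average of the
#'   per-tree predictions) and `per_tree` (n x n_trees matrix).
#' @export
predict_forest <- function(model, X) {
  x <- if (inherits(X, "descriptor_matrix")) X$x else as.matrix(X)
  missing <- setdiff(model$columns, colnames(x))
  extra <- setdiff(colnames(x), model$columns)
  if (length(missing) || length(extra)) {
    stop("query columns do not match training columns; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  x <- x[, model$columns, drop = FALSE]
  pr <- stats::predict(model$rf, newdata = x, predict.all = TRUE)
  list(mean = unname(pr$aggregate), per_tree = unname(pr$individual))
}

#' Out-of-bag permutation importance
#'
#' Importance of a descriptor is the mean increase in out-of-bag squared
#' prediction error when that descriptor's values are permuted (i.e.
#' randomly reassigned to the wrong mutant), averaged over trees.
#'
#' @param model a `forest_model`.
#' @return named numeric vector, one value per descriptor.
#' @export
forest_importance <- function(model) {
  imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  stats::setNames(as.numeric(imp), model$columns)
}

#' y-scramble significance threshold for descriptor importance
#'
#' Descriptors can show non-zero permutation importance by chance.  The
#' screen trains `n_null` forests on copies of the data whose responses
#' are randomly reassigned to the wrong rows (destroying any real
#' structure-property relationship) and records the maximum importance
#' observed across all null models.  Only descriptors whose importance in
#' the real model exceeds this maximum are deemed significant.
#'
#' @param X a `descriptor_matrix` (or matrix + `response`).
#' @param params [forest_params()] for both real and null models.
#' @param n_null number of y-scrambled null models (default 10).
#' @param seed seed for the scrambles (null model k uses `seed + k`).
#' @param response response vector when `X` is a plain matrix.
#' @return list with `threshold` (maximum importance seen in any null
#'   model, floored at zero), `importance` (real-model importances),
#'   `significant` (names of descriptors above the threshold) and
#'   `null_max` (per-null-model maxima).
#' @export
importance_threshold <- function(X, params = forest_params(), n_null = 10,
                                 seed = params$seed, response = NULL) {
  stopifnot(n_null >= 1)
  xy <- as_xy(X, response)
  real <- train_forest(xy$x, params, response = xy$y)
  imp <- forest_importance(real)
  null_max <- vapply(seq_len(n_null), function(k) {
    set.seed(seed + k)
    y_s <- sample(xy$y)
    p <- params; p$seed <- params$seed + 1000L + k
    m <- train_forest(xy$x, p, response = y_s)
    max(forest_importance(m))
  }, numeric(1))
  thr <- max(0, null_max)   # a negative chance level would never screen
  list(threshold = thr,
       importance = imp,
       significant = names(imp)[imp > thr],
       null_max = null_max)
}
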