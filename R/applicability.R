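## Applicability domain by ensemble-prediction variance: a query is inside
## the domain of the model when the variance of the per-tree predictions
## for that query is smaller than a reference variance derived from the
## cross-validated models.

#' Per-query variance of the tree-ensemble predictions
#'
#' Population variance (divisor n) of the per-tree predictions for each
#' query row.
#'
#' @param model a `forest_model`.
#' @param X query matrix or `descriptor_matrix`.
#' @return numeric vector of variances (degrees C squared).
#' @export
ensemble_variance <- function(model, X) {
  pt <- predict_forest(model, X)$per_tree
  if (ncol(pt) < 2) {
    warning("single-tree model: ensemble variance is identically 0")
  }
  rowMeans(pt^2) - rowMeans(pt)^2
}

#' Cross-validation reference variance
#'
#' Two readings of "the variance of the cross-validated models" are
#' offered:
#' * `"residual"` (default): the population variance of the held-out
#'   prediction errors pooled over all rounds.  This is the scale of the
#'   cross-validated models' own uncertainty; tree-ensemble variances sit
#'   on the same scale, so the criterion discriminates (queries near the
#'   training distribution fall below it, shifted queries above).
#' * `"per_mutant"`: for every training mutant, the population variance
#'   of its held-out predictions across rounds, aggregated by `aggregate`
#'   (mean or median).  Because round-to-round spread of forest *means*
#'   is suppressed by averaging over trees, this reference is typically
#'   one to two orders of magnitude below any query's tree-ensemble
#'   variance and flags essentially everything as out of domain; it is
#'   kept for diagnostic use.
#'
#' @param cv a `cv_result` with at least 2 rounds.
#' @param method `"residual"` (default) or `"per_mutant"`.
#' @param aggregate `"mean"` (default) or `"median"`; only used by
#'   `"per_mutant"`.
#' @return scalar reference variance (degrees C squared).
#' @export
cv_reference_variance <- function(cv, method = c("residual", "per_mutant"),
                                  aggregate = c("mean", "median")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cv, "cv_result"))
  p <- cv$predictions
  if (ncol(p) < 2) stop("reference variance needs >= 2 cross-validation rounds")
  if (method == "residual") {
    err <- as.vector(p) - rep(cv$observed, times = ncol(p))
    mean(err^2) - mean(err)^2
  } else {
    per_mutant <- rowMeans(p^2) - rowMeans(p)^2
    if (aggregate == "mean") mean(per_mutant) else stats::median(per_mutant)
  }
}

#' Applicability-domain assessment of query mutants
#'
#' A query is in the applicability domain when its ensemble-prediction
#' variance is less than the reference variance of the cross-validated
#' models; predictions outside the domain are deemed unreliable.
#'
#' @param model a `forest_model`.
#' @param X query matrix or `descriptor_matrix`.
#' @param reference reference variance, from [cv_reference_variance()].
#' @return an `ad_report`: data frame with `variance` and `in_domain`
#'   per query, attributes `reference` and `fraction_out_of_domain`
#'   (percent).
#' @export
ad_assess <- function(model, X, reference) {
  stopifnot(is.finite(reference), reference >= 0)
  v <- ensemble_variance(model, X)
  in_dom <- v < reference
  out <- data.frame(variance = v, in_domain = in_dom)
  structure(out, class = c("ad_report", "data.frame"),
            reference = reference,
            fraction_out_of_domain = 100 * mean(!in_dom))
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf(
    "<ad_report> %d queries, reference %.3f, %.1f%% out of domain\n",
    nrow(x), attr(x, "reference"), attr(x, "fraction_out_of_domain")))
  invisible(x)
}
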