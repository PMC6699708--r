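# R interface to the compiled random forest regression learner.

#' Fit a random forest regression
#'
#' Bagged CART regression trees: each tree is grown on a bootstrap sample,
#' each split considers `mtry` randomly drawn candidate features, terminal
#' nodes hold at most `nodesize` samples and predict their mean. All
#' randomness flows through R's RNG, so a given `seed` makes the fit
#' bit-reproducible.
#'
#' @param X numeric matrix or data.frame of predictors (n x p).
#' @param y numeric response of length n.
#' @param ntree number of trees (default 300).
#' @param mtry candidate features per split; default floor(p/3), at least 1.
#' @param nodesize terminal node size (default 5, the usual regression
#'   setting).
#' @param seed optional integer seed applied locally.
#' @return an object of class `melon_rf`.
#' @export
rf_fit <- function(X, y, ntree = 300, mtry = NULL, nodesize = 5, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X and y sizes differ")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stopf("non-finite values in training data")
  p <- ncol(X)
  mtry <- mtry %||% max(1L, floor(p / 3))
  if (mtry > p) stopf("mtry (%d) exceeds number of predictors (%d)", mtry, p)
  build <- function() cpp_rf_build(X, y, as.integer(ntree), as.integer(mtry),
                                   as.integer(nodesize))
  trees <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(trees = trees, ntree = ntree, mtry = mtry,
                 nodesize = nodesize, feature_names = colnames(X),
                 X = X, y = y, y_range = range(y)),
            class = "melon_rf")
}

#' @export
predict.melon_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  if (ncol(newdata) != ncol(object$X)) stopf("newdata has wrong column count")
  cpp_rf_predict(object$trees, newdata)
}

#' Out-of-bag predictions of a fitted forest
#'
#' @param fit a [rf_fit()] object.
#' @return numeric vector aligned with the training rows (NA for rows that
#'   were never out of bag).
#' @export
rf_oob_predict <- function(fit) {
  stopifnot(inherits(fit, "melon_rf"))
  cpp_rf_oob_predict(fit$trees, fit$X)
}

#' Permutation importance under the MSE criterion
#'
#' For each tree, the out-of-bag MSE increase when one feature's
#' out-of-bag values are shuffled, averaged over `nrep` shuffles and all
#' trees. Ranks are descending in importance with ties broken by column
#' position (the fixed parameter numbering when X holds the 65 parameters
#' in order).
#'
#' @param fit a [rf_fit()] object.
#' @param nrep permutation repetitions per tree/feature (default 5).
#' @param seed optional integer seed.
#' @return data.frame (feature, importance, rank) sorted by rank; class
#'   `melon_importance`.
#' @export
rf_importance <- function(fit, nrep = 5, seed = NULL) {
  stopifnot(inherits(fit, "melon_rf"))
  run <- function() cpp_rf_importance(fit$trees, fit$X, fit$y,
                                      as.integer(nrep))
  imp <- if (is.null(seed)) run() else with_seed(seed, run())
  nms <- fit$feature_names %||% paste0("x", seq_along(imp))
  ord <- order(-imp, seq_along(imp))
  out <- data.frame(feature = nms, importance = imp,
                    rank = NA_integer_, stringsAsFactors = FALSE)
  out$rank[ord] <- seq_along(imp)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("melon_importance", "data.frame")
  out
}
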