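#' Fit a probability random forest
#'
#' Bagged classification trees with gini splits and per-node feature
#' subsampling; class probability is the in-bag positive fraction of the
#' reached leaf, averaged over trees. This is the stock random-forest
#' recipe (500 trees, `mtry = floor(sqrt(p))`, no tuning): the diagnostic
#' signal lives in the marker features, not in classifier tuning.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y labels: `"malignant"`/`"benign"`, a factor, or 0/1 with 1 the
#'   positive (malignant) class.
#' @param num_trees number of trees.
#' @param mtry features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param min_node minimum terminal-node size (5: slightly smoothed leaf
#'   probabilities, the usual choice for probability forests).
#' @param seed optional integer seed (`NULL` continues the RNG stream).
#' @return object of class `cfmeth_rf`.
#' @export
rf_fit <- function(x, y, num_trees = 500L, mtry = NULL, min_node = 5L,
                   seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y01 <- as_binary_label(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  forest <- .rf_build(x, as.integer(y01), as.integer(num_trees),
                      as.integer(mtry), as.integer(min_node))
  structure(list(forest = forest, features = colnames(x),
                 num_trees = num_trees, mtry = mtry, min_node = min_node),
            class = "cfmeth_rf")
}

#' @rdname rf_fit
#' @param object a fitted `cfmeth_rf`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return `predict()`: numeric vector of malignant probabilities.
#' @export
predict.cfmeth_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  storage.mode(newdata) <- "double"
  as.vector(.rf_predict(object$forest, newdata))
}

# Normalize labels to 0/1 with malignant = 1.
as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("malignant", "benign")))
      stop("labels must be 'malignant'/'benign'", call. = FALSE)
    return(as.integer(y == "malignant"))
  }
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
  as.integer(y)
}
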