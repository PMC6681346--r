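#' Fit a bagged random forest of CART trees
#'
#' Each tree is grown on a bootstrap resample (n draws with replacement) with
#' `mtry` features sampled without replacement as candidates at every split.
#' Predictions are by majority vote with ties resolved to the class that is
#' lower in canonical (sorted) order. The fit is fully reproducible from
#' `seed`. Feature columns are matched by name, so results do not depend on
#' the column order of `X`.
#'
#' @param X Numeric matrix or data frame, samples x features, with column
#'   names.
#' @param y Class labels, one per sample.
#' @param n_trees Number of trees (default 10000; a few hundred already
#'   stabilize votes and importances for p <= 16 features).
#' @param mtry Features sampled per split; default `floor(sqrt(p))`.
#' @param max_depth,min_leaf_size Tree-growing limits as in [cart()].
#' @param bootstrap If `FALSE`, every tree sees the full sample (useful for
#'   degenerate single-tree checks).
#' @param seed Integer seed driving bootstrap and feature sampling.
#' @return An object of class `phenol_forest` with `print`, `predict`,
#'   [feature_importance()] and [representative_tree()] methods.
#' @export
phenol_forest <- function(X, y, n_trees = 10000, mtry = NULL,
                          max_depth = Inf, min_leaf_size = 1,
                          bootstrap = TRUE, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  stopifnot(n == length(y), n_trees >= 1)
  features <- sort(colnames(X))
  X <- X[, features, drop = FALSE]
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  stopifnot(mtry >= 1, mtry <= p)
  classes <- sort(unique(as.character(y)))
  y_int <- match(as.character(y), classes)
  params <- list(max_depth = max_depth, min_leaf_size = min_leaf_size,
                 mtry = mtry)

  set.seed(seed)
  trees <- vector("list", n_trees)
  gains <- matrix(0, nrow = n_trees, ncol = p,
                  dimnames = list(NULL, features))
  for (t in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    root <- .grow_node(X, y_int, idx, 0, params, length(classes), length(idx))
    trees[[t]] <- root
    gains[t, ] <- .node_gains(root, numeric(p))
  }

  structure(
    list(trees = trees, n_trees = n_trees, classes = classes,
         features = features, mtry = mtry, bootstrap = bootstrap,
         seed = seed, params = params, gains = gains, n = n),
    class = "phenol_forest"
  )
}

# votes: samples x classes count matrix from all member trees
.forest_votes <- function(object, X) {
  votes <- matrix(0L, nrow = nrow(X), ncol = length(object$classes))
  for (root in object$trees) {
    pred <- .predict_node(root, X)
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + 1L
  }
  votes
}

#' @export
predict.phenol_forest <- function(object, newdata, ...) {
  X <- .prediction_matrix(newdata, object$features)
  votes <- .forest_votes(object, X)
  # which.max on rows: first (= canonically lowest) class wins ties
  object$classes[max.col(votes, ties.method = "first")]
}

#' @export
print.phenol_forest <- function(x, ...) {
  cat("Random forest of CART trees\n")
  cat(sprintf("  trees = %d, mtry = %d, bootstrap = %s, seed = %d\n",
              x$n_trees, x$mtry, x$bootstrap, x$seed))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  imp <- feature_importance(x)
  cat("  top features:",
      paste(utils::head(imp$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Mean-decrease-in-Gini feature importance
#'
#' For every feature, the Gini impurity decrease of each split using it is
#' weighted by the fraction of the tree's samples reaching that node, summed
#' per tree and averaged over trees; the averages are normalized to sum to 1.
#'
#' @param forest A [phenol_forest()].
#' @return Data frame with `feature` and `importance`, sorted non-increasing;
#'   all training features appear (zero importance if never used).
#' @export
feature_importance <- function(forest) {
  stopifnot(inherits(forest, "phenol_forest"))
  imp <- colMeans(forest$gains)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = forest$features[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Extract the forest's representative tree
#'
#' The member tree whose predictions on `X` agree with the forest's majority
#' vote for the largest fraction of samples; ties resolve to the lowest tree
#' index. The result is a standalone [cart()] object, useful for displaying
#' a single interpretable tree on the ensemble's behalf.
#'
#' @param forest A [phenol_forest()].
#' @param X Samples on which agreement is measured (typically the training
#'   data).
#' @return A `cart` object.
#' @export
representative_tree <- function(forest, X) {
  stopifnot(inherits(forest, "phenol_forest"))
  X <- .prediction_matrix(X, forest$features)
  votes <- .forest_votes(forest, X)
  majority <- max.col(votes, ties.method = "first")
  agreement <- vapply(
    forest$trees,
    function(root) mean(.predict_node(root, X) == majority),
    numeric(1)
  )
  best <- which.max(agreement)  # first max = lowest index
  structure(
    list(root = forest$trees[[best]], classes = forest$classes,
         features = forest$features, params = forest$params,
         n = forest$n, tree_index = best,
         agreement = agreement[best]),
    class = "cart"
  )
}
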