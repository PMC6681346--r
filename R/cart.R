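#' Gini impurity of a class-count vector
#'
#' 1 - sum((n_c / n)^2), the probability that two draws with replacement from
#' the node disagree in class; 0 for a pure node.
#'
#' @param class_counts Non-negative numeric vector of per-class counts with a
#'   positive total.
#' @return Impurity in [0, 1).
#' @export
#' @examples
#' gini_impurity(c(5, 5))   # 0.5
#' gini_impurity(c(10, 0))  # 0
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- sum(class_counts)
  if (n <= 0) stop("total count must be > 0", call. = FALSE)
  1 - sum((class_counts / n)^2)
}

# Scan one feature for the impurity-maximizing threshold.
# v: numeric values; y_int: integer class codes 1..K; returns
# list(threshold, decrease) or NULL. Thresholds are midpoints between
# consecutive distinct sorted values; both children must hold >= min_leaf
# samples. Ties in decrease resolve to the lowest threshold.
.scan_feature <- function(v, y_int, K, min_leaf) {
  n <- length(v)
  ord <- order(v, method = "radix")
  vs <- v[ord]
  ys <- y_int[ord]

  # cumulative class counts after each position
  left <- matrix(0, nrow = n, ncol = K)
  for (k in seq_len(K)) left[, k] <- cumsum(ys == k)
  total <- left[n, ]

  pos <- which(vs[-n] < vs[-1])                 # split after position i
  pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
  if (length(pos) == 0) return(NULL)

  nl <- pos
  nr <- n - pos
  lc <- left[pos, , drop = FALSE]
  rc <- matrix(total, nrow = length(pos), ncol = K, byrow = TRUE) - lc
  gini_l <- 1 - rowSums((lc / nl)^2)
  gini_r <- 1 - rowSums((rc / nr)^2)
  parent <- 1 - sum((total / n)^2)
  decrease <- parent - (nl / n) * gini_l - (nr / n) * gini_r

  best <- which.max(decrease)                   # first max = lowest threshold
  if (decrease[best] <= 1e-15) return(NULL)
  list(threshold = (vs[pos[best]] + vs[pos[best] + 1]) / 2,
       decrease = decrease[best])
}

#' Best single split of a dataset
#'
#' Exhaustive scan over candidate features and all midpoints between
#' consecutive distinct sorted values, maximizing the weighted Gini impurity
#' decrease. Ties are broken by candidate-feature order, then by the lower
#' threshold. Samples with value <= threshold go left.
#'
#' @param X Numeric matrix or data frame, samples x features, with column
#'   names.
#' @param y Class labels (character or factor), one per sample.
#' @param candidates Character vector of feature names to consider
#'   (default: all columns of `X`).
#' @param min_leaf_size Minimum samples required in each child (default 1).
#' @return List with `feature`, `threshold` and `decrease`, or `NULL` when no
#'   split decreases impurity.
#' @export
best_split <- function(X, y, candidates = colnames(X), min_leaf_size = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  classes <- sort(unique(as.character(y)))
  y_int <- match(as.character(y), classes)
  best <- NULL
  for (f in candidates) {
    cand <- .scan_feature(X[, f], y_int, length(classes), min_leaf_size)
    if (!is.null(cand) && (is.null(best) || cand$decrease > best$decrease)) {
      best <- list(feature = f, threshold = cand$threshold,
                   decrease = cand$decrease)
    }
  }
  best
}

# Recursive tree grower on integer-coded labels. Returns a node: either
# list(leaf = TRUE, counts, pred) or
# list(leaf = FALSE, feature, threshold, left, right, gain) where gain is the
# node-fraction-weighted impurity decrease used for Gini importance.
.grow_node <- function(X, y_int, idx, depth, params, K, n_root) {
  counts <- tabulate(y_int[idx], nbins = K)
  make_leaf <- function() {
    list(leaf = TRUE, counts = counts, pred = which.max(counts))
  }
  if (sum(counts > 0) <= 1 || depth >= params$max_depth ||
      length(idx) < 2 * params$min_leaf_size) {
    return(make_leaf())
  }
  p <- ncol(X)
  feats <- seq_len(p)
  if (params$mtry < p) {
    feats <- sort(sample.int(p, params$mtry))
  }
  best <- NULL
  best_f <- NA_integer_
  for (f in feats) {
    cand <- .scan_feature(X[idx, f], y_int[idx], K, params$min_leaf_size)
    if (!is.null(cand) && (is.null(best) || cand$decrease > best$decrease)) {
      best <- cand
      best_f <- f
    }
  }
  if (is.null(best)) return(make_leaf())
  go_left <- X[idx, best_f] <= best$threshold
  list(
    leaf = FALSE,
    feature = best_f,
    threshold = best$threshold,
    gain = best$decrease * length(idx) / n_root,
    left = .grow_node(X, y_int, idx[go_left], depth + 1, params, K, n_root),
    right = .grow_node(X, y_int, idx[!go_left], depth + 1, params, K, n_root)
  )
}

# Sum of importance gains per feature index over a node subtree.
.node_gains <- function(node, acc) {
  if (node$leaf) return(acc)
  acc[node$feature] <- acc[node$feature] + node$gain
  acc <- .node_gains(node$left, acc)
  .node_gains(node$right, acc)
}

# Vectorized routing: integer predictions (class codes) for a matrix whose
# columns are in training-feature order.
.predict_node <- function(node, X) {
  out <- integer(nrow(X))
  route <- function(node, rows) {
    if (length(rows) == 0) return()
    if (node$leaf) {
      out[rows] <<- node$pred
      return()
    }
    go_left <- X[rows, node$feature] <= node$threshold
    route(node$left, rows[go_left])
    route(node$right, rows[!go_left])
  }
  route(node, seq_len(nrow(X)))
  out
}

# Validate prediction input against training features and return a numeric
# matrix with columns in training order.
.prediction_matrix <- function(newdata, features) {
  X <- as.matrix(newdata)
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0) {
    stop("unknown feature(s) in model not present in newdata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X[, features, drop = FALSE]
}

#' Fit a CART classification tree
#'
#' Recursive binary partitioning with the Gini criterion: each node is split
#' at the threshold maximizing the weighted impurity decrease, until nodes
#' are pure, the depth limit is reached, or children would fall below
#' `min_leaf_size`. Values `<= threshold` route left. Feature columns are
#' matched and ordered by name, so fits and predictions are invariant to
#' input column order.
#'
#' @param X Numeric matrix or data frame, samples x features, with column
#'   names.
#' @param y Class labels, one per sample.
#' @param max_depth Maximum tree depth (root = depth 0); default unlimited.
#' @param min_leaf_size Minimum samples per leaf (default 1).
#' @param mtry Number of features sampled (without replacement, using the
#'   current RNG) as split candidates at each node; default all features.
#' @return An object of class `cart` with `print`, `summary` and `predict`
#'   methods.
#' @export
cart <- function(X, y, max_depth = Inf, min_leaf_size = 1, mtry = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty input", call. = FALSE)
  if (is.null(colnames(X))) {
    stop("X must have column names", call. = FALSE)
  }
  stopifnot(nrow(X) == length(y))
  features <- sort(colnames(X))
  X <- X[, features, drop = FALSE]
  classes <- sort(unique(as.character(y)))
  y_int <- match(as.character(y), classes)
  params <- list(
    max_depth = max_depth,
    min_leaf_size = min_leaf_size,
    mtry = if (is.null(mtry)) ncol(X) else mtry
  )
  stopifnot(params$mtry >= 1, params$mtry <= ncol(X))
  root <- .grow_node(X, y_int, seq_len(nrow(X)), 0, params, length(classes),
                     nrow(X))
  structure(
    list(root = root, classes = classes, features = features,
         params = params, n = nrow(X)),
    class = "cart"
  )
}

#' @export
predict.cart <- function(object, newdata, ...) {
  X <- .prediction_matrix(newdata, object$features)
  object$classes[.predict_node(object$root, X)]
}

# depth and node counts for display
.node_stats <- function(node, depth = 0) {
  if (node$leaf) return(c(leaves = 1, depth = depth))
  l <- .node_stats(node$left, depth + 1)
  r <- .node_stats(node$right, depth + 1)
  c(leaves = l[["leaves"]] + r[["leaves"]],
    depth = max(l[["depth"]], r[["depth"]]))
}

#' @export
print.cart <- function(x, ...) {
  s <- .node_stats(x$root)
  cat("CART classification tree\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  n = %d, leaves = %d, depth = %d\n",
              x$n, s[["leaves"]], s[["depth"]]))
  invisible(x)
}

#' @export
summary.cart <- function(object, ...) {
  print(object)
  cat("splits (feature <= threshold goes left):\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf: ", object$classes[node$pred], " (",
          paste(node$counts, collapse = "/"), ")\n", sep = "")
    } else {
      cat(pad, object$features[node$feature], " <= ",
          format(node$threshold, digits = 4), "\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(object$root, 1)
  invisible(object)
}
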