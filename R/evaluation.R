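#' Stratified train/test split
#'
#' Splits sample indices into disjoint, exhaustive train and test sets. The
#' train size is `ceiling(train_fraction * n)`, allocated per class by floor
#' plus largest fractional remainder (ties by class order), so a 2/3 split of
#' a 47-sample binary dataset yields exactly 32 training samples. Stratified
#' splits guarantee at least one training sample per class; a singleton class
#' is placed entirely in training with a warning since it cannot be
#' stratified.
#'
#' @param y Class labels, one per sample.
#' @param train_fraction Fraction of samples for training, in (0, 1).
#' @param seed Integer seed; the split is fully reproducible from it.
#' @param stratified Stratify by class (default `TRUE`).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, train_fraction, seed = 1, stratified = TRUE) {
  y <- as.character(y)
  n <- length(y)
  stopifnot(train_fraction > 0, train_fraction < 1, n >= 2)
  n_train <- ceiling(train_fraction * n)
  if (n_train >= n) stop("test set would be empty", call. = FALSE)
  if (n_train < 1) stop("train set would be empty", call. = FALSE)

  set.seed(seed)
  if (!stratified) {
    train <- sort(sample.int(n, n_train))
    return(list(train = train, test = setdiff(seq_len(n), train)))
  }

  classes <- sort(unique(y))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  singletons <- classes[counts == 1]
  if (length(singletons) > 0) {
    warning("singleton class(es) assigned entirely to training: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }

  # per-class quotas: at least 1 (all of a singleton), floor + largest
  # remainder up to the target train size
  quota <- pmax(1L, as.integer(floor(train_fraction * counts)))
  quota <- pmin(quota, counts)
  quota[classes %in% singletons] <- 1L
  deficit <- n_train - sum(quota)
  if (deficit > 0) {
    room <- counts - quota
    frac <- train_fraction * counts - floor(train_fraction * counts)
    ord <- order(-frac, seq_along(classes))
    for (i in rep(ord, length.out = sum(room))) {
      if (deficit == 0) break
      if (room[i] > 0 && counts[i] > 1) {
        quota[i] <- quota[i] + 1L
        room[i] <- room[i] - 1L
        deficit <- deficit - 1L
      }
    }
  } else if (deficit < 0) {
    # trim from classes with the most training samples, never below 1
    ord <- order(-quota, seq_along(classes))
    for (i in rep(ord, length.out = sum(quota))) {
      if (deficit == 0) break
      if (quota[i] > 1) {
        quota[i] <- quota[i] - 1L
        deficit <- deficit + 1L
      }
    }
  }

  train <- integer(0)
  for (i in seq_along(classes)) {
    members <- which(y == classes[i])
    take <- if (length(members) == 1) members else sample(members, quota[i])
    train <- c(train, take)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Classification accuracy
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Fraction of exact matches in [0, 1].
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    stop("label vectors must have equal positive length", call. = FALSE)
  }
  mean(as.character(truth) == as.character(predicted))
}

#' F1 score for a positive class
#'
#' Harmonic mean of precision and recall for `positive`. When precision +
#' recall is 0 (no true and no predicted positives, or no overlap at all),
#' F1 is 0 by convention and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The positive class (default `"Erica"`).
#' @return F1 in [0, 1].
#' @export
f1_score <- function(truth, predicted, positive = "Erica") {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    stop("label vectors must have equal positive length", call. = FALSE)
  }
  truth <- as.character(truth) == positive
  predicted <- as.character(predicted) == positive
  tp <- sum(truth & predicted)
  fp <- sum(!truth & predicted)
  fn <- sum(truth & !predicted)
  if (tp == 0 && (fp + fn == 0 || (tp + fp == 0 && tp + fn == 0))) {
    return(structure(0, degenerate = TRUE))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (precision + recall == 0) return(structure(0, degenerate = TRUE))
  2 * precision * recall / (precision + recall)
}

#' Classifier factories for the evaluation harness
#'
#' A classifier factory is a `function(X, y, seed)` returning a prediction
#' function `function(newdata) -> labels`. These constructors configure the
#' built-in backends:
#' \describe{
#'   \item{classifier_cart}{a single CART tree ([cart()]).}
#'   \item{classifier_forest}{a bagged CART forest ([phenol_forest()]).}
#'   \item{classifier_svm}{a pluggable external backend wrapping
#'     \code{e1071::svm} (radial kernel); requires the `e1071` package.}
#'   \item{classifier_majority}{predicts the most frequent training class —
#'     a floor baseline.}
#' }
#'
#' @param max_depth,min_leaf_size,n_trees,mtry Passed through to the
#'   respective fitting function.
#' @param ... Passed through to `e1071::svm`.
#' @return A classifier factory function.
#' @name classifier_factories
NULL

#' @rdname classifier_factories
#' @export
classifier_cart <- function(max_depth = Inf, min_leaf_size = 1) {
  function(X, y, seed = 1) {
    model <- cart(X, y, max_depth = max_depth, min_leaf_size = min_leaf_size)
    function(newdata) predict(model, newdata)
  }
}

#' @rdname classifier_factories
#' @export
classifier_forest <- function(n_trees = 200, mtry = NULL, max_depth = Inf,
                              min_leaf_size = 1) {
  function(X, y, seed = 1) {
    model <- phenol_forest(X, y, n_trees = n_trees, mtry = mtry,
                           max_depth = max_depth,
                           min_leaf_size = min_leaf_size, seed = seed)
    function(newdata) predict(model, newdata)
  }
}

#' @rdname classifier_factories
#' @export
classifier_svm <- function(...) {
  args <- list(...)
  function(X, y, seed = 1) {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("the SVM backend needs the 'e1071' package", call. = FALSE)
    }
    set.seed(seed)
    model <- do.call(e1071::svm,
                     c(list(x = as.matrix(X), y = factor(y)), args))
    function(newdata) {
      as.character(predict(model, as.matrix(newdata)))
    }
  }
}

#' @rdname classifier_factories
#' @export
classifier_majority <- function() {
  function(X, y, seed = 1) {
    tab <- sort(table(as.character(y)), decreasing = TRUE)
    winner <- names(tab)[1]
    function(newdata) rep(winner, nrow(as.matrix(newdata)))
  }
}

# deterministic per-cell seed derivation, kept within 32-bit integer range
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647L)
}

#' Replicated algorithm comparison across training fractions
#'
#' For every (training fraction, replicate) cell the data are split once
#' (stratified, seed-derived) and every algorithm is trained and scored on
#' the identical split, giving a paired comparison. Accuracy and F1 for the
#' positive class are recorded per cell and summarized as mean and sd per
#' (algorithm, fraction). A failing algorithm yields an `NA` record carrying
#' the error message rather than aborting the grid.
#'
#' @param X Feature matrix/data frame with column names.
#' @param y Class labels.
#' @param algorithms Named list of classifier factories (see
#'   [classifier_factories]).
#' @param fractions Training fractions (default `c(0.5, 0.6, 2/3, 0.8)`).
#' @param n_replications Replicates per fraction (default 5).
#' @param seed Master seed; cell seeds are derived deterministically.
#' @param positive Positive class for F1 (default `"Erica"`).
#' @return An `eval_report`: list with `records` (one row per algorithm x
#'   fraction x replicate) and `summary` (mean/sd per algorithm x fraction).
#' @export
compare_algorithms <- function(X, y, algorithms,
                               fractions = c(0.5, 0.6, 2 / 3, 0.8),
                               n_replications = 5, seed = 1,
                               positive = "Erica") {
  stopifnot(length(algorithms) >= 1, !is.null(names(algorithms)))
  X <- as.matrix(X)
  y <- as.character(y)
  records <- list()
  cell <- 0L
  for (f_i in seq_along(fractions)) {
    for (rep_i in seq_len(n_replications)) {
      cell <- cell + 1L
      cell_seed <- .derive_seed(seed, cell)
      split <- split_train_test(y, fractions[f_i], seed = cell_seed)
      for (alg in names(algorithms)) {
        rec <- data.frame(
          algorithm = alg, train_fraction = fractions[f_i],
          replicate = rep_i, accuracy = NA_real_, f1 = NA_real_,
          error = NA_character_, stringsAsFactors = FALSE
        )
        res <- tryCatch({
          predictor <- algorithms[[alg]](X[split$train, , drop = FALSE],
                                         y[split$train], seed = cell_seed)
          pred <- predictor(X[split$test, , drop = FALSE])
          list(acc = accuracy(y[split$test], pred),
               f1 = as.numeric(f1_score(y[split$test], pred, positive)))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$error <- conditionMessage(res)
        } else {
          rec$accuracy <- res$acc
          rec$f1 <- res$f1
        }
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)
  agg <- stats::aggregate(
    records[c("accuracy", "f1")],
    by = records[c("algorithm", "train_fraction")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  summary <- data.frame(
    algorithm = agg$algorithm,
    train_fraction = agg$train_fraction,
    mean_accuracy = agg$accuracy[, "mean"],
    sd_accuracy = agg$accuracy[, "sd"],
    mean_f1 = agg$f1[, "mean"],
    sd_f1 = agg$f1[, "sd"],
    stringsAsFactors = FALSE
  )
  structure(list(records = records, summary = summary), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Algorithm comparison (", nrow(x$records), " cells)\n", sep = "")
  s <- x$summary
  s$mean_accuracy <- round(s$mean_accuracy, 3)
  s$sd_accuracy <- round(s$sd_accuracy, 3)
  s$mean_f1 <- round(s$mean_f1, 3)
  s$sd_f1 <- round(s$sd_f1, 3)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Partitions samples into `n_folds` stratified folds (per-class round-robin
#' after a seeded shuffle; fold sizes differ by at most one), trains on k-1
#' folds and scores on the held-out fold, so every sample is tested exactly
#' once.
#'
#' @param X Feature matrix/data frame with column names.
#' @param y Class labels.
#' @param classifier A classifier factory (see [classifier_factories]).
#' @param n_folds Number of folds (default 5; must be in 2..n).
#' @param seed Integer seed.
#' @param positive Positive class for F1 (default `"Erica"`).
#' @return List with `folds` (per-fold accuracy/F1), `mean_accuracy`,
#'   `sd_accuracy`, `mean_f1`, `sd_f1` and the fold `assignments`.
#' @export
cross_validate <- function(X, y, classifier, n_folds = 5, seed = 1,
                           positive = "Erica") {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- length(y)
  if (n_folds > n) stop("n_folds must not exceed n samples", call. = FALSE)
  stopifnot(n_folds >= 2)

  set.seed(seed)
  fold_of <- integer(n)
  offset <- 0L
  for (cl in sort(unique(y))) {
    members <- sample(which(y == cl))
    fold_of[members] <- ((seq_along(members) - 1L + offset) %% n_folds) + 1L
    offset <- offset + length(members)  # balance folds across classes
  }

  folds <- data.frame(fold = seq_len(n_folds), accuracy = NA_real_,
                      f1 = NA_real_)
  for (k in seq_len(n_folds)) {
    test <- which(fold_of == k)
    train <- which(fold_of != k)
    predictor <- classifier(X[train, , drop = FALSE], y[train],
                            seed = .derive_seed(seed, k))
    pred <- predictor(X[test, , drop = FALSE])
    folds$accuracy[k] <- accuracy(y[test], pred)
    folds$f1[k] <- as.numeric(f1_score(y[test], pred, positive))
  }
  list(
    folds = folds,
    mean_accuracy = mean(folds$accuracy),
    sd_accuracy = stats::sd(folds$accuracy),
    mean_f1 = mean(folds$f1),
    sd_f1 = stats::sd(folds$f1),
    assignments = fold_of
  )
}
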