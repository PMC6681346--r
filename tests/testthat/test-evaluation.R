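test_that("the stratified 2/3 split of 47 binary samples has 32 train members", {
  y <- rep(c("Erica", "non-Erica"), c(29, 18))
  s <- split_train_test(y, 2 / 3, seed = 1)
  expect_length(s$train, 32)
  expect_length(s$test, 15)
  # disjoint and exhaustive
  expect_setequal(c(s$train, s$test), seq_along(y))
  expect_length(intersect(s$train, s$test), 0)
  # per-class allocation: floor + largest remainder
  expect_equal(sum(y[s$train] == "Erica"), 20)
  expect_equal(sum(y[s$train] == "non-Erica"), 12)
})

test_that("splits are seed-reproducible and guard their edge cases", {
  y <- rep(c("a", "b"), c(6, 4))
  expect_identical(split_train_test(y, 0.5, seed = 3),
                   split_train_test(y, 0.5, seed = 3))
  expect_false(identical(split_train_test(y, 0.5, seed = 3)$train,
                         split_train_test(y, 0.5, seed = 4)$train))
  expect_error(split_train_test(y, 0.999), "test set")
  y_singleton <- c(rep("big", 8), "solo")
  expect_warning(s <- split_train_test(y_singleton, 0.5), "solo")
  expect_true(which(y_singleton == "solo") %in% s$train)
})

test_that("accuracy and F1 match brute-force confusion-matrix oracles", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy(c("a", "a", "a", "b"), c("a", "a", "b", "b")), 0.75)
  expect_error(accuracy("a", c("a", "b")), "equal")
  # TP=2 FP=1 FN=1 -> precision = recall = 2/3 -> F1 = 2/3
  truth <- c("E", "E", "E", "x", "x")
  pred <- c("E", "E", "x", "E", "x")
  expect_equal(as.numeric(f1_score(truth, pred, positive = "E")), 2 / 3)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    truth <- sample(c("E", "x"), n, replace = TRUE)
    pred <- sample(c("E", "x"), n, replace = TRUE)
    expect_equal(accuracy(truth, pred), oracle_accuracy(truth, pred))
    expect_equal(as.numeric(f1_score(truth, pred, positive = "E")),
                 oracle_f1(truth, pred, "E"))
  }
  # degenerate convention: no true and no predicted positives
  f <- f1_score(c("x", "x"), c("x", "x"), positive = "E")
  expect_equal(as.numeric(f), 0)
  expect_true(attr(f, "degenerate"))
})

test_that("the comparison grid is complete, paired and leak-detectable", {
  pd <- planted_importance_dataset(60, seed = 18)
  # an oracle classifier that memorizes the full label vector (test leak):
  # must score accuracy 1 in every cell, proving the harness wiring
  leak <- function(X, y, seed = 1) {
    known <- cbind(pd$X, label = match(pd$y, sort(unique(pd$y))))
    function(newdata) {
      idx <- match(apply(as.matrix(newdata), 1, paste, collapse = ","),
                   apply(known[, colnames(newdata), drop = FALSE], 1,
                         paste, collapse = ","))
      sort(unique(pd$y))[known[idx, "label"]]
    }
  }
  rep_out <- compare_algorithms(
    pd$X, pd$y,
    algorithms = list(leak = leak, majority = classifier_majority()),
    fractions = c(0.5, 2 / 3), n_replications = 5, seed = 19
  )
  expect_equal(nrow(rep_out$records), 2 * 2 * 5)
  expect_true(all(rep_out$records$accuracy[rep_out$records$algorithm == "leak"] == 1))
  # majority baseline scores the majority fraction of each test cell
  maj <- rep_out$records[rep_out$records$algorithm == "majority", ]
  expect_true(all(maj$accuracy > 0.3 & maj$accuracy < 0.8))
  expect_equal(nrow(rep_out$summary), 2 * 2)
})

test_that("a failing algorithm is recorded, not fatal", {
  pd <- planted_importance_dataset(40, seed = 20)
  boom <- function(X, y, seed = 1) stop("deliberate failure")
  rep_out <- compare_algorithms(
    pd$X, pd$y, algorithms = list(boom = boom, cart = classifier_cart()),
    fractions = 0.5, n_replications = 2, seed = 21
  )
  boom_rows <- rep_out$records[rep_out$records$algorithm == "boom", ]
  expect_true(all(is.na(boom_rows$accuracy)))
  expect_true(all(grepl("deliberate", boom_rows$error)))
  cart_rows <- rep_out$records[rep_out$records$algorithm == "cart", ]
  expect_true(all(!is.na(cart_rows$accuracy)))
})

test_that("cross-validation partitions samples into balanced stratified folds", {
  pd <- planted_importance_dataset(47, seed = 22)
  cv <- cross_validate(pd$X, pd$y, classifier_cart(), n_folds = 5, seed = 23)
  sizes <- table(cv$assignments)
  expect_equal(length(sizes), 5)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(seq_along(pd$y), seq_along(cv$assignments))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
  expect_error(cross_validate(pd$X, pd$y, classifier_cart(), n_folds = 48),
               "exceed")
})

test_that("leave-one-out on trivially separable data is perfect", {
  n <- 16
  X <- cbind(v = c(seq(0, 0.1, length.out = n / 2),
                   seq(5, 5.1, length.out = n / 2)))
  y <- rep(c("lo", "hi"), each = n / 2)
  cv <- cross_validate(X, y, classifier_cart(), n_folds = n, seed = 24,
                       positive = "hi")
  expect_equal(cv$mean_accuracy, 1)
})
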