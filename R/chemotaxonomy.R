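#' Threshold rule for identifying Erica from relative phenol abundances
#'
#' Erica samples are flagged when the relative contribution of coumaryl
#' phenols exceeds 0.20 (strictly) and the relative contribution of benzoic
#' acids lies within the closed interval [0.05, 0.12]. Both component
#' decisions and the underlying fractions are returned so boundary cases can
#' be audited. The rule depends only on fractions, so it is invariant to
#' rescaling all contents of a sample.
#'
#' @param rel Output of [relative_group_abundances()] (needs `coumaryl` and
#'   `benzoic` columns).
#' @param coumaryl_min Strict lower threshold on the coumaryl fraction
#'   (default 0.20).
#' @param benzoic_range Closed interval for the benzoic-acids fraction
#'   (default c(0.05, 0.12)).
#' @return Data frame with `sample_id`, `species`, `coumaryl_value`,
#'   `benzoic_value`, `coumaryl_pass`, `benzoic_pass`, `is_erica`.
#' @export
classify_erica_rule <- function(rel, coumaryl_min = 0.20,
                                benzoic_range = c(0.05, 0.12)) {
  stopifnot(all(c("coumaryl", "benzoic") %in% names(rel)),
            length(benzoic_range) == 2, benzoic_range[1] <= benzoic_range[2])
  coumaryl_pass <- rel$coumaryl > coumaryl_min
  benzoic_pass <- rel$benzoic >= benzoic_range[1] &
    rel$benzoic <= benzoic_range[2]
  data.frame(
    sample_id = rel$sample_id,
    species = rel$species,
    coumaryl_value = rel$coumaryl,
    benzoic_value = rel$benzoic,
    coumaryl_pass = coumaryl_pass,
    benzoic_pass = benzoic_pass,
    is_erica = coumaryl_pass & benzoic_pass,
    stringsAsFactors = FALSE
  )
}

#' Z-score normalization of a feature matrix
#'
#' Standardizes each column to mean 0 and standard deviation 1 (n-1
#' denominator), Z = (X - mean(X)) / sd(X). Constant columns carry no
#' information for distance-based methods; they are mapped to all-zeros with
#' a warning.
#'
#' @param m Numeric matrix or data frame, samples x features.
#' @return Matrix of the same shape.
#' @export
zscore_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 samples to Z-score", call. = FALSE)
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  constant <- sdev == 0
  if (any(constant)) {
    warning("constant column(s) mapped to zeros: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    sdev[constant] <- 1
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdev, "/")
  z[, constant] <- 0
  z
}

#' Ward/Euclidean agglomerative clustering
#'
#' Hierarchical clustering with the Ward minimum-variance criterion on
#' squared Euclidean distances (the classic Ward convention: merge heights
#' are Ward cost increments, computed by the Lance-Williams update inside
#' \code{\link[stats]{hclust}}), cut into `k` groups. The caller is expected
#' to normalize features first (see [zscore_normalize()]).
#'
#' @param m Numeric matrix, samples x features (already normalized).
#' @param k Number of clusters to cut the dendrogram into (<= n samples).
#' @return List with `labels` (integer vector in 1..k), `merge_history`
#'   (data frame of the n-1 merges: `cluster_a`, `cluster_b`, `height`;
#'   negative indices are original samples, positive indices earlier merges,
#'   as in \code{hclust}), and the underlying `hclust` object.
#' @export
ward_cluster <- function(m, k) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  d <- stats::dist(m, method = "euclidean")
  hc <- stats::hclust(d^2, method = "ward.D")
  labels <- stats::cutree(hc, k = k)
  list(
    labels = unname(labels),
    merge_history = data.frame(
      cluster_a = hc$merge[, 1],
      cluster_b = hc$merge[, 2],
      height = hc$height
    ),
    hclust = hc
  )
}

#' Principal component analysis of a phenol feature matrix
#'
#' PCA via singular-value decomposition of the column-centered matrix.
#' Loadings are orthonormal; each component's sign is fixed so that its
#' largest-magnitude loading entry is positive.
#'
#' @param m Numeric matrix, samples x features.
#' @param n_components Number of components to keep
#'   (<= min(nrow - 1, ncol)).
#' @return List with `scores` (samples x n_components), `loadings`
#'   (features x n_components) and `explained_variance` (fractions of total
#'   variance, non-increasing).
#' @export
phenol_pca <- function(m, n_components) {
  m <- as.matrix(m)
  n <- nrow(m)
  p <- ncol(m)
  if (n_components > min(n - 1, p)) {
    stop("n_components must be <= min(n - 1, p)", call. = FALSE)
  }
  centered <- sweep(m, 2, colMeans(m), "-")
  total_var <- sum(centered^2)
  if (total_var == 0) {
    stop("zero variance: all rows identical", call. = FALSE)
  }
  sv <- svd(centered)
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- centered %*% loadings
  # sign convention: largest |loading| entry of each component positive
  for (j in keep) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(m)
  list(
    scores = scores,
    loadings = loadings,
    explained_variance = sv$d[keep]^2 / total_var
  )
}
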