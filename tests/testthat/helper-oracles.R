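# Independent oracles and fixture builders, deliberately written without
# reference to the package internals they check.

# The 17 (compound, group) membership pairs, typed out by hand from the group
# defining equations. Used as a brute-force oracle for group_sums().
membership_pairs <- list(
  c("4-hydroxybenzaldehyde", "p_hydroxy"),
  c("4-hydroxyacetophenone", "p_hydroxy"),
  c("4-hydroxybenzoic acid", "p_hydroxy"),
  c("vanillin", "vanillyl"),
  c("4-hydroxy-3-methoxyacetophenone", "vanillyl"),
  c("vanillic acid", "vanillyl"),
  c("syringaldehyde", "syringyl"),
  c("3,5-dimethoxy-4-hydroxyacetophenone", "syringyl"),
  c("syringic acid", "syringyl"),
  c("p-coumaric acid", "coumaryl"),
  c("ferulic acid", "coumaryl"),
  c("benzoic acid", "benzoic"),
  c("salicylic acid", "benzoic"),
  c("phthalic acid", "benzoic"),
  c("3-hydroxybenzoic acid", "hydroxy_benzoic"),
  c("4-hydroxybenzoic acid", "hydroxy_benzoic"),
  c("3,5-dihydroxybenzoic acid", "hydroxy_benzoic")
)

# Brute-force group sums: iterate over the hand-typed pairs one by one.
oracle_group_sums <- function(contents) {
  sums <- c(p_hydroxy = 0, vanillyl = 0, syringyl = 0, coumaryl = 0,
            benzoic = 0, hydroxy_benzoic = 0)
  for (pair in membership_pairs) {
    sums[pair[2]] <- sums[pair[2]] + contents[[pair[1]]]
  }
  sums
}

# Brute-force confusion-matrix metrics.
oracle_accuracy <- function(truth, pred) {
  hits <- 0
  for (i in seq_along(truth)) if (truth[i] == pred[i]) hits <- hits + 1
  hits / length(truth)
}

oracle_f1 <- function(truth, pred, positive) {
  tp <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    t_pos <- truth[i] == positive
    p_pos <- pred[i] == positive
    if (t_pos && p_pos) tp <- tp + 1
    if (!t_pos && p_pos) fp <- fp + 1
    if (t_pos && !p_pos) fn <- fn + 1
  }
  if (tp + fp == 0 || tp + fn == 0) {
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) return(0)
  }
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (is.nan(prec)) prec <- 0
  if (is.nan(rec)) rec <- 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Random valid dataset with uniform contents, optionally with recoveries.
random_dataset <- function(n, seed = 1, with_recovery = FALSE) {
  set.seed(seed)
  m <- matrix(runif(n * 16, 0.01, 5), nrow = n)
  colnames(m) <- phenol_compounds()
  df <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    species = sample(c("Erica", "Festuca", "unknown"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (with_recovery) df$recovery <- runif(n, 0.5, 1)
  phenol_dataset(cbind(df, as.data.frame(m, check.names = FALSE)))
}

# Single-row dataset from a named content vector.
profile_dataset <- function(contents, species = "unknown", recovery = NA) {
  df <- data.frame(sample_id = "p1", species = species, recovery = recovery,
                   stringsAsFactors = FALSE)
  suppressWarnings(
    phenol_dataset(cbind(df, as.data.frame(as.list(contents),
                                           check.names = FALSE)))
  )
}
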