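test_that("group sums match the hand-typed membership oracle on random profiles", {
  d <- random_dataset(200, seed = 42)
  g <- group_sums(d)
  m <- content_matrix(d)
  for (i in sample(nrow(d), 25)) {
    expected <- oracle_group_sums(as.list(m[i, ]))
    got <- unlist(g[i, names(expected)])
    expect_equal(unname(got), unname(expected))
  }
  # conservation: six groups double-count exactly the 4-hydroxybenzoic content
  overlap <- rowSums(g[, names(phenol_groups())]) - g$total_phenols
  expect_equal(overlap, unname(m[, "4-hydroxybenzoic acid"]),
               tolerance = 1e-12)
})

test_that("group sums reproduce member counts on a unit profile", {
  unit <- setNames(rep(1, 16), phenol_compounds())
  g <- group_sums(profile_dataset(unit))
  expect_equal(unlist(g[1, names(phenol_groups())], use.names = FALSE),
               c(3, 3, 3, 2, 3, 3))
  expect_equal(g$total_phenols, 16)
  zero <- setNames(rep(0, 16), phenol_compounds())
  g0 <- group_sums(profile_dataset(zero))
  expect_true(all(unlist(g0[1, c(names(phenol_groups()), "total_phenols")]) == 0))
})

test_that("relative abundances divide by the 16-compound total", {
  unit <- setNames(rep(1, 16), phenol_compounds())
  rel <- relative_group_abundances(group_sums(profile_dataset(unit)))
  expect_equal(rel$coumaryl, 2 / 16)
  # fractions sum to (total + 4-hydroxybenzoic)/total
  d <- random_dataset(50, seed = 5)
  g <- group_sums(d)
  rel <- relative_group_abundances(g)
  lhs <- rowSums(rel[, names(phenol_groups())])
  rhs <- (g$total_phenols + content_matrix(d)[, "4-hydroxybenzoic acid"]) /
    g$total_phenols
  expect_equal(lhs, unname(rhs), tolerance = 1e-12)
  zero <- setNames(rep(0, 16), phenol_compounds())
  expect_error(relative_group_abundances(group_sums(profile_dataset(zero))),
               "empty profile")
})

test_that("proxy ratios are simple quotients and fail when vanillyl is 0", {
  g <- data.frame(sample_id = "x", species = "unknown",
                  vanillyl = 2, syringyl = 3, coumaryl = 1)
  r <- proxy_ratios(g)
  expect_equal(r$s_over_v, 1.5)
  expect_equal(r$c_over_v, 0.5)
  g$coumaryl <- 0
  expect_equal(proxy_ratios(g)$c_over_v, 0)
  g$vanillyl <- 0
  expect_error(proxy_ratios(g), "vanillyl")
})

test_that("Shannon index hits its closed forms", {
  unit <- setNames(rep(1, 16), phenol_compounds())
  expect_equal(unname(shannon_index(profile_dataset(unit))), log(16),
               tolerance = 1e-12)
  single <- setNames(c(5, rep(0, 15)), phenol_compounds())
  expect_equal(unname(shannon_index(profile_dataset(single))), 0)
  two <- setNames(c(3, 3, rep(0, 14)), phenol_compounds())
  expect_equal(unname(shannon_index(profile_dataset(two))), log(2),
               tolerance = 1e-12)
  zero <- setNames(rep(0, 16), phenol_compounds())
  expect_error(shannon_index(profile_dataset(zero)), "all-zero")
})

test_that("Shannon index is bounded, permutation- and scale-invariant", {
  d <- random_dataset(100, seed = 9)
  h <- shannon_index(d)
  expect_true(all(h >= 0 & h <= log(16) + 1e-12))
  m <- content_matrix(d)
  perm <- sample(16)
  d_perm <- profile_dataset(setNames(m[1, perm], phenol_compounds()))
  expect_equal(unname(shannon_index(d_perm)), unname(h[1]),
               tolerance = 1e-12)
  d_scaled <- profile_dataset(setNames(m[1, ] * 7.3, phenol_compounds()))
  expect_equal(unname(shannon_index(d_scaled)), unname(h[1]),
               tolerance = 1e-12)
})

test_that("recovery correction exactly inverts simulated proportional loss", {
  d <- random_dataset(40, seed = 13)
  true_m <- content_matrix(d)
  set.seed(14)
  r <- runif(40, 0.3, 1)
  lost <- as.data.frame(d)
  lost[phenol_compounds()] <- lost[phenol_compounds()] * r
  lost$recovery <- r
  corrected <- recovery_correct(phenol_dataset(lost))
  expect_equal(content_matrix(corrected), true_m, tolerance = 1e-12)
  expect_true(all(corrected$recovery == 1))
  # recovery 1 -> identity
  lost$recovery <- 1
  lost[phenol_compounds()] <- true_m
  expect_equal(content_matrix(recovery_correct(phenol_dataset(lost))), true_m)
  # absent recovery -> error
  expect_error(recovery_correct(d), "no recovery information")
})

test_that("feature table stitches groups, fractions, ratios and diversity", {
  d <- random_dataset(10, seed = 21)
  f <- phenol_features(d)
  expect_equal(f$coumaryl_rel, f$coumaryl / f$total_phenols)
  expect_equal(f$s_over_v, f$syringyl / f$vanillyl)
  expect_equal(f$h, unname(shannon_index(d)))
})
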