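test_that("the default configuration reproduces the study design", {
  cfg <- default_generator_config()
  names_n <- vapply(cfg$species, function(s) s$name, character(1))
  ns <- vapply(cfg$species, function(s) s$n_samples, integer(1))
  expect_equal(sum(ns), 47L)
  expect_equal(ns[names_n == "Erica"], 29L)
  totals <- setNames(vapply(cfg$species, function(s) s$total_mean, numeric(1)),
                     names_n)
  expect_equal(totals[c("Alchemilla", "Erica", "Helichrysum", "Kniphofia",
                        "Lobelia", "Festuca")],
               c(Alchemilla = 18, Erica = 16, Helichrysum = 22, Kniphofia = 6,
                 Lobelia = 22, Festuca = 51))
  expect_equal(sum(vapply(default_generator_config(scale_factor = 3)$species,
                          function(s) s$n_samples, integer(1))), 141L)
})

test_that("configured mean compositions encode the documented contrasts", {
  cfg <- default_generator_config()
  comp <- sapply(cfg$species, function(s) s$mean_composition)
  colnames(comp) <- vapply(cfg$species, function(s) s$name, character(1))
  groups <- phenol_groups()
  gfrac <- sapply(names(groups), function(g) {
    colSums(comp[groups[[g]], , drop = FALSE])
  })
  # Erica and only Erica passes the threshold rule at its expected composition
  pass <- gfrac[, "coumaryl"] > 0.20 &
    gfrac[, "benzoic"] >= 0.05 & gfrac[, "benzoic"] <= 0.12
  expect_identical(names(pass)[pass], "Erica")
  # p-hydroxy: Helichrysum highest, Erica lowest
  expect_equal(names(which.max(gfrac[, "p_hydroxy"])), "Helichrysum")
  expect_equal(names(which.min(gfrac[, "p_hydroxy"])), "Erica")
  # Festuca: top coumaryl, bottom vanillyl and benzoic
  expect_equal(names(which.max(gfrac[, "coumaryl"])), "Festuca")
  expect_equal(names(which.min(gfrac[, "vanillyl"])), "Festuca")
  expect_equal(names(which.min(gfrac[, "benzoic"])), "Festuca")
  # benzoic acids: the two singleton herbs on top
  expect_setequal(names(sort(gfrac[, "benzoic"], decreasing = TRUE)[1:2]),
                  c("Kniphofia", "Lobelia"))
})

test_that("simulation is deterministic and structurally valid", {
  cfg <- default_generator_config(seed = 123)
  d1 <- simulate_phenol_dataset(cfg)
  d2 <- simulate_phenol_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 47)
  m <- content_matrix(d1)
  expect_true(all(m > 0))
  expect_true(all(d1$recovery >= 0.6 & d1$recovery <= 0.95))
  # compositions (fractions of each sample's total) sum to 1 by construction
  expect_equal(rowSums(m / rowSums(m)), setNames(rep(1, 47), rownames(m)),
               tolerance = 1e-12)
})

test_that("species means converge to configured targets at scale 10", {
  cfg <- default_generator_config(scale_factor = 10)
  d <- recovery_correct(simulate_phenol_dataset(cfg))
  m <- content_matrix(d)
  comp <- m / rowSums(m)
  groups <- phenol_groups()
  for (sp in cfg$species) {
    rows <- d$species == sp$name
    mean_comp <- colMeans(comp[rows, , drop = FALSE])
    for (g in names(groups)) {
      expect_lt(abs(sum(mean_comp[groups[[g]]]) -
                      sum(sp$mean_composition[groups[[g]]])), 0.02)
    }
    rel_err <- abs(mean(rowSums(m[rows, , drop = FALSE])) - sp$total_mean) /
      sp$total_mean
    expect_lt(rel_err, 0.10)
  }
})

test_that("generated profiles separate under the Erica rule across seeds", {
  rates <- t(vapply(1:10, function(s) {
    d <- recovery_correct(simulate_phenol_dataset(
      default_generator_config(seed = s)))
    r <- classify_erica_rule(relative_group_abundances(group_sums(d)))
    c(erica = mean(r$is_erica[r$species == "Erica"]),
      other = mean(r$is_erica[r$species != "Erica"]))
  }, numeric(2)))
  expect_gte(mean(rates[, "erica"]), 0.9)
  expect_lte(mean(rates[, "other"]), 0.1)
})

test_that("planted threshold data are labelled exactly at the cut", {
  pt <- planted_threshold_dataset(500, cut = 0.21, seed = 4)
  expect_identical(pt$y, ifelse(pt$X[, "coumaryl"] > 0.21, "Erica", "non-Erica"))
  # class balance tracks the uniform measure above the cut
  expect_equal(mean(pt$y == "Erica"), (0.45 - 0.21) / 0.45, tolerance = 0.08)
  # determinism
  pt2 <- planted_threshold_dataset(500, cut = 0.21, seed = 4)
  expect_identical(pt, pt2)
})
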