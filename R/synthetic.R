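#' Specification of one synthetic species class
#'
#' Describes how phenol profiles of one species are simulated: per-sample
#' compound compositions are drawn from a Dirichlet distribution around
#' `mean_composition` with precision `concentration`, per-sample phenol
#' totals from a log-normal with mean `total_mean` (g kg^-1 TOC) and
#' coefficient of variation `total_cv`, and internal-standard recoveries
#' uniformly from `recovery_range`.
#'
#' @param name Species name.
#' @param n_samples Number of samples to generate.
#' @param mean_composition Named numeric vector over the 16 canonical
#'   compounds, strictly positive, summing to 1.
#' @param total_mean Mean total phenol content, g kg^-1 TOC.
#' @param concentration Dirichlet precision (> 0); larger = less
#'   within-species compositional spread.
#' @param total_cv Coefficient of variation of the log-normal totals.
#' @param recovery_range Interval within (0, 1] for simulated recoveries.
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, n_samples, mean_composition, total_mean,
                         concentration = 800, total_cv = 0.06,
                         recovery_range = c(0.6, 0.95)) {
  compounds <- phenol_compounds()
  stopifnot(
    n_samples >= 1,
    setequal(names(mean_composition), compounds),
    all(mean_composition > 0),
    abs(sum(mean_composition) - 1) < 1e-9,
    concentration > 0, total_mean > 0, total_cv >= 0,
    length(recovery_range) == 2,
    recovery_range[1] > 0, recovery_range[2] <= 1,
    recovery_range[1] <= recovery_range[2]
  )
  structure(
    list(name = name, n_samples = as.integer(n_samples),
         mean_composition = mean_composition[compounds],
         total_mean = total_mean, concentration = concentration,
         total_cv = total_cv, recovery_range = recovery_range),
    class = "species_spec"
  )
}

# Expand group-level fractions to a 16-compound mean composition by spreading
# each group's fraction uniformly over its member compounds. `fractions` is a
# vector over the six disjoint composition slots: p_hydroxy (3 compounds,
# including the shared 4-hydroxybenzoic acid), vanillyl, syringyl, coumaryl,
# benzoic, and the two hydroxy-benzoic compounds outside p_hydroxy.
.composition_from_groups <- function(fractions) {
  groups <- phenol_groups()
  slots <- list(
    groups$p_hydroxy,
    groups$vanillyl,
    groups$syringyl,
    groups$coumaryl,
    groups$benzoic,
    setdiff(groups$hydroxy_benzoic, groups$p_hydroxy)
  )
  stopifnot(length(fractions) == 6, abs(sum(fractions) - 1) < 1e-9)
  comp <- numeric(16)
  names(comp) <- phenol_compounds()
  for (i in seq_along(slots)) {
    comp[slots[[i]]] <- fractions[i] / length(slots[[i]])
  }
  comp
}

#' Default synthetic-study configuration
#'
#' Six species with the study's sample counts (29 Erica, 5 Alchemilla,
#' 7 Festuca, 4 Helichrysum, 1 Kniphofia, 1 Lobelia; 47 samples at scale
#' factor 1) and mean total phenol contents (Erica 16, Alchemilla 18,
#' Festuca 51, Helichrysum 22, Kniphofia 6, Lobelia 22 g kg^-1 TOC). Mean
#' compositions are synthetic (per-compound values were never published) and
#' are constructed from group-level fractions so that:
#' Erica's expected coumaryl fraction exceeds 0.20 with benzoic acids inside
#' 0.05-0.12 while every other species violates at least one condition;
#' Helichrysum has the highest p-hydroxy fraction and the lowest
#' hydroxy-benzoic, Erica the lowest p-hydroxy; Festuca has high coumaryl
#' and syringyl with the lowest vanillyl and benzoic; Kniphofia and Lobelia
#' have the highest benzoic acids, Lobelia the highest vanillyl and lowest
#' syringyl.
#'
#' @param scale_factor Integer multiplier on all per-species sample counts.
#' @param seed Integer seed stored in the configuration.
#' @param concentration Dirichlet precision shared by all species
#'   (default 800).
#' @param total_cv Total-content coefficient of variation (default 0.06).
#' @param recovery_range Simulated recovery interval (default 0.6-0.95).
#' @return A `phenol_generator_config` list (`species`, `seed`,
#'   `scale_factor`).
#' @export
default_generator_config <- function(scale_factor = 1, seed = 42,
                                     concentration = 800, total_cv = 0.06,
                                     recovery_range = c(0.6, 0.95)) {
  stopifnot(scale_factor >= 1)
  # columns: p_hydroxy, vanillyl, syringyl, coumaryl, benzoic,
  #          hydroxy-benzoic (the two compounds outside p_hydroxy)
  defs <- list(
    Erica       = list(n = 29, total = 16,
                       frac = c(0.04, 0.22, 0.22, 0.27, 0.085, 0.165)),
    Alchemilla  = list(n = 5, total = 18,
                       frac = c(0.14, 0.10, 0.36, 0.09, 0.08, 0.23)),
    Festuca     = list(n = 7, total = 51,
                       frac = c(0.10, 0.06, 0.28, 0.33, 0.02, 0.21)),
    Helichrysum = list(n = 4, total = 22,
                       frac = c(0.32, 0.24, 0.20, 0.08, 0.105, 0.055)),
    Kniphofia   = list(n = 1, total = 6,
                       frac = c(0.08, 0.26, 0.10, 0.12, 0.32, 0.12)),
    Lobelia     = list(n = 1, total = 22,
                       frac = c(0.10, 0.28, 0.08, 0.12, 0.25, 0.17))
  )
  species <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    species_spec(
      name = nm, n_samples = d$n * scale_factor,
      mean_composition = .composition_from_groups(d$frac),
      total_mean = d$total, concentration = concentration,
      total_cv = total_cv, recovery_range = recovery_range
    )
  })
  structure(
    list(species = species, seed = as.integer(seed),
         scale_factor = as.integer(scale_factor)),
    class = "phenol_generator_config"
  )
}

#' @export
print.phenol_generator_config <- function(x, ...) {
  cat("phenol generator config: seed", x$seed,
      "| scale", x$scale_factor, "\n")
  for (sp in x$species) {
    cat(sprintf("  %-12s n = %3d, total = %4.1f g/kg TOC\n",
                sp$name, sp$n_samples, sp$total_mean))
  }
  invisible(x)
}

#' Simulate a species-labelled phenol dataset
#'
#' For every sample: a 16-compound composition is drawn from
#' Dirichlet(concentration x mean_composition) (via gamma draws), a total
#' phenol content from a log-normal matching the species' mean and CV, and a
#' recovery fraction uniformly from the species' recovery range. The stored
#' compound contents are the "as-measured" values, i.e. the true contents
#' (composition x total) multiplied by the recovery, so that
#' [recovery_correct()] exactly restores the true contents and the
#' correction stage is exercised end to end. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [default_generator_config()]-style configuration.
#' @return A [phenol_dataset()] with `recovery` filled in.
#' @export
simulate_phenol_dataset <- function(config) {
  stopifnot(inherits(config, "phenol_generator_config"))
  if (anyDuplicated(vapply(config$species, `[[`, "", "name"))) {
    stop("species names must be unique", call. = FALSE)
  }
  compounds <- phenol_compounds()
  set.seed(config$seed)
  rows <- list()
  for (sp in config$species) {
    alpha <- sp$concentration * sp$mean_composition
    sdlog <- sqrt(log(1 + sp$total_cv^2))
    meanlog <- log(sp$total_mean) - sdlog^2 / 2
    for (i in seq_len(sp$n_samples)) {
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      composition <- g / sum(g)
      total <- stats::rlnorm(1, meanlog = meanlog, sdlog = sdlog)
      recovery <- stats::runif(1, sp$recovery_range[1], sp$recovery_range[2])
      contents <- composition * total * recovery  # as-measured (with loss)
      row <- as.data.frame(as.list(stats::setNames(contents, compounds)),
                           check.names = FALSE)
      row <- cbind(
        data.frame(sample_id = sprintf("%s_%03d", sp$name, i),
                   species = sp$name, recovery = recovery,
                   stringsAsFactors = FALSE),
        row
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  phenol_dataset(do.call(rbind, rows))
}

#' Two-class dataset with a single planted threshold
#'
#' One informative feature (named `coumaryl`) is uniform on (0, 0.45) and the
#' class is `"Erica"` exactly when its value exceeds `cut`; the remaining
#' features are label-independent uniform noise. Used to check that CART
#' recovers a single decisive cut such as the 0.21 coumaryl threshold.
#'
#' @param n Number of samples (>= 10).
#' @param cut Planted threshold (default 0.21).
#' @param noise_features Number of noise features (default 4).
#' @param seed Integer seed.
#' @return List with matrix `X` and label vector `y`.
#' @export
planted_threshold_dataset <- function(n, cut = 0.21, noise_features = 4,
                                      seed = 1) {
  stopifnot(n >= 10)
  set.seed(seed)
  signal <- stats::runif(n, 0, 0.45)
  X <- cbind(coumaryl = signal)
  if (noise_features > 0) {
    noise <- matrix(stats::runif(n * noise_features, 0, 0.45), nrow = n)
    colnames(noise) <- paste0("noise", seq_len(noise_features))
    X <- cbind(X, noise)
  }
  list(X = X, y = ifelse(signal > cut, "Erica", "non-Erica"))
}

#' Two-class dataset with signal planted in two named features
#'
#' Emulates the relative-abundance feature set in which only the coumaryl
#' and benzoic-acid fractions carry class information: for `"Erica"` samples
#' `coumaryl` is centered at 0.27 (sd 0.04) and `benzoic` at 0.085
#' (sd 0.02); for `"non-Erica"` samples at 0.12 (sd 0.05) and 0.17
#' (sd 0.05). The remaining features (`syringyl`, `vanillyl`, `p_hydroxy`,
#' `hydroxy_benzoic`, ...) are label-independent uniform noise on (0, 0.45).
#' Values are truncated at 0. Used for feature-importance ranking checks.
#'
#' @param n Number of samples (split as evenly as possible between classes).
#' @param noise_features Number of noise features, up to extra generic names
#'   beyond the four group-like ones (default 4).
#' @param seed Integer seed.
#' @return List with matrix `X` and label vector `y`.
#' @export
planted_importance_dataset <- function(n, noise_features = 4, seed = 1) {
  stopifnot(n >= 10)
  set.seed(seed)
  n_pos <- floor(n / 2)
  y <- c(rep("Erica", n_pos), rep("non-Erica", n - n_pos))
  coumaryl <- pmax(0, ifelse(y == "Erica",
                             stats::rnorm(n, 0.27, 0.04),
                             stats::rnorm(n, 0.12, 0.05)))
  benzoic <- pmax(0, ifelse(y == "Erica",
                            stats::rnorm(n, 0.085, 0.02),
                            stats::rnorm(n, 0.17, 0.05)))
  X <- cbind(coumaryl = coumaryl, benzoic = benzoic)
  if (noise_features > 0) {
    noise_names <- c("syringyl", "vanillyl", "p_hydroxy", "hydroxy_benzoic",
                     paste0("noise", seq_len(max(0, noise_features - 4))))
    noise_names <- noise_names[seq_len(noise_features)]
    noise <- matrix(stats::runif(n * noise_features, 0, 0.45), nrow = n)
    colnames(noise) <- noise_names
    X <- cbind(X, noise)
  }
  perm <- sample.int(n)  # shuffle so class blocks are not contiguous
  list(X = X[perm, , drop = FALSE], y = y[perm])
}
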