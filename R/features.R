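#' Correct compound contents for internal-standard recovery
#'
#' Analyte losses during extraction and clean-up are quantified by the
#' measured recovery of a spiked internal standard (ethylvanillin). The
#' correction divides every compound content by the sample's recovery
#' fraction, i.e. it exactly inverts a proportional loss, and sets the
#' recovery of the result to 1.
#'
#' @param dataset A [phenol_dataset()] whose `recovery` column is present and
#'   in (0, 1] for every sample.
#' @return A `phenol_dataset` with corrected contents and recovery 1.
#' @export
recovery_correct <- function(dataset) {
  stopifnot(inherits(dataset, "phenol_dataset"))
  if (anyNA(dataset$recovery)) {
    stop("no recovery information for sample(s): ",
         paste(dataset$sample_id[is.na(dataset$recovery)], collapse = ", "),
         call. = FALSE)
  }
  compounds <- phenol_compounds()
  out <- as.data.frame(dataset)
  out[compounds] <- out[compounds] / out$recovery
  out$recovery <- 1
  phenol_dataset(out)
}

#' Phenol group sums (g kg^-1 TOC)
#'
#' Sums the per-compound contents into the six diagnostic groups of
#' [phenol_groups()]. `total_phenols` is the plain sum over all 16 compounds,
#' so the six group sums exceed it by exactly the 4-hydroxybenzoic acid
#' content (the one double-membership compound).
#'
#' @param dataset A [phenol_dataset()].
#' @return Data frame with `sample_id`, `species`, the six group sums, and
#'   `total_phenols`.
#' @export
group_sums <- function(dataset) {
  stopifnot(inherits(dataset, "phenol_dataset"))
  m <- content_matrix(dataset)
  groups <- phenol_groups()
  out <- data.frame(
    sample_id = dataset$sample_id,
    species = dataset$species,
    stringsAsFactors = FALSE
  )
  for (g in names(groups)) {
    out[[g]] <- rowSums(m[, groups[[g]], drop = FALSE])
  }
  out$total_phenols <- rowSums(m)
  out
}

#' Relative group abundances
#'
#' Each group sum divided by `total_phenols` (the 16-compound total). Because
#' 4-hydroxybenzoic acid is counted in both p_hydroxy and hydroxy_benzoic,
#' the six fractions sum to (total + 4-hydroxybenzoic)/total rather than
#' exactly 1; the per-group definitions are kept as-is rather than
#' renormalized.
#'
#' @param g Output of [group_sums()].
#' @return Data frame with `sample_id`, `species` and the six fractions.
#' @export
relative_group_abundances <- function(g) {
  grp <- names(phenol_groups())
  stopifnot(all(c("total_phenols", grp) %in% names(g)))
  if (any(g$total_phenols <= 0)) {
    stop("empty profile: total_phenols must be > 0 (sample(s): ",
         paste(g$sample_id[g$total_phenols <= 0], collapse = ", "), ")",
         call. = FALSE)
  }
  out <- g[, c("sample_id", "species")]
  out[grp] <- g[grp] / g$total_phenols
  out
}

#' Lignin source-proxy ratios S/V and C/V
#'
#' The classical syringyl/vanillyl and coumaryl(cinnamyl)/vanillyl ratios
#' used as vascular-plant source proxies for organic matter.
#'
#' @param g Output of [group_sums()] (or any data frame with `vanillyl`,
#'   `syringyl` and `coumaryl` columns).
#' @return Data frame with `sample_id`, `species`, `s_over_v`, `c_over_v`.
#' @export
proxy_ratios <- function(g) {
  stopifnot(all(c("vanillyl", "syringyl", "coumaryl") %in% names(g)))
  if (any(g$vanillyl == 0)) {
    stop("S/V and C/V undefined: vanillyl = 0 (sample(s): ",
         paste(g$sample_id[g$vanillyl == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  data.frame(
    sample_id = g$sample_id,
    species = g$species,
    s_over_v = g$syringyl / g$vanillyl,
    c_over_v = g$coumaryl / g$vanillyl,
    stringsAsFactors = FALSE
  )
}

#' Shannon-Wiener phenol diversity index
#'
#' H = -sum(p_i log p_i) in nats, where p_i is compound i's share of the
#' 16-compound total within a sample and 0 log 0 is taken as 0. H ranges
#' from 0 (a single compound) to log(16) ~ 2.7726 (perfectly even profile)
#' and measures how evenly a sample's phenols are distributed over the
#' sixteen compounds.
#'
#' @param dataset A [phenol_dataset()].
#' @return Named numeric vector of H values (names = sample ids).
#' @export
shannon_index <- function(dataset) {
  stopifnot(inherits(dataset, "phenol_dataset"))
  m <- content_matrix(dataset)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("all-zero profile: Shannon index undefined (sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "), ")", call. = FALSE)
  }
  p <- m / totals
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -rowSums(terms)
  names(h) <- dataset$sample_id
  h
}

#' Per-sample phenol feature table
#'
#' Convenience wrapper computing, for every sample: the six group sums,
#' `total_phenols`, the six relative group abundances (suffix `_rel`), the
#' S/V and C/V proxy ratios, and the Shannon-Wiener diversity index `h`.
#'
#' @param dataset A [phenol_dataset()]; correct for recovery first with
#'   [recovery_correct()] if recoveries were measured.
#' @return Data frame with one row per sample.
#' @export
phenol_features <- function(dataset) {
  g <- group_sums(dataset)
  rel <- relative_group_abundances(g)
  ratios <- proxy_ratios(g)
  grp <- names(phenol_groups())
  out <- g
  out[paste0(grp, "_rel")] <- rel[grp]
  out$s_over_v <- ratios$s_over_v
  out$c_over_v <- ratios$c_over_v
  out$h <- unname(shannon_index(dataset))
  out
}
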