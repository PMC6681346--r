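#' The sixteen canonical CuO-oxidation phenolic compounds
#'
#' Mild alkaline CuO oxidation of plant tissue releases a reproducible set of
#' sixteen phenolic monomers that are quantified by GC-MS and expressed in
#' g per kg total organic carbon (TOC). All functions in this package identify
#' compounds by these canonical lower-case names, in this fixed order.
#'
#' @return Character vector of the 16 canonical compound names.
#' @seealso [phenol_groups()] for the group memberships.
#' @export
#' @examples
#' phenol_compounds()
phenol_compounds <- function() {
  c(
    "4-hydroxybenzaldehyde",
    "4-hydroxyacetophenone",
    "4-hydroxybenzoic acid",
    "vanillin",
    "4-hydroxy-3-methoxyacetophenone",
    "vanillic acid",
    "syringaldehyde",
    "3,5-dimethoxy-4-hydroxyacetophenone",
    "syringic acid",
    "p-coumaric acid",
    "ferulic acid",
    "benzoic acid",
    "salicylic acid",
    "phthalic acid",
    "3-hydroxybenzoic acid",
    "3,5-dihydroxybenzoic acid"
  )
}

#' Phenol group definitions
#'
#' The six diagnostic phenol groups used throughout lignin-phenol
#' chemotaxonomy, each defined as a sum of canonical compounds:
#' \describe{
#'   \item{p_hydroxy}{4-hydroxybenzaldehyde + 4-hydroxyacetophenone +
#'     4-hydroxybenzoic acid}
#'   \item{vanillyl}{vanillin + 4-hydroxy-3-methoxyacetophenone +
#'     vanillic acid}
#'   \item{syringyl}{syringaldehyde + 3,5-dimethoxy-4-hydroxyacetophenone +
#'     syringic acid}
#'   \item{coumaryl}{p-coumaric acid + ferulic acid}
#'   \item{benzoic}{benzoic acid + salicylic acid + phthalic acid}
#'   \item{hydroxy_benzoic}{3-hydroxybenzoic acid + 4-hydroxybenzoic acid +
#'     3,5-dihydroxybenzoic acid}
#' }
#' 4-hydroxybenzoic acid is the single compound with a double membership
#' (p_hydroxy and hydroxy_benzoic); every other compound belongs to exactly
#' one group.
#'
#' @return Named list of six character vectors of compound names.
#' @export
#' @examples
#' phenol_groups()$coumaryl
phenol_groups <- function() {
  list(
    p_hydroxy = c(
      "4-hydroxybenzaldehyde",
      "4-hydroxyacetophenone",
      "4-hydroxybenzoic acid"
    ),
    vanillyl = c(
      "vanillin",
      "4-hydroxy-3-methoxyacetophenone",
      "vanillic acid"
    ),
    syringyl = c(
      "syringaldehyde",
      "3,5-dimethoxy-4-hydroxyacetophenone",
      "syringic acid"
    ),
    coumaryl = c("p-coumaric acid", "ferulic acid"),
    benzoic = c("benzoic acid", "salicylic acid", "phthalic acid"),
    hydroxy_benzoic = c(
      "3-hydroxybenzoic acid",
      "4-hydroxybenzoic acid",
      "3,5-dihydroxybenzoic acid"
    )
  )
}

#' Species labels recognised by the package
#'
#' The six dominant species classes plus `"unknown"` for unlabelled samples.
#'
#' @return Character vector of valid species labels.
#' @export
phenol_species <- function() {
  c("Erica", "Alchemilla", "Festuca", "Helichrysum", "Kniphofia", "Lobelia",
    "unknown")
}

# Synonym table: common spelling variants -> canonical name. Keys are stored
# after the same normalization applied to inputs (lower case, collapsed
# whitespace, unified dashes), so lookups are robust to case and separators.
.compound_synonyms <- c(
  "3,5-dimethoxy-4-acetophenone"  = "3,5-dimethoxy-4-hydroxyacetophenone",
  "acetosyringone"                = "3,5-dimethoxy-4-hydroxyacetophenone",
  "acetovanillone"                = "4-hydroxy-3-methoxyacetophenone",
  "p-hydroxybenzoic acid"         = "4-hydroxybenzoic acid",
  "p-hydroxybenzaldehyde"         = "4-hydroxybenzaldehyde",
  "p-hydroxyacetophenone"         = "4-hydroxyacetophenone",
  "coumaric acid"                 = "p-coumaric acid"
)

#' Normalize a compound name to its canonical registry form
#'
#' Lower-cases, collapses whitespace/underscores, unifies dash characters and
#' resolves known spelling variants (e.g. "3,5-dimethoxy-4-acetophenone" is
#' the same compound as "3,5-dimethoxy-4-hydroxyacetophenone").
#'
#' @param x Character vector of compound names.
#' @return Character vector of the same length; canonical names where
#'   recognised, otherwise the cleaned-up input unchanged.
#' @export
#' @examples
#' canonical_compound_name(c("Ferulic Acid", "p_coumaric_acid"))
canonical_compound_name <- function(x) {
  clean <- tolower(trimws(x))
  clean <- gsub("[–—−]", "-", clean)  # en/em dash, minus
  clean <- gsub("_", " ", clean)
  clean <- gsub("\\s+", " ", clean)
  # underscore-style names often carry a leading separator ("_4_hydroxy...")
  clean <- sub("^[ -]+", "", clean)
  # punctuation-insensitive lookup so "p_coumaric_acid" or "3,5 dimethoxy..."
  # resolve to the canonical spelling
  squash <- function(s) gsub("[^a-z0-9]", "", s)
  canon <- phenol_compounds()
  lookup <- c(stats::setNames(canon, squash(canon)),
              stats::setNames(unname(.compound_synonyms),
                              squash(names(.compound_synonyms))))
  hit <- match(squash(clean), names(lookup))
  clean[!is.na(hit)] <- lookup[hit[!is.na(hit)]]
  clean
}

#' Compound-group membership table
#'
#' Flattens [phenol_groups()] into a two-column data frame with one row per
#' (compound, group) pair. Because 4-hydroxybenzoic acid belongs to two
#' groups the table has 17 rows for 16 compounds.
#'
#' @return A data frame with columns `compound` and `group`.
#' @export
compound_group_table <- function() {
  groups <- phenol_groups()
  data.frame(
    compound = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
}
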