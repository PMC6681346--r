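#' Construct a phenol sample dataset
#'
#' A `phenol_dataset` is a data frame with one row per sample and columns
#' `sample_id`, `species`, optionally `recovery` (internal-standard recovery
#' fraction in (0, 1]) and one column per canonical compound
#' ([phenol_compounds()]) holding contents in g kg^-1 TOC.
#'
#' @param df A data frame with the columns described above. Compound columns
#'   are matched case-insensitively after canonical-name normalization
#'   ([canonical_compound_name()]).
#' @return A validated data frame of class `phenol_dataset` with compound
#'   columns renamed to canonical names and reordered to registry order.
#' @export
phenol_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  compounds <- phenol_compounds()

  if (!all(c("sample_id", "species") %in% names(df))) {
    stop("dataset needs 'sample_id' and 'species' columns", call. = FALSE)
  }

  canon <- canonical_compound_name(names(df))
  is_compound <- canon %in% compounds
  names(df)[is_compound] <- canon[is_compound]

  missing <- setdiff(compounds, names(df))
  if (length(missing) > 0) {
    stop("missing compound column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df))) {
    stop("duplicated compound column(s) after name normalization: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }

  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }

  df$species <- as.character(df$species)
  bad_species <- !(df$species %in% phenol_species())
  if (any(bad_species)) {
    warning("unknown species label(s) ",
            paste(unique(df$species[bad_species]), collapse = ", "),
            "; parsed as \"unknown\"", call. = FALSE)
    df$species[bad_species] <- "unknown"
  }

  if (!"recovery" %in% names(df)) df$recovery <- NA_real_
  df$recovery <- as.numeric(df$recovery)
  rec_ok <- is.na(df$recovery) | (df$recovery > 0 & df$recovery <= 1)
  if (!all(rec_ok)) {
    stop("recovery must be in (0, 1] (rows: ",
         paste(which(!rec_ok), collapse = ", "), ")", call. = FALSE)
  }

  for (cmp in compounds) {
    v <- as.numeric(df[[cmp]])
    if (anyNA(v)) {
      stop("non-numeric or missing content in column '", cmp, "'",
           call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      stop("negative content in column '", cmp, "', row(s) ",
           paste(neg, collapse = ", "), call. = FALSE)
    }
    df[[cmp]] <- v
  }

  df <- df[, c("sample_id", "species", "recovery", compounds)]
  rownames(df) <- NULL
  class(df) <- c("phenol_dataset", "data.frame")
  df
}

#' @export
print.phenol_dataset <- function(x, ...) {
  cat("phenol_dataset:", nrow(x), "samples,",
      length(phenol_compounds()), "compounds\n")
  tab <- table(x$species)
  cat("species:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract the sample-by-compound content matrix
#'
#' @param dataset A `phenol_dataset`.
#' @return Numeric matrix (samples x 16 compounds, g kg^-1 TOC) with
#'   `sample_id` row names and canonical compound column names.
#' @export
content_matrix <- function(dataset) {
  m <- as.matrix(as.data.frame(dataset)[, phenol_compounds(), drop = FALSE])
  rownames(m) <- dataset$sample_id
  m
}

#' Read a phenol sample table from CSV
#'
#' Expects a header row with `sample_id`, `species`, one column per canonical
#' compound (any recognised spelling, case-insensitive) and an optional
#' `recovery` column. Decimal separator is "."; encoding UTF-8.
#'
#' @param path Path to the CSV file.
#' @return A [phenol_dataset()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  phenol_dataset(df)
}

#' Write a phenol sample table to CSV
#'
#' Columns are written in registry order with at least 10 significant digits
#' so that a read/write round trip preserves contents to well below 1e-9.
#'
#' @param dataset A [phenol_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "phenol_dataset"))
  df <- as.data.frame(dataset)
  num_cols <- c("recovery", phenol_compounds())
  for (cl in num_cols) df[[cl]] <- sprintf("%.12g", df[[cl]])
  df$recovery[df$recovery == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
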