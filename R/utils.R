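#' @importFrom rlang .data
#' @importFrom utils head
NULL

# Concept types recognised across all resources, in the canonical order used
# to orient unordered pair-type labels (drug-gene, disease-variant, ...).
CTYPE_LEVELS <- c("drug", "disease", "gene", "variant", "haplotype")

# Source labels for the three association resources.
SOURCE_LEVELS <- c("pharmgkb", "gwas", "fda")

# Raw entity-type spellings found in source files, mapped to canonical types.
CTYPE_ALIASES <- c(
  "drug"             = "drug",
  "disease"          = "disease",
  "gene"             = "gene",
  "variant location" = "variant",
  "variant"          = "variant",
  "snp"              = "variant",
  "haplotype"        = "haplotype"
)

#' Canonicalise a concept name for identity and matching
#'
#' Lower-cases, trims, collapses internal whitespace and replaces curly
#' quotes with their ASCII equivalents. All name matching in the package
#' (seed filtering, lexicon lookup, predication joining) goes through this
#' one function so that the rules stay consistent.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalised names.
#' @export
norm_name <- function(x) {
  x <- ascii_quotes(x)
  x <- stringr::str_squish(x)
  tolower(x)
}

# Replace typographic quotes/dashes commonly present in extracted text.
ascii_quotes <- function(x) {
  x <- gsub("‘|’", "'", x)
  x <- gsub("“|”", "\"", x)
  gsub("–|—", "-", x)
}

#' Canonical concept identity key
#'
#' A concept is identified by its canonical type plus its normalised name
#' (`"gene:cyp1a2"`). The key is stable under case and whitespace changes in
#' the raw name, and two concepts of different types never collide.
#'
#' @param ctype Canonical concept type (`drug`, `disease`, `gene`,
#'   `variant`, `haplotype`).
#' @param name Raw concept name.
#' @return Character vector of keys.
#' @export
concept_key <- function(ctype, name) {
  paste0(ctype, ":", norm_name(name))
}

# Map raw entity-type strings to canonical types; unknown types are an error
# naming the offending value.
canonical_ctype <- function(x) {
  key <- norm_name(x)
  out <- unname(CTYPE_ALIASES[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown entity type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

# Orient an unordered concept pair so key1 <= key2 under the canonical
# type order (then lexicographically). Returns a list(key1, key2, pair_type).
orient_pair <- function(ctype1, key1, ctype2, key2) {
  r1 <- match(ctype1, CTYPE_LEVELS)
  r2 <- match(ctype2, CTYPE_LEVELS)
  swap <- r2 < r1 | (r1 == r2 & key2 < key1)
  list(
    key1 = ifelse(swap, key2, key1),
    key2 = ifelse(swap, key1, key2),
    pair_type = paste(
      ifelse(swap, ctype2, ctype1),
      ifelse(swap, ctype1, ctype2),
      sep = "-"
    )
  )
}

# Split a multi-valued cell on "," and ";", trim, and drop empties.
split_multi <- function(x) {
  parts <- strsplit(x %||% "", "[,;]")[[1]]
  parts <- stringr::str_squish(parts)
  parts[nzchar(parts)]
}

# Placeholder names treated as missing entities in source rows.
PLACEHOLDER_NAMES <- c("", "nr", "intergenic", "na")

is_placeholder_name <- function(x) {
  norm_name(x) %in% PLACEHOLDER_NAMES
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# ";"-join a list column of character vectors for TSV export.
join_multi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

# Inverse of join_multi: ";"-split a character vector into a list column.
split_multi_col <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}
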