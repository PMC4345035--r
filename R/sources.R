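#' Read a cancer seed list
#'
#' One term per line; blank lines and `#` comments are skipped. Terms are
#' de-duplicated case-insensitively, keeping the first spelling seen.
#'
#' @param path Path to a plain-text seed file.
#' @return Character vector of seed terms (original spelling).
#' @export
read_seed_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_squish(ascii_quotes(lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- lines[!duplicated(norm_name(lines))]
  if (length(terms) == 0) {
    stop("seed list is empty: ", path, call. = FALSE)
  }
  terms
}

# Empty canonical association-row tibble. pmids is a list column of
# character vectors so multi-valued PMID cells survive round trips.
empty_association_rows <- function() {
  tibble::tibble(
    entity1_id   = character(0),
    entity1_name = character(0),
    entity1_type = character(0),
    entity2_id   = character(0),
    entity2_name = character(0),
    entity2_type = character(0),
    pmids        = list(),
    source       = character(0)
  )
}

# Attach per-reason drop statistics to a parsed row tibble.
set_drop_stats <- function(rows, rows_in, drops) {
  attr(rows, "drop_stats") <- tibble::tibble(
    reason = names(drops),
    n = unname(unlist(drops))
  )
  attr(rows, "rows_in") <- rows_in
  rows
}

#' Drop statistics of a parsed source table
#'
#' Every reader counts the input rows it discards, by reason, so that
#' parsing stays auditable: `rows_in = rows kept + sum(drop_stats$n)`
#' (expanded formats such as the GWAS Catalog count records, not pairs).
#'
#' @param rows A tibble returned by one of the `read_*` functions.
#' @return A tibble with columns `reason` and `n`.
#' @export
drop_stats <- function(rows) {
  attr(rows, "drop_stats") %||% tibble::tibble(reason = character(0), n = integer(0))
}

read_tsv_quiet <- function(path, delim = "\t", quote = "\"") {
  readr::read_delim(
    path,
    delim = delim, quote = quote,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(0), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(
      "file ", path, " is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

#' Read a PharmGKB-style relationships file
#'
#' Parses a tab-separated relationships table with the seven columns
#' `Entity1_id`, `Entity1_name`, `Entity1_type`, `Entity2_id`,
#' `Entity2_name`, `Entity2_type`, `PMIDs` into canonical association rows.
#' The PMIDs cell is split on `;`; rows in which either entity name is
#' missing (or a placeholder such as `NR`/`intergenic`) are dropped and
#' counted in [drop_stats()].
#'
#' @param path Path to the relationships file.
#' @param delim Field delimiter (default tab).
#' @param quote Quote character.
#' @return A tibble of association rows with `source = "pharmgkb"`.
#' @export
read_pharmgkb_relationships <- function(path, delim = "\t", quote = "\"") {
  df <- read_tsv_quiet(path, delim, quote)
  cols <- c(
    "Entity1_id", "Entity1_name", "Entity1_type",
    "Entity2_id", "Entity2_name", "Entity2_type", "PMIDs"
  )
  require_columns(df, cols, path)
  if (nrow(df) == 0) {
    warning("no data rows in ", path, call. = FALSE)
    return(set_drop_stats(empty_association_rows(), 0L, list()))
  }
  missing_name <- is_placeholder_name(df$Entity1_name) |
    is_placeholder_name(df$Entity2_name)
  kept <- df[!missing_name, , drop = FALSE]
  rows <- tibble::tibble(
    entity1_id   = stringr::str_squish(ascii_quotes(kept$Entity1_id)),
    entity1_name = stringr::str_squish(ascii_quotes(kept$Entity1_name)),
    entity1_type = canonical_ctype(kept$Entity1_type),
    entity2_id   = stringr::str_squish(ascii_quotes(kept$Entity2_id)),
    entity2_name = stringr::str_squish(ascii_quotes(kept$Entity2_name)),
    entity2_type = canonical_ctype(kept$Entity2_type),
    pmids        = lapply(kept$PMIDs, split_multi),
    source       = "pharmgkb"
  )
  set_drop_stats(rows, nrow(df), list(missing_entity_name = sum(missing_name)))
}

#' Read entity detail files (disease/drug/gene)
#'
#' Parses a PharmGKB-style entity file carrying source-provided vocabulary
#' codes into a long tibble with one row per (entity, vocabulary, code).
#' Expected columns: `Id`, `Name`, `Type`, plus any of `SNOMED-CT`,
#' `RxNorm`, `MeSH`, `UMLS` (empty cells mean no code).
#'
#' @param path Path to the entity file.
#' @return Tibble with columns `source_id`, `name`, `ctype`, `vocabulary`,
#'   `code`.
#' @export
read_entity_records <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("Id", "Name", "Type"), path)
  vocab_cols <- intersect(c("SNOMED-CT", "RxNorm", "MeSH", "UMLS"), names(df))
  base <- tibble::tibble(
    source_id = df$Id,
    name = stringr::str_squish(ascii_quotes(df$Name)),
    ctype = canonical_ctype(df$Type)
  )
  out <- lapply(vocab_cols, function(v) {
    code <- stringr::str_squish(df[[v]])
    keep <- nzchar(code)
    dplyr::mutate(base[keep, ], vocabulary = v, code = code[keep])
  })
  dplyr::bind_rows(out)
}

#' Read the GWAS Catalog restricted to cancer seeds
#'
#' Keeps only records whose `Disease/Trait` matches a seed term
#' (case- and whitespace-insensitively). Each kept record is expanded into
#' pairwise association rows: one disease-gene row per reported gene, one
#' disease-SNP row per SNP, and one gene-SNP row per (gene, SNP)
#' combination within the record. Multi-valued gene and SNP cells are split
#' on `,` and `;`. SNP identifiers that are not `rs` followed by digits are
#' skipped with a warning; placeholder gene names (`NR`, `intergenic`) are
#' dropped and counted.
#'
#' @param path Path to the catalog file (TSV with header).
#' @param seeds Character vector of seed terms (see [read_seed_list()]).
#' @param delim Field delimiter.
#' @return A tibble of association rows with `source = "gwas"`.
#' @export
read_gwas_catalog <- function(path, seeds, delim = "\t") {
  df <- read_tsv_quiet(path, delim)
  require_columns(df, c("Disease/Trait", "Reported Gene(s)", "SNPs"), path)
  seed_keys <- norm_name(seeds)
  trait_match <- norm_name(df$`Disease/Trait`) %in% seed_keys
  kept <- df[trait_match, , drop = FALSE]

  n_bad_snp <- 0L
  n_placeholder_gene <- 0L
  out <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    trait <- stringr::str_squish(ascii_quotes(kept$`Disease/Trait`[i]))
    genes <- split_multi(kept$`Reported Gene(s)`[i])
    ph <- is_placeholder_name(genes)
    n_placeholder_gene <- n_placeholder_gene + sum(ph)
    genes <- genes[!ph]
    snps <- split_multi(kept$SNPs[i])
    bad <- !grepl("^rs[0-9]+$", snps)
    if (any(bad)) {
      warning(
        "skipping malformed SNP id(s): ", paste(snps[bad], collapse = ", "),
        call. = FALSE
      )
      n_bad_snp <- n_bad_snp + sum(bad)
      snps <- snps[!bad]
    }
    rows <- list()
    if (length(genes) > 0) {
      rows$dg <- tibble::tibble(
        entity1_id = trait, entity1_name = trait, entity1_type = "disease",
        entity2_id = genes, entity2_name = genes, entity2_type = "gene"
      )
    }
    if (length(snps) > 0) {
      rows$ds <- tibble::tibble(
        entity1_id = trait, entity1_name = trait, entity1_type = "disease",
        entity2_id = snps, entity2_name = snps, entity2_type = "variant"
      )
    }
    if (length(genes) > 0 && length(snps) > 0) {
      combos <- expand.grid(gene = genes, snp = snps, stringsAsFactors = FALSE)
      rows$gs <- tibble::tibble(
        entity1_id = combos$gene, entity1_name = combos$gene,
        entity1_type = "gene",
        entity2_id = combos$snp, entity2_name = combos$snp,
        entity2_type = "variant"
      )
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  rows <- dplyr::bind_rows(out)
  if (nrow(rows) == 0) {
    rows <- empty_association_rows()
  } else {
    rows$pmids <- rep(list(character(0)), nrow(rows))
    rows$source <- "gwas"
  }
  set_drop_stats(
    rows, nrow(df),
    list(
      trait_not_in_seeds = sum(!trait_match),
      malformed_snp_id = n_bad_snp,
      placeholder_gene = n_placeholder_gene
    )
  )
}

#' Read the FDA pharmacogenomic biomarker table, oncology rows only
#'
#' Keeps rows whose `Therapeutic areas` cell contains "Oncology"
#' (case-insensitively) and expands multi-gene `HUGO Symbol` cells into one
#' drug-gene association row per (drug, gene) combination. The drug column
#' may be named `Drug` or `Drug name`.
#'
#' @param path Path to the biomarker table (TSV with header).
#' @param delim Field delimiter.
#' @return A tibble of association rows with `source = "fda"`.
#' @export
read_fda_biomarkers <- function(path, delim = "\t") {
  df <- read_tsv_quiet(path, delim)
  drug_col <- intersect(c("Drug", "Drug name"), names(df))[1]
  if (is.na(drug_col)) {
    stop("file ", path, " is missing a drug-name column (Drug or Drug name)",
      call. = FALSE
    )
  }
  require_columns(df, c("Therapeutic areas", "HUGO Symbol"), path)
  onc <- grepl("oncology", df$`Therapeutic areas`, ignore.case = TRUE)
  kept <- df[onc, , drop = FALSE]
  out <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    drug <- stringr::str_squish(ascii_quotes(kept[[drug_col]][i]))
    genes <- split_multi(kept$`HUGO Symbol`[i])
    genes <- genes[!is_placeholder_name(genes)]
    if (!nzchar(drug) || length(genes) == 0) next
    out[[i]] <- tibble::tibble(
      entity1_id = drug, entity1_name = drug, entity1_type = "drug",
      entity2_id = genes, entity2_name = genes, entity2_type = "gene"
    )
  }
  rows <- dplyr::bind_rows(out)
  if (nrow(rows) == 0) {
    rows <- empty_association_rows()
  } else {
    rows$pmids <- rep(list(character(0)), nrow(rows))
    rows$source <- "fda"
  }
  set_drop_stats(rows, nrow(df), list(not_oncology = sum(!onc)))
}

#' Read a SemMedDB-style predication table
#'
#' Parses subject-predicate-object-PMID rows. Rows with a blank predicate
#' are skipped; exact duplicate (subject, predicate, object, pmid) tuples
#' are collapsed to one row.
#'
#' @param path Path to the predication table (TSV with header columns
#'   `subject_name`, `predicate`, `object_name`, `pmid`; SemMedDB-style
#'   uppercase spellings `SUBJECT_NAME` etc. are also accepted).
#' @return Tibble with columns `subject_name`, `predicate`, `object_name`,
#'   `pmid`.
#' @export
read_predications <- function(path) {
  df <- read_tsv_quiet(path)
  names(df) <- tolower(names(df))
  require_columns(df, c("subject_name", "predicate", "object_name", "pmid"), path)
  df <- tibble::tibble(
    subject_name = stringr::str_squish(ascii_quotes(df$subject_name)),
    predicate = stringr::str_squish(df$predicate),
    object_name = stringr::str_squish(ascii_quotes(df$object_name)),
    pmid = stringr::str_squish(df$pmid)
  )
  blank <- !nzchar(df$predicate) | !grepl("^[A-Za-z_]+$", df$predicate)
  rows <- dplyr::distinct(df[!blank, , drop = FALSE])
  set_drop_stats(rows, nrow(df), list(blank_predicate = sum(blank)))
}

#' Write association rows to a canonical TSV
#'
#' The dump is lossless: [read_association_rows()] on the emitted file
#' reproduces the identical row multiset. Intended for the `--dump-parsed`
#' audit trail.
#'
#' @param rows Association-row tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_rows <- function(rows, path) {
  out <- dplyr::mutate(rows, pmids = join_multi(.data$pmids))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a canonical association-row TSV
#'
#' @param path Path written by [write_association_rows()].
#' @return Association-row tibble.
#' @export
read_association_rows <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, names(empty_association_rows()), path)
  dplyr::mutate(df, pmids = split_multi_col(.data$pmids))
}
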