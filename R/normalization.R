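# Vocabulary a concept type normalizes into, and the syntax its codes obey.
VOCAB_FOR_CTYPE <- c(
  drug = "RxNorm", disease = "SNOMED-CT", gene = "HGNC",
  variant = "dbSNP", haplotype = "none"
)

code_syntax_ok <- function(vocabulary, code) {
  switch(vocabulary,
    "RxNorm" = grepl("^[0-9]+$", code),
    "SNOMED-CT" = grepl("^[0-9]+$", code),
    TRUE
  )
}

#' Read a flat term lexicon
#'
#' The packaged stand-in for an ontology term-lookup service: a TSV with
#' columns `vocabulary`, `code`, `preferred_name`, `synonyms`
#' (semicolon-separated, may be empty).
#'
#' @param path Path to the lexicon TSV.
#' @return Lexicon tibble.
#' @export
read_lexicon <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("vocabulary", "code", "preferred_name", "synonyms"), path)
  df
}

#' Exact-match resolver over a flat lexicon
#'
#' Returns a lookup function `f(name, vocabulary)` that mirrors the
#' exact-match contract of an ontology annotation service (the analogue of
#' querying with `isexactmatch = 1`): a code is returned only when the
#' query equals a preferred name or synonym after case folding and
#' whitespace collapsing; otherwise `NA`. Any function honouring this
#' contract (for example a live REST client) can be passed wherever a
#' resolver is expected.
#'
#' @param lexicon Lexicon tibble from [read_lexicon()].
#' @return A function `(name, vocabulary) -> code or NA_character_`.
#' @export
lexicon_resolver <- function(lexicon) {
  entries <- lexicon |>
    dplyr::mutate(syn = lapply(.data$synonyms, function(s) {
      c(character(0), if (!is.na(s) && nzchar(s)) strsplit(s, ";")[[1]])
    }))
  long <- tibble::tibble(
    vocabulary = rep(entries$vocabulary, lengths(entries$syn) + 1),
    term = norm_name(unlist(Map(
      function(p, s) c(p, s), entries$preferred_name, entries$syn
    ))),
    code = rep(entries$code, lengths(entries$syn) + 1)
  ) |>
    dplyr::distinct(.data$vocabulary, .data$term, .keep_all = TRUE)
  function(name, vocabulary) {
    i <- match(paste(vocabulary, norm_name(name)), paste(long$vocabulary, long$term))
    if (is.na(i)) NA_character_ else long$code[i]
  }
}

#' Read manual mapping overrides
#'
#' A YAML file with one block per vocabulary mapping names to codes:
#' ```yaml
#' RxNorm:
#'   "some drug name": "12345"
#' SNOMED-CT:
#'   "some disease name": "6789"
#' ```
#' Codes with the wrong syntax for their vocabulary (RxCUIs and SNOMED-CT
#' identifiers must be numeric) are a configuration error.
#'
#' @param path Path to the YAML file.
#' @return Named list `vocabulary -> named character vector (name -> code)`.
#' @export
read_manual_overrides <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(v) {
    codes <- vapply(raw[[v]], as.character, character(1))
    bad <- !vapply(codes, function(cd) code_syntax_ok(v, cd), logical(1))
    if (any(bad)) {
      stop(
        "invalid ", v, " code(s) in manual overrides: ",
        paste(codes[bad], collapse = ", "),
        call. = FALSE
      )
    }
    names(codes) <- norm_name(names(raw[[v]]))
    codes
  })
  names(out) <- names(raw)
  out
}

# Default name-pattern rules assigning a failure category to unmapped
# drug/disease names. First matching rule wins; "other" is the fallback.
default_failure_rules <- function() {
  tibble::tibble(
    category = c("chemical IUPAC name", "drug class", "too broad", "too narrow"),
    ctype = c("drug", "drug", "disease", "disease"),
    pattern = c(
      "[0-9]+-[a-z]|yl-|-benzene|-amine|oxy-|sulfon",
      "(s( and | )[a-z]+s$)|products$|agents$|inhibitors$",
      "disorders$|diseases$|conditions$",
      "^\\S+( \\S+){3,}$"
    )
  )
}

classify_unmapped <- function(name, ctype, rules = default_failure_rules()) {
  nm <- norm_name(name)
  for (i in seq_len(nrow(rules))) {
    if (ctype == rules$ctype[i] &&
        grepl(rules$pattern[i], nm, ignore.case = TRUE)) {
      return(rules$category[i])
    }
  }
  "other"
}

#' Normalize concepts to standard vocabularies
#'
#' Maps disease terms to SNOMED-CT and drug terms to RxNorm through three
#' tiers tried in order, the first hit winning and its method recorded:
#'
#' 1. `source_provided` — a code carried by the source entity files;
#' 2. `resolver_exact` — an exact-match lookup against the resolver;
#' 3. `manual` — a user-supplied override file.
#'
#' Genes and variants are already standard forms (HUGO symbols, rsIDs) and
#' pass through with their names as codes; haplotype names have no target
#' vocabulary and pass through unmapped-but-standard with vocabulary
#' `"none"`. Concepts failing all tiers stay in the network with
#' `method = "unmapped"` and a failure category assigned by name-pattern
#' rules.
#'
#' @param concepts Concept tibble (key, name, ctype), e.g. the `concepts`
#'   element of [expand_from_seeds()].
#' @param entities Optional long entity tibble from [read_entity_records()]
#'   supplying source-provided codes.
#' @param resolver Optional resolver function (see [lexicon_resolver()]).
#' @param overrides Optional manual overrides (see
#'   [read_manual_overrides()]).
#' @param failure_rules Rules tibble for categorising unmapped names.
#' @return Tibble (key, name, ctype, vocabulary, code, method,
#'   failure_category).
#' @export
normalize_concepts <- function(concepts, entities = NULL, resolver = NULL,
                               overrides = NULL,
                               failure_rules = default_failure_rules()) {
  n <- nrow(concepts)
  vocab <- unname(VOCAB_FOR_CTYPE[concepts$ctype])
  code <- rep(NA_character_, n)
  method <- rep("unmapped", n)
  category <- rep(NA_character_, n)

  entity_lookup <- NULL
  if (!is.null(entities) && nrow(entities) > 0) {
    entity_lookup <- entities |>
      dplyr::mutate(term = norm_name(.data$name)) |>
      dplyr::distinct(.data$vocabulary, .data$term, .keep_all = TRUE)
  }

  for (i in seq_len(n)) {
    ct <- concepts$ctype[i]
    if (ct %in% c("gene", "variant")) {
      code[i] <- if (ct == "gene") toupper(concepts$name[i]) else
        norm_name(concepts$name[i])
      method[i] <- "source_provided"
      next
    }
    if (ct == "haplotype") {
      code[i] <- concepts$name[i]
      method[i] <- "source_provided"
      next
    }
    v <- vocab[i]
    nm <- norm_name(concepts$name[i])
    if (!is.null(entity_lookup)) {
      j <- which(entity_lookup$vocabulary == v & entity_lookup$term == nm)
      if (length(j) > 0) {
        code[i] <- entity_lookup$code[j[1]]
        method[i] <- "source_provided"
        next
      }
    }
    if (!is.null(resolver)) {
      hit <- resolver(concepts$name[i], v)
      if (!is.na(hit)) {
        code[i] <- hit
        method[i] <- "resolver_exact"
        next
      }
    }
    if (!is.null(overrides) && v %in% names(overrides)) {
      hit <- overrides[[v]][nm]
      if (!is.na(hit)) {
        code[i] <- unname(hit)
        method[i] <- "manual"
        next
      }
    }
    category[i] <- classify_unmapped(concepts$name[i], ct, failure_rules)
  }
  tibble::tibble(
    key = concepts$key, name = concepts$name, ctype = concepts$ctype,
    vocabulary = ifelse(method == "unmapped", "none", vocab),
    code = code, method = method, failure_category = category
  )
}

#' Mapping coverage report
#'
#' Summarises normalization outcomes per concept type: totals, mapped
#' counts, percentage mapped (one decimal), per-method counts, and the
#' list of unmapped names with their failure categories.
#'
#' @param norms Normalization tibble from [normalize_concepts()].
#' @return A list with `by_ctype`, `by_method` and `unmapped` tibbles.
#' @export
coverage_report <- function(norms) {
  if (nrow(norms) == 0) {
    return(list(
      by_ctype = tibble::tibble(
        ctype = character(0), total = integer(0), mapped = integer(0),
        pct_mapped = numeric(0)
      ),
      by_method = tibble::tibble(
        ctype = character(0), method = character(0), n = integer(0)
      ),
      unmapped = tibble::tibble(
        name = character(0), ctype = character(0),
        failure_category = character(0)
      )
    ))
  }
  by_ctype <- norms |>
    dplyr::group_by(.data$ctype) |>
    dplyr::summarise(
      total = dplyr::n(),
      mapped = sum(.data$method != "unmapped"),
      pct_mapped = round(100 * .data$mapped / .data$total, 1),
      .groups = "drop"
    )
  by_method <- norms |>
    dplyr::count(.data$ctype, .data$method, name = "n")
  unmapped <- norms |>
    dplyr::filter(.data$method == "unmapped") |>
    dplyr::select("name", "ctype", "failure_category")
  list(by_ctype = by_ctype, by_method = by_method, unmapped = unmapped)
}
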