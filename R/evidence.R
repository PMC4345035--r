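#' Build a name-to-concept index for predication matching
#'
#' Maps normalised concept names (and, when a normalization table is
#' supplied, the preferred names of their assigned codes from the lexicon)
#' to concept keys. Predication subject/object strings are resolved through
#' this index by case-insensitive exact match.
#'
#' @param concepts Concept tibble (key, name).
#' @param norms Optional normalization tibble from [normalize_concepts()].
#' @param lexicon Optional lexicon tibble supplying preferred names for
#'   codes.
#' @return Tibble (term, key), one row per distinct term.
#' @export
build_name_index <- function(concepts, norms = NULL, lexicon = NULL) {
  idx <- tibble::tibble(term = norm_name(concepts$name), key = concepts$key)
  if (!is.null(norms) && !is.null(lexicon)) {
    pref <- norms |>
      dplyr::filter(!is.na(.data$code)) |>
      dplyr::inner_join(
        lexicon[, c("vocabulary", "code", "preferred_name")],
        by = c("vocabulary", "code")
      )
    if (nrow(pref) > 0) {
      idx <- dplyr::bind_rows(
        idx,
        tibble::tibble(term = norm_name(pref$preferred_name), key = pref$key)
      )
    }
  }
  dplyr::distinct(idx, .data$term, .keep_all = TRUE)
}

#' Attach literature evidence from semantic predications
#'
#' Joins a predication table against the network's association edges:
#' a predication supports an edge when its subject and object names each
#' resolve (case-insensitive exact match through `name_index`) to the
#' edge's two endpoints, in either order. Matching predications contribute
#' their PMIDs and predicate strings (kept verbatim, including `NEG_`
#' prefixes). Edges that already carry source PMIDs (PharmGKB rows) are
#' reported with provenance `source_file`; edges gaining PMIDs only through
#' predications get provenance `predication_match`. Evidence only
#' decorates existing edges; no new association is ever created.
#'
#' @param edges Edge tibble (key1, key2, pmids list-column).
#' @param predications Predication tibble from [read_predications()].
#' @param name_index Index from [build_name_index()].
#' @return A list with `attachments` (key1, key2, pmids, predicates,
#'   provenance — one row per edge with any evidence) and counters
#'   `n_matched`, `n_unmatched`.
#' @export
attach_evidence <- function(edges, predications, name_index) {
  pred <- predications
  pred$skey <- name_index$key[match(norm_name(pred$subject_name), name_index$term)]
  pred$okey <- name_index$key[match(norm_name(pred$object_name), name_index$term)]
  pred <- pred[!is.na(pred$skey) & !is.na(pred$okey) & pred$skey != pred$okey, ,
    drop = FALSE
  ]
  # orient the matched pair the same way edges are oriented (symmetric join)
  lo <- pmin(pred$skey, pred$okey)
  hi <- pmax(pred$skey, pred$okey)
  pred$pair <- paste(lo, hi, sep = "||")

  edge_lo <- pmin(edges$key1, edges$key2)
  edge_hi <- pmax(edges$key1, edges$key2)
  edge_pair <- paste(edge_lo, edge_hi, sep = "||")

  matched <- pred[pred$pair %in% edge_pair, , drop = FALSE]
  by_pair <- matched |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      match_pmids = list(sort(unique(.data$pmid))),
      predicates = list(sort(unique(.data$predicate))),
      .groups = "drop"
    )
  i <- match(edge_pair, by_pair$pair)
  hit <- !is.na(i)
  match_pmids <- rep(list(character(0)), nrow(edges))
  predicates <- rep(list(character(0)), nrow(edges))
  match_pmids[hit] <- by_pair$match_pmids[i[hit]]
  predicates[hit] <- by_pair$predicates[i[hit]]
  att <- tibble::tibble(
    key1 = edges$key1,
    key2 = edges$key2,
    source_pmids = edges$pmids,
    match_pmids = match_pmids,
    predicates = predicates
  )
  att$pmids <- Map(
    function(a, b) sort(unique(c(a, b))),
    att$source_pmids, att$match_pmids
  )
  has_source <- lengths(att$source_pmids) > 0
  has_match <- lengths(att$match_pmids) > 0
  att$provenance <- dplyr::case_when(
    has_source ~ "source_file",
    has_match ~ "predication_match",
    TRUE ~ NA_character_
  )
  out <- att[has_source | has_match, c("key1", "key2", "pmids", "predicates", "provenance")]
  list(
    attachments = out,
    n_matched = sum(has_match),
    n_unmatched = nrow(edges) - sum(has_source | has_match)
  )
}

#' Write evidence attachments to TSV
#'
#' @param attachments Attachment tibble from [attach_evidence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(attachments, path) {
  out <- attachments |>
    dplyr::mutate(
      pmids = join_multi(.data$pmids),
      predicates = join_multi(.data$predicates)
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
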