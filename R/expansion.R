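#' Collapse association rows into concept and edge tables
#'
#' Builds the undirected pair graph underlying the expansion: one concept
#' per identity key (see [concept_key()]), one edge per unordered pair.
#' Duplicate pairs are merged with their PMID lists and source sets
#' unioned; self-loops are dropped and counted. A name appearing with two
#' different concept types is an integration error, since concept identity
#' must be stable across resources.
#'
#' @param rows Association-row tibble (possibly from several sources,
#'   `dplyr::bind_rows()` them first).
#' @return A list with `concepts` (key, name, ctype, sources),
#'   `edges` (key1, key2, pair_type, sources, pmids) and `n_self_loops`.
#' @export
associations_from_rows <- function(rows) {
  if (nrow(rows) == 0) {
    return(list(
      concepts = tibble::tibble(
        key = character(0), name = character(0), ctype = character(0),
        sources = list()
      ),
      edges = empty_edge_table(),
      n_self_loops = 0L
    ))
  }
  mentions <- dplyr::bind_rows(
    tibble::tibble(
      name = rows$entity1_name, ctype = rows$entity1_type,
      source = rows$source
    ),
    tibble::tibble(
      name = rows$entity2_name, ctype = rows$entity2_type,
      source = rows$source
    )
  )
  mentions$norm <- norm_name(mentions$name)
  conflicts <- mentions |>
    dplyr::distinct(.data$norm, .data$ctype) |>
    dplyr::count(.data$norm) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    stop(
      "conflicting concept types for name(s): ",
      paste(head(conflicts$norm, 5), collapse = ", "),
      call. = FALSE
    )
  }
  mentions$key <- concept_key(mentions$ctype, mentions$name)
  concepts <- mentions |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      name = .data$name[1],
      ctype = .data$ctype[1],
      sources = list(sort(unique(.data$source))),
      .groups = "drop"
    )

  k1 <- concept_key(rows$entity1_type, rows$entity1_name)
  k2 <- concept_key(rows$entity2_type, rows$entity2_name)
  self <- k1 == k2
  n_self <- sum(self)
  rows <- rows[!self, , drop = FALSE]
  op <- orient_pair(rows$entity1_type, k1[!self], rows$entity2_type, k2[!self])
  edge_rows <- tibble::tibble(
    key1 = op$key1, key2 = op$key2, pair_type = op$pair_type,
    source = rows$source, pmids = rows$pmids
  )
  edges <- edge_rows |>
    dplyr::group_by(.data$key1, .data$key2, .data$pair_type) |>
    dplyr::summarise(
      sources = list(sort(unique(.data$source))),
      pmids = list(sort(unique(unlist(.data$pmids)))),
      .groups = "drop"
    )
  list(concepts = concepts, edges = edges, n_self_loops = n_self)
}

empty_edge_table <- function() {
  tibble::tibble(
    key1 = character(0), key2 = character(0), pair_type = character(0),
    sources = list(), pmids = list()
  )
}

#' Seed-based iterative association extraction
#'
#' Performs the degree-limited breadth-first expansion at the core of the
#' CPN construction: starting from the seed concepts, first-degree concepts
#' are the direct neighbours of a seed, second-degree concepts the
#' neighbours of first-degree concepts, and so on, stopping once
#' fourth-degree concepts have been reached (with the default
#' `max_degree = 4`). A concept's degree is its minimum edge distance from
#' any seed; each non-seed concept receives the weight score
#' `5 - degree` (degree 1 scores 4, degree 2 scores 3, degree 3 scores 2,
#' degree 4 scores 1), encoding the assumption that seed-proximal concepts
#' are more strongly cancer-associated. Seeds themselves sit at degree 0
#' with weight 5, continuing the same line.
#'
#' Seed terms are matched to concepts by normalised name, any type.
#' Seed terms with no matching concept in the association table are kept as
#' isolated disease-typed nodes at degree 0 (and reported with a warning),
#' so that a seed with no associations still appears in the result.
#'
#' @param rows Association-row tibble (e.g. from
#'   [read_pharmgkb_relationships()]).
#' @param seeds Character vector of seed terms.
#' @param max_degree Maximum degree retained (default 4).
#' @return A list with `concepts`, `edges` (both restricted to retained
#'   concepts), and `degrees`: a tibble (key, name, ctype, degree, weight).
#' @export
expand_from_seeds <- function(rows, seeds, max_degree = 4) {
  stopifnot(max_degree >= 1)
  if (length(seeds) == 0) stop("no seed terms supplied", call. = FALSE)
  net <- associations_from_rows(rows)
  concepts <- net$concepts
  seed_norm <- unique(norm_name(seeds))
  hit <- norm_name(concepts$name) %in% seed_norm
  unresolved <- setdiff(seed_norm, norm_name(concepts$name))
  if (length(unresolved) > 0) {
    warning(
      length(unresolved), " seed term(s) not found in the association table: ",
      paste(head(unresolved, 5), collapse = ", "),
      call. = FALSE
    )
    extra <- tibble::tibble(
      key = concept_key("disease", unresolved),
      name = unresolved,
      ctype = "disease",
      sources = rep(list(character(0)), length(unresolved))
    )
    concepts <- dplyr::bind_rows(concepts, extra)
    hit <- c(hit, rep(TRUE, length(unresolved)))
  }
  seed_keys <- concepts$key[hit]

  g <- igraph::graph_from_data_frame(
    net$edges[, c("key1", "key2")],
    directed = FALSE,
    vertices = concepts$key
  )
  d <- igraph::distances(g, v = seed_keys, mode = "all")
  min_dist <- if (length(seed_keys) == 0) {
    rep(Inf, nrow(concepts))
  } else {
    apply(d, 2, min)[concepts$key]
  }
  keep <- is.finite(min_dist) & min_dist <= max_degree
  degrees <- tibble::tibble(
    key = concepts$key[keep],
    name = concepts$name[keep],
    ctype = concepts$ctype[keep],
    degree = as.integer(min_dist[keep]),
    weight = 5L - as.integer(min_dist[keep])
  ) |>
    dplyr::arrange(.data$degree, .data$key)

  kept_keys <- degrees$key
  edges <- net$edges[
    net$edges$key1 %in% kept_keys & net$edges$key2 %in% kept_keys, ,
    drop = FALSE
  ]
  list(
    concepts = concepts[concepts$key %in% kept_keys, , drop = FALSE],
    edges = edges,
    degrees = degrees
  )
}

#' Restrict GWAS rows to associations co-occurring in PharmGKB
#'
#' The GWAS Catalog is not expanded iteratively; only its associations that
#' co-occur with the PharmGKB-derived concept set are retained. In mode
#' `"any"` (the default) a row is kept when at least one of its two
#' concepts is already known to the PharmGKB expansion; mode `"both"`
#' requires both endpoints.
#'
#' @param gwas_rows Association-row tibble from [read_gwas_catalog()].
#' @param pharmgkb_keys Character vector of concept keys retained by
#'   [expand_from_seeds()] on the PharmGKB source.
#' @param mode `"any"` or `"both"`.
#' @return The filtered association-row tibble.
#' @export
apply_gwas_cooccurrence_filter <- function(gwas_rows, pharmgkb_keys,
                                           mode = c("any", "both")) {
  mode <- match.arg(mode)
  if (nrow(gwas_rows) == 0) return(gwas_rows)
  in1 <- concept_key(gwas_rows$entity1_type, gwas_rows$entity1_name) %in%
    pharmgkb_keys
  in2 <- concept_key(gwas_rows$entity2_type, gwas_rows$entity2_name) %in%
    pharmgkb_keys
  keep <- if (mode == "any") in1 | in2 else in1 & in2
  out <- gwas_rows[keep, , drop = FALSE]
  set_drop_stats(out, nrow(gwas_rows), list(not_cooccurring = sum(!keep)))
}
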