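#' Read a known-indications table
#'
#' TSV with columns `drug` and `disease` (concept keys or plain names;
#' names are converted to keys). Emulates the "Indications & Usage" section
#' of structured product labels as a per-drug list.
#'
#' @param path Path to the TSV.
#' @return Tibble (drug, disease) of concept keys.
#' @export
read_known_indications <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("drug", "disease"), path)
  tibble::tibble(
    drug = ifelse(grepl(":", df$drug), df$drug, concept_key("drug", df$drug)),
    disease = ifelse(
      grepl(":", df$disease), df$disease, concept_key("disease", df$disease)
    )
  )
}

#' Read a VIP pair annotation file
#'
#' TSV with columns `key1`, `key2` flagging very-important-pharmacogene
#' associations; used as a path-ranking feature. An absent file simply
#' means no edge is VIP-flagged.
#'
#' @param path Path to the TSV.
#' @return Tibble (key1, key2).
#' @export
read_vip_pairs <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("key1", "key2"), path)
  df[, c("key1", "key2")]
}

# Score one simple path: total node weight (unweighted nodes count 0) and
# number of VIP-flagged edges along it.
score_path <- function(keys, node_weight, vip_pairs) {
  w <- node_weight[keys]
  w[is.na(w)] <- 0L
  pairs <- paste(
    pmin(keys[-length(keys)], keys[-1]),
    pmax(keys[-length(keys)], keys[-1])
  )
  list(weight_sum = sum(w), vip_count = sum(pairs %in% vip_pairs))
}

#' Infer candidate indications for a query drug
#'
#' Retrieves every disease node within `radius` edges of the query drug as
#' a repurposing candidate — the network-analysis reading of "disease
#' nodes at most 3 nodes away" used in the case studies, where e.g.
#' drug-gene-disease is a length-2 path. For each candidate all simple
#' paths of length up to `radius` from the drug to the disease are
#' enumerated (shortest first, capped at `max_paths_per_disease`).
#' Candidates are ranked by the ordered tuple (shortest-path length
#' ascending, its node-weight sum descending, its VIP-edge count
#' descending, disease key ascending) and flagged as novel when the
#' disease is absent from the drug's known-indication list.
#'
#' @param graph A `cpn` object.
#' @param drug Concept key of the query drug (must have type `drug`).
#' @param radius Maximum edge distance searched (default 3).
#' @param known Tibble (drug, disease) of known indications, or a character
#'   vector of disease keys known for this drug.
#' @param max_paths_per_disease Cap on enumerated paths per candidate.
#' @return Tibble (drug, disease, disease_name, distance, n_paths,
#'   shortest_path, weight_sum, vip_count, novel), ranked; the full path
#'   node lists are in the `paths` attribute.
#' @export
infer_indications <- function(graph, drug, radius = 3, known = character(0),
                              max_paths_per_disease = 100) {
  stopifnot(radius >= 1)
  check_center(graph, drug)
  ctype <- graph$nodes$ctype[match(drug, graph$nodes$key)]
  if (ctype != "drug") {
    stop("query concept is not a drug: ", drug, " (type ", ctype, ")",
      call. = FALSE
    )
  }
  known_diseases <- if (is.data.frame(known)) {
    known$disease[known$drug == drug]
  } else {
    known
  }

  ig <- as_igraph_cpn(graph)
  d <- igraph::distances(ig, v = drug)[1, ]
  disease_keys <- graph$nodes$key[graph$nodes$ctype == "disease"]
  targets <- names(d)[is.finite(d) & d >= 1 & d <= radius &
    names(d) %in% disease_keys]
  if (length(targets) == 0) {
    out <- tibble::tibble(
      drug = character(0), disease = character(0),
      disease_name = character(0), distance = integer(0),
      n_paths = integer(0), shortest_path = character(0),
      weight_sum = integer(0), vip_count = integer(0), novel = logical(0)
    )
    attr(out, "paths") <- list()
    return(out)
  }

  node_weight <- stats::setNames(graph$nodes$weight, graph$nodes$key)
  vip_edges <- graph$edges[graph$edges$vip, , drop = FALSE]
  vip_pairs <- paste(
    pmin(vip_edges$key1, vip_edges$key2),
    pmax(vip_edges$key1, vip_edges$key2)
  )

  all_paths <- igraph::all_simple_paths(ig, from = drug, to = targets,
    cutoff = radius
  )
  path_keys <- lapply(all_paths, function(p) igraph::V(ig)$name[p])
  end_key <- vapply(path_keys, function(k) k[length(k)], character(1))

  rows <- lapply(targets, function(dk) {
    paths <- path_keys[end_key == dk]
    lens <- lengths(paths) - 1L
    scores <- lapply(paths, score_path, node_weight = node_weight,
      vip_pairs = vip_pairs
    )
    ws <- vapply(scores, `[[`, numeric(1), "weight_sum")
    vc <- vapply(scores, `[[`, numeric(1), "vip_count")
    ord <- order(lens, -ws, -vc,
      vapply(paths, paste, character(1), collapse = ">")
    )
    keep <- head(ord, max_paths_per_disease)
    best <- keep[1]
    tibble::tibble(
      drug = drug,
      disease = dk,
      disease_name = graph$nodes$name[match(dk, graph$nodes$key)],
      distance = as.integer(d[dk]),
      n_paths = length(paths),
      shortest_path = paste(paths[[best]], collapse = ">"),
      weight_sum = as.integer(ws[best]),
      vip_count = as.integer(vc[best]),
      novel = !(dk %in% known_diseases),
      kept_paths = list(paths[keep])
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(
      .data$distance, dplyr::desc(.data$weight_sum),
      dplyr::desc(.data$vip_count), .data$disease
    )
  paths <- out$kept_paths
  names(paths) <- out$disease
  out$kept_paths <- NULL
  attr(out, "paths") <- paths
  out
}

#' Neighbourhood degree profile of a concept
#'
#' Counts distinct concepts (and the disease subset) at each exact edge
#' distance from a center node, as used to describe a query drug's
#' neighbourhood (e.g. how many concepts are one, two and three nodes
#' away).
#'
#' @param graph A `cpn` object.
#' @param center Concept key.
#' @param max_distance Largest distance reported.
#' @return Tibble (distance, n_concepts, n_diseases).
#' @export
degree_profile <- function(graph, center, max_distance) {
  check_center(graph, center)
  ig <- as_igraph_cpn(graph)
  d <- igraph::distances(ig, v = center)[1, ]
  disease_keys <- graph$nodes$key[graph$nodes$ctype == "disease"]
  tibble::tibble(distance = seq_len(max_distance)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_concepts = sum(d == .data$distance, na.rm = TRUE),
      n_diseases = sum(d == .data$distance & names(d) %in% disease_keys,
        na.rm = TRUE
      )
    ) |>
    dplyr::ungroup()
}

#' Write repurposing candidates to TSV
#'
#' @param candidates Tibble from [infer_indications()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(candidates, path, progress = FALSE)
  invisible(path)
}
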