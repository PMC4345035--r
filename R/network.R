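#' Allowed pair types per source resource
#'
#' The CPN admits a fixed matrix of association types per source: the
#' PharmGKB relationships file contributes drug, disease, gene, variant and
#' haplotype pairs; the GWAS Catalog contributes disease-variant,
#' disease-gene and gene-variant pairs; the FDA biomarker table contributes
#' drug-gene pairs only. Pair-type labels are oriented by the canonical
#' type order (drug, disease, gene, variant, haplotype).
#'
#' @return Named list `source -> character vector of allowed pair types`.
#' @export
pair_type_matrix <- function() {
  list(
    pharmgkb = c(
      "drug-disease", "drug-gene", "drug-variant", "drug-haplotype",
      "drug-drug", "disease-gene", "disease-variant", "disease-haplotype",
      "gene-gene", "gene-variant"
    ),
    gwas = c("disease-gene", "disease-variant", "gene-variant"),
    fda = c("drug-gene")
  )
}

#' Assemble the cancer pharmacogenomics network
#'
#' Merges the expanded PharmGKB association graph with the filtered GWAS
#' rows and the FDA biomarker rows into one heterogeneous network. Nodes
#' are merged across resources by concept key (source sets unioned) and
#' carry their degree/weight from the seed expansion plus, when available,
#' their normalized vocabulary code; edges are merged by unordered pair and
#' carry sources, PMIDs and predicates. Every edge is validated against
#' the pair-type matrix for each contributing source; in `"strict"` mode a
#' violation is an error, in `"permissive"` mode a warning.
#'
#' @param expansion Result of [expand_from_seeds()] on the PharmGKB rows.
#' @param gwas_rows Filtered GWAS association rows (may be `NULL`).
#' @param fda_rows FDA association rows (may be `NULL`).
#' @param norms Optional normalization tibble from [normalize_concepts()].
#' @param evidence Optional attachment tibble from [attach_evidence()].
#' @param vip Optional tibble (key1, key2) of VIP pairs; matching edges are
#'   flagged `vip = TRUE`.
#' @param type_matrix Pair-type matrix (see [pair_type_matrix()]).
#' @param validation `"strict"` or `"permissive"`.
#' @return An object of class `cpn`: a list with `nodes` and `edges`
#'   tibbles.
#' @export
build_cpn <- function(expansion, gwas_rows = NULL, fda_rows = NULL,
                      norms = NULL, evidence = NULL, vip = NULL,
                      type_matrix = pair_type_matrix(),
                      validation = c("strict", "permissive")) {
  validation <- match.arg(validation)
  extra_rows <- dplyr::bind_rows(gwas_rows, fda_rows)
  if (nrow(extra_rows) > 0) {
    extra <- associations_from_rows(extra_rows)
    nodes <- dplyr::bind_rows(
      expansion$concepts,
      dplyr::anti_join(extra$concepts, expansion$concepts, by = "key")
    )
    # union source sets for concepts present on both sides
    shared <- dplyr::inner_join(
      extra$concepts[, c("key", "sources")],
      expansion$concepts[, "key"],
      by = "key"
    )
    i <- match(shared$key, nodes$key)
    nodes$sources[i] <- Map(
      function(a, b) sort(unique(c(a, b))),
      nodes$sources[i], shared$sources
    )
    edges <- dplyr::bind_rows(expansion$edges, extra$edges) |>
      dplyr::group_by(.data$key1, .data$key2, .data$pair_type) |>
      dplyr::summarise(
        sources = list(sort(unique(unlist(.data$sources)))),
        pmids = list(sort(unique(unlist(.data$pmids)))),
        .groups = "drop"
      )
  } else {
    nodes <- expansion$concepts
    edges <- expansion$edges
  }

  i <- match(nodes$key, expansion$degrees$key)
  nodes$degree <- expansion$degrees$degree[i]
  nodes$weight <- expansion$degrees$weight[i]

  if (!is.null(norms)) {
    j <- match(nodes$key, norms$key)
    nodes$vocabulary <- norms$vocabulary[j]
    nodes$code <- norms$code[j]
    nodes$method <- norms$method[j]
  } else {
    nodes$vocabulary <- NA_character_
    nodes$code <- NA_character_
    nodes$method <- NA_character_
  }

  edges$predicates <- rep(list(character(0)), nrow(edges))
  edges$provenance <- ifelse(lengths(edges$pmids) > 0, "source_file", NA_character_)
  if (!is.null(evidence) && nrow(evidence) > 0) {
    epair <- paste(pmin(edges$key1, edges$key2), pmax(edges$key1, edges$key2))
    apair <- paste(pmin(evidence$key1, evidence$key2), pmax(evidence$key1, evidence$key2))
    k <- match(epair, apair)
    hit <- !is.na(k)
    edges$pmids[hit] <- evidence$pmids[k[hit]]
    edges$predicates[hit] <- evidence$predicates[k[hit]]
    edges$provenance[hit] <- evidence$provenance[k[hit]]
  }

  edges$vip <- FALSE
  if (!is.null(vip) && nrow(vip) > 0) {
    epair <- paste(pmin(edges$key1, edges$key2), pmax(edges$key1, edges$key2))
    vpair <- paste(pmin(vip$key1, vip$key2), pmax(vip$key1, vip$key2))
    edges$vip <- epair %in% vpair
  }

  # pair-type validation against the per-source matrix
  for (i in seq_len(nrow(edges))) {
    for (s in edges$sources[[i]]) {
      allowed <- type_matrix[[s]]
      if (!is.null(allowed) && !(edges$pair_type[i] %in% allowed)) {
        msg <- paste0(
          "pair type ", edges$pair_type[i], " is not allowed for source ", s,
          " (", edges$key1[i], " -- ", edges$key2[i], ")"
        )
        if (validation == "strict") stop(msg, call. = FALSE) else
          warning(msg, call. = FALSE)
      }
    }
  }

  graph <- structure(list(nodes = nodes, edges = edges), class = "cpn")
  stopifnot(all(edges$key1 %in% nodes$key), all(edges$key2 %in% nodes$key))
  graph
}

#' @export
print.cpn <- function(x, ...) {
  cat("Cancer PGx network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tb <- table(x$nodes$ctype)
  cat("  nodes by type:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  te <- table(x$edges$pair_type)
  cat("  edges by pair type:", paste(names(te), te, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Summary statistics of a CPN
#'
#' @param graph A `cpn` object.
#' @return A list with scalar `n_nodes`/`n_edges` and tibbles
#'   `nodes_by_ctype`, `edges_by_pair_type`. The pair-type counts partition
#'   the edge set.
#' @export
cpn_stats <- function(graph) {
  list(
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    nodes_by_ctype = dplyr::count(graph$nodes, .data$ctype, name = "n"),
    edges_by_pair_type = dplyr::count(graph$edges, .data$pair_type, name = "n")
  )
}

#' Convert a CPN to an igraph object
#'
#' All node and edge attributes are carried over; list columns (sources,
#' pmids, predicates) are flattened to `;`-joined strings so the result is
#' serialisable.
#'
#' @param graph A `cpn` object.
#' @return An undirected `igraph` graph.
#' @export
as_igraph_cpn <- function(graph) {
  blank_na <- function(x) ifelse(is.na(x), "", x)
  # the display name must not collide with igraph's vertex "name" (the key)
  nodes <- graph$nodes |>
    dplyr::rename(label = "name") |>
    dplyr::mutate(
      sources = join_multi(.data$sources),
      dplyr::across(dplyr::where(is.character), blank_na),
      degree = ifelse(is.na(.data$degree), -1L, .data$degree),
      weight = ifelse(is.na(.data$weight), -1L, .data$weight)
    ) |>
    dplyr::select("key", dplyr::everything())
  edges <- graph$edges |>
    dplyr::mutate(
      sources = join_multi(.data$sources),
      pmids = join_multi(.data$pmids),
      predicates = join_multi(.data$predicates),
      dplyr::across(dplyr::where(is.character), blank_na)
    )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Rebuild a CPN from an igraph object
#'
#' Inverse of [as_igraph_cpn()] up to row order.
#'
#' @param ig An igraph graph produced by [as_igraph_cpn()] or read back
#'   from a GraphML export.
#' @return A `cpn` object.
#' @export
cpn_from_igraph <- function(ig) {
  na_blank <- function(x) ifelse(!nzchar(x), NA_character_, x)
  nodes <- igraph::as_data_frame(ig, what = "vertices") |>
    tibble::as_tibble() |>
    dplyr::select(-dplyr::any_of("id")) |>  # GraphML vertex ids are synthetic
    dplyr::rename(key = "name", name = "label") |>
    dplyr::mutate(sources = split_multi_col(.data$sources)) |>
    dplyr::mutate(
      dplyr::across(dplyr::where(is.character), na_blank),
      degree = ifelse(.data$degree < 0, NA_integer_, as.integer(.data$degree)),
      weight = ifelse(.data$weight < 0, NA_integer_, as.integer(.data$weight))
    )
  edges <- igraph::as_data_frame(ig, what = "edges") |>
    tibble::as_tibble() |>
    dplyr::rename(key1 = "from", key2 = "to") |>
    dplyr::mutate(
      sources = split_multi_col(.data$sources),
      pmids = split_multi_col(.data$pmids),
      predicates = split_multi_col(.data$predicates)
    ) |>
    dplyr::mutate(
      dplyr::across(dplyr::where(is.character), na_blank),
      vip = as.logical(.data$vip)
    )
  op <- orient_pair(
    sub(":.*", "", edges$key1), edges$key1,
    sub(":.*", "", edges$key2), edges$key2
  )
  edges$key1 <- op$key1
  edges$key2 <- op$key2
  structure(list(nodes = nodes, edges = edges), class = "cpn")
}

#' Export a CPN for visualization
#'
#' Writes the network as GraphML (attribute-preserving canonical format;
#' re-import yields an identical attributed graph), SIF (one
#' `key1 pair_type key2` line per edge, for Cytoscape), or a pair of
#' node/edge attribute TSVs (`<path>.nodes.tsv`, `<path>.edges.tsv`).
#'
#' @param graph A `cpn` object.
#' @param path Output path (for `tsv`, the common prefix).
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return The path(s) written, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph_cpn(graph)
    # igraph stores NA strings as the literal "NA" on write; make it explicit
    igraph::write_graph(ig, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "sif") {
    lines <- paste(graph$edges$key1, graph$edges$pair_type, graph$edges$key2)
    readr::write_lines(lines, path)
    return(invisible(path))
  }
  node_path <- paste0(path, ".nodes.tsv")
  edge_path <- paste0(path, ".edges.tsv")
  graph$nodes |>
    dplyr::mutate(sources = join_multi(.data$sources)) |>
    readr::write_tsv(node_path, progress = FALSE)
  graph$edges |>
    dplyr::mutate(
      sources = join_multi(.data$sources),
      pmids = join_multi(.data$pmids),
      predicates = join_multi(.data$predicates)
    ) |>
    readr::write_tsv(edge_path, progress = FALSE)
  invisible(c(node_path, edge_path))
}

#' Import a CPN from a GraphML export
#'
#' @param path Path written by [export_graph()] with `format = "graphml"`.
#' @return A `cpn` object.
#' @export
import_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  cpn_from_igraph(ig)
}

#' Extract the neighbourhood subnetwork around a concept
#'
#' Induced subgraph on all nodes within `radius` edges of `center`, as used
#' to extract per-seed or per-drug subnetworks for display.
#'
#' @param graph A `cpn` object.
#' @param center Concept key of the center node.
#' @param radius Non-negative integer edge radius.
#' @return A `cpn` object restricted to the neighbourhood.
#' @export
subnetwork <- function(graph, center, radius) {
  stopifnot(radius >= 0)
  check_center(graph, center)
  ig <- as_igraph_cpn(graph)
  d <- igraph::distances(ig, v = center)[1, ]
  keep <- names(d)[is.finite(d) & d <= radius]
  nodes <- graph$nodes[graph$nodes$key %in% keep, , drop = FALSE]
  edges <- graph$edges[
    graph$edges$key1 %in% keep & graph$edges$key2 %in% keep, ,
    drop = FALSE
  ]
  structure(list(nodes = nodes, edges = edges), class = "cpn")
}

# Error on an unknown center key, listing near-miss names for the user.
check_center <- function(graph, center) {
  if (center %in% graph$nodes$key) return(invisible(TRUE))
  frag <- sub("^[a-z]+:", "", center)
  near <- graph$nodes$key[grepl(frag, graph$nodes$key, fixed = TRUE)]
  stop(
    "concept not found in network: ", center,
    if (length(near) > 0) {
      paste0("; did you mean: ", paste(head(near, 5), collapse = ", "), "?")
    },
    call. = FALSE
  )
}
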