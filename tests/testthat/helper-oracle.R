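# Brute-force multi-source shortest-path oracle, independent of the
# package's igraph-based expansion: Bellman-Ford relaxation over the edge
# list until a fixed point.
oracle_distances <- function(n_nodes, edges, sources) {
  dist <- rep(Inf, n_nodes)
  dist[sources] <- 0
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      i <- edges$from[e]
      j <- edges$to[e]
      if (dist[i] + 1 < dist[j]) {
        dist[j] <- dist[i] + 1
        changed <- TRUE
      }
      if (dist[j] + 1 < dist[i]) {
        dist[i] <- dist[j] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

# Random undirected association table over n nodes with typed names drawn
# from disjoint per-type alphabets. Node 1 is always a disease so it can
# serve as the seed.
random_graph_rows <- function(n_nodes, n_edges) {
  ctypes <- c("disease", sample(
    c("drug", "disease", "gene", "variant", "haplotype"),
    n_nodes - 1,
    replace = TRUE
  ))
  names <- paste0(ctypes, "_node_", seq_len(n_nodes))
  from <- sample(n_nodes, n_edges, replace = TRUE)
  to <- sample(n_nodes, n_edges, replace = TRUE)
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  rows <- tibble::tibble(
    entity1_id = names[from], entity1_name = names[from],
    entity1_type = ctypes[from],
    entity2_id = names[to], entity2_name = names[to],
    entity2_type = ctypes[to],
    pmids = rep(list(character(0)), length(from)),
    source = "pharmgkb"
  )
  list(
    rows = rows, n_nodes = n_nodes, names = names, ctypes = ctypes,
    edges = tibble::tibble(from = from, to = to)
  )
}

# Compare package expansion degrees with the oracle on one random graph.
expect_degrees_match_oracle <- function(g, max_degree = g$n_nodes) {
  if (nrow(g$rows) == 0) return(invisible(TRUE))
  ex <- suppressWarnings(
    expand_from_seeds(g$rows, g$names[1], max_degree = max_degree)
  )
  dist <- oracle_distances(g$n_nodes, g$edges, sources = 1)
  expected <- tibble::tibble(
    key = concept_key(g$ctypes, g$names),
    degree = dist
  )
  expected <- expected[is.finite(expected$degree) &
    expected$degree <= max_degree, ]
  got <- ex$degrees[match(expected$key, ex$degrees$key), ]
  expect_equal(nrow(ex$degrees), nrow(expected))
  expect_equal(got$degree, as.integer(expected$degree))
}

# Association-row tibble from a compact pair spec: list of
# c(name1, type1, name2, type2[, pmids]).
rows_from_pairs <- function(pairs, source = "pharmgkb") {
  dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(
      entity1_id = p[1], entity1_name = p[1], entity1_type = p[2],
      entity2_id = p[3], entity2_name = p[3], entity2_type = p[4],
      pmids = list(if (length(p) > 4) p[5:length(p)] else character(0)),
      source = source
    )
  }))
}

# Build a small CPN straight from pair specs (expansion + assembly).
make_cpn <- function(pairs, seeds, max_degree = 4, ...) {
  rows <- rows_from_pairs(pairs)
  ex <- suppressWarnings(expand_from_seeds(rows, seeds, max_degree = max_degree))
  build_cpn(ex, ...)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
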