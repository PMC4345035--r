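small_cpn <- function() {
  pairs <- list(
    c("SeedD", "disease", "rs1", "variant", "10"),
    c("rs1", "variant", "GENE1", "gene", "11"),
    c("GENE1", "gene", "DrugA", "drug", "12"),
    c("DrugA", "drug", "GENE2", "gene"),
    c("GENE2", "gene", "DiseaseB", "disease")
  )
  make_cpn(pairs, "SeedD")
}

test_that("concepts merge across resources by key with sources unioned", {
  rows <- rows_from_pairs(list(c("SeedD", "disease", "GENE1", "gene")))
  ex <- expand_from_seeds(rows, "SeedD")
  gwas <- rows_from_pairs(
    list(c("SeedD", "disease", "GENE1", "gene")),
    source = "gwas"
  )
  fda <- rows_from_pairs(
    list(c("DrugA", "drug", "GENE1", "gene")),
    source = "fda"
  )
  graph <- build_cpn(ex, gwas_rows = gwas, fda_rows = fda)
  expect_equal(nrow(graph$nodes), 3)
  gene <- graph$nodes[graph$nodes$key == "gene:gene1", ]
  expect_setequal(gene$sources[[1]], c("pharmgkb", "gwas", "fda"))
  edge <- graph$edges[graph$edges$pair_type == "disease-gene", ]
  expect_setequal(edge$sources[[1]], c("pharmgkb", "gwas"))
  # the FDA drug is outside the seed expansion, so it carries no degree
  expect_true(is.na(graph$nodes$degree[graph$nodes$key == "drug:druga"]))
})

test_that("pair types outside a source's allowed matrix are rejected", {
  rows <- rows_from_pairs(list(c("SeedD", "disease", "DrugA", "drug")))
  ex <- expand_from_seeds(rows, "SeedD")
  fda_bad <- rows_from_pairs(
    list(c("DrugA", "drug", "DrugB", "drug")),
    source = "fda"
  )
  expect_error(
    build_cpn(ex, fda_rows = fda_bad, validation = "strict"),
    "not allowed for source fda"
  )
  expect_warning(
    graph <- build_cpn(ex, fda_rows = fda_bad, validation = "permissive"),
    "not allowed for source fda"
  )
  expect_equal(nrow(graph$edges), 2)
})

test_that("stats partition nodes and edges", {
  graph <- small_cpn()
  # DiseaseB sits at degree 5 and is dropped by the default depth cap
  st <- cpn_stats(graph)
  expect_equal(st$n_nodes, 5)
  expect_equal(st$n_edges, 4)
  expect_equal(sum(st$nodes_by_ctype$n), st$n_nodes)
  expect_equal(sum(st$edges_by_pair_type$n), st$n_edges)
})

test_that("SIF export writes one line per edge", {
  graph <- small_cpn()
  path <- tempfile(fileext = ".sif")
  export_graph(graph, path, format = "sif")
  lines <- readLines(path)
  expect_equal(length(lines), nrow(graph$edges))
  expect_true(any(grepl("^disease:seedd disease-variant variant:rs1$", lines)))
})

test_that("GraphML round trip preserves nodes, edges and attributes", {
  pairs <- list(
    c("SeedD", "disease", "GENE1", "gene", "10"),
    c("GENE1", "gene", "DrugA", "drug", "11", "12")
  )
  rows <- rows_from_pairs(pairs)
  ex <- expand_from_seeds(rows, "SeedD")
  norms <- normalize_concepts(
    ex$concepts,
    resolver = lexicon_resolver(read_lexicon(default_lexicon_path()))
  )
  vip <- tibble::tibble(key1 = "gene:gene1", key2 = "drug:druga")
  graph <- build_cpn(ex, norms = norms, vip = vip)
  path <- tempfile(fileext = ".graphml")
  export_graph(graph, path, format = "graphml")
  back <- import_graphml(path)
  ord <- function(x) dplyr::arrange(x, key)
  orde <- function(x) dplyr::arrange(x, key1, key2)
  expect_equal(ord(back$nodes), ord(graph$nodes), ignore_attr = TRUE)
  expect_equal(
    orde(back$edges)[names(graph$edges)], orde(graph$edges),
    ignore_attr = TRUE
  )
})

test_that("TSV export carries node and edge attribute tables", {
  graph <- small_cpn()
  prefix <- tempfile()
  paths <- export_graph(graph, prefix, format = "tsv")
  nodes <- readr::read_tsv(paths[1], show_col_types = FALSE)
  edges <- readr::read_tsv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(nodes), nrow(graph$nodes))
  expect_equal(nrow(edges), nrow(graph$edges))
  expect_true(all(c("key", "name", "ctype", "degree", "weight") %in% names(nodes)))
  expect_true(all(c("key1", "key2", "pair_type", "pmids") %in% names(edges)))
})

test_that("subnetwork extraction obeys its radius", {
  graph <- small_cpn()
  sub0 <- subnetwork(graph, "drug:druga", 0)
  expect_equal(sub0$nodes$key, "drug:druga")
  expect_equal(nrow(sub0$edges), 0)
  sub1 <- subnetwork(graph, "drug:druga", 1)
  expect_setequal(sub1$nodes$key, c("drug:druga", "gene:gene1", "gene:gene2"))
  expect_equal(nrow(sub1$edges), 2)
  # radius 2 equals a brute-force distance filter
  set.seed(11)
  g <- random_graph_rows(20, 30)
  ex <- suppressWarnings(expand_from_seeds(g$rows, g$names[1], max_degree = 20))
  # random typed graphs contain pair types outside the source matrix
  graph2 <- build_cpn(ex, type_matrix = list())
  center <- graph2$nodes$key[1]
  sub2 <- subnetwork(graph2, center, 2)
  keys <- concept_key(g$ctypes, g$names)
  ci <- match(center, keys)
  dist_c <- oracle_distances(g$n_nodes, g$edges, sources = ci)
  expected <- intersect(keys[dist_c <= 2], graph2$nodes$key)
  expect_setequal(sub2$nodes$key, expected)
})

test_that("unknown center names raise a lookup error with near misses", {
  graph <- small_cpn()
  expect_error(subnetwork(graph, "drug:drug", 1), "did you mean")
})
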