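case_study_cpn <- function() {
  # emulates the two published inference examples: Capecitabine two hops
  # from bladder neoplasms via CYP1A1, Paclitaxel two hops from Alzheimer
  # disease via both MTHFR and rs1801133
  pairs <- list(
    c("Urinary Bladder Neoplasms", "disease", "CYP1A1", "gene"),
    c("CYP1A1", "gene", "Capecitabine", "drug"),
    c("Urinary Bladder Neoplasms", "disease", "MTHFR", "gene"),
    c("Paclitaxel", "drug", "MTHFR", "gene"),
    c("Paclitaxel", "drug", "rs1801133", "variant"),
    c("MTHFR", "gene", "Alzheimer Disease", "disease"),
    c("rs1801133", "variant", "Alzheimer Disease", "disease")
  )
  make_cpn(pairs, "Urinary Bladder Neoplasms")
}

test_that("shortest repurposing path is drug-gene-disease in the worked case", {
  graph <- case_study_cpn()
  cand <- infer_indications(graph, "drug:capecitabine", radius = 3)
  ubn <- cand[cand$disease == "disease:urinary bladder neoplasms", ]
  expect_equal(nrow(ubn), 1)
  expect_equal(ubn$distance, 2L)
  expect_equal(
    ubn$shortest_path,
    "drug:capecitabine>gene:cyp1a1>disease:urinary bladder neoplasms"
  )
})

test_that("diseases reachable through both a gene and a variant are found once", {
  graph <- case_study_cpn()
  known <- tibble::tibble(
    drug = "drug:paclitaxel",
    disease = "disease:urinary bladder neoplasms"
  )
  cand <- infer_indications(graph, "drug:paclitaxel", radius = 3, known = known)
  alz <- cand[cand$disease == "disease:alzheimer disease", ]
  expect_equal(nrow(alz), 1)
  expect_equal(alz$distance, 2L)
  expect_gte(alz$n_paths, 2)
  expect_true(alz$novel)
  ubn <- cand[cand$disease == "disease:urinary bladder neoplasms", ]
  expect_false(ubn$novel)
})

test_that("indication inference never returns diseases beyond the radius", {
  # one branch chain per distance 1..5
  pairs <- list(c("DrugQ", "drug", "Disease_d1", "disease"))
  for (d in 2:5) {
    chain <- c(
      list(c("DrugQ", "drug", sprintf("GENEQ%d1", d), "gene")),
      lapply(seq_len(d - 2), function(i) {
        c(sprintf("GENEQ%d%d", d, i), "gene", sprintf("GENEQ%d%d", d, i + 1), "gene")
      }),
      list(c(
        sprintf("GENEQ%d%d", d, d - 1), "gene",
        sprintf("Disease_d%d", d), "disease"
      ))
    )
    pairs <- c(pairs, chain)
  }
  rows <- rows_from_pairs(pairs)
  ex <- suppressWarnings(expand_from_seeds(rows, "Disease_d1", max_degree = 10))
  graph <- build_cpn(ex)
  cand <- infer_indications(graph, "drug:drugq", radius = 3)
  expect_equal(max(cand$distance), 3L)
  expect_setequal(
    cand$disease,
    paste0("disease:disease_d", 1:3)
  )
  # completeness at a larger radius
  cand5 <- infer_indications(graph, "drug:drugq", radius = 5)
  expect_setequal(cand5$disease, paste0("disease:disease_d", 1:5))
})

test_that("returned diseases match a brute-force distance oracle", {
  set.seed(5)
  for (rep in 1:10) {
    g <- random_graph_rows(30, 45)
    ex <- suppressWarnings(expand_from_seeds(g$rows, g$names[1], max_degree = 30))
    graph <- build_cpn(ex, type_matrix = list())
    drugs <- graph$nodes$key[graph$nodes$ctype == "drug"]
    if (length(drugs) == 0) next
    drug <- drugs[1]
    ci <- match(drug, concept_key(g$ctypes, g$names))
    dist <- oracle_distances(g$n_nodes, g$edges, sources = ci)
    keys <- concept_key(g$ctypes, g$names)
    expected <- keys[g$ctypes == "disease" & dist >= 1 & dist <= 3]
    expected <- intersect(expected, graph$nodes$key)
    cand <- infer_indications(graph, drug, radius = 3)
    expect_setequal(cand$disease, expected)
    expect_equal(
      cand$distance,
      as.integer(dist[match(cand$disease, keys)])
    )
  }
})

test_that("ranking is deterministic and ordered by the rank tuple", {
  graph <- case_study_cpn()
  c1 <- infer_indications(graph, "drug:paclitaxel", radius = 3)
  c2 <- infer_indications(graph, "drug:paclitaxel", radius = 3)
  expect_identical(c1, c2)
  expect_true(all(diff(c1$distance) >= 0))
  same_d <- split(c1, c1$distance)
  for (blk in same_d) {
    expect_true(all(diff(blk$weight_sum) <= 0 |
      diff(as.integer(factor(blk$disease))) > 0))
  }
})

test_that("VIP-flagged edges raise a path's vip count", {
  pairs <- list(
    c("SeedD", "disease", "GENE1", "gene"),
    c("GENE1", "gene", "DrugA", "drug")
  )
  vip <- tibble::tibble(key1 = "gene:gene1", key2 = "drug:druga")
  graph <- make_cpn(pairs, "SeedD", vip = vip)
  cand <- infer_indications(graph, "drug:druga", radius = 2)
  expect_equal(cand$vip_count, 1L)
})

test_that("degree profile counts concepts and diseases at exact distances", {
  # star with 4 leaves
  pairs <- lapply(1:4, function(i) {
    c("DrugHub", "drug", sprintf("Disease_leaf%d", i), "disease")
  })
  rows <- rows_from_pairs(pairs)
  ex <- expand_from_seeds(rows, "Disease_leaf1")
  graph <- build_cpn(ex)
  prof <- degree_profile(graph, "drug:drughub", max_distance = 2)
  expect_equal(prof$n_concepts[prof$distance == 1], 4)
  expect_equal(prof$n_diseases[prof$distance == 1], 4)
  expect_equal(prof$n_concepts[prof$distance == 2], 0)

  # layered chain: counts at each distance are the planted layer sizes and
  # sum to the reachable nodes minus the center
  graph2 <- case_study_cpn()
  prof2 <- degree_profile(graph2, "drug:paclitaxel", max_distance = 6)
  expect_equal(sum(prof2$n_concepts), nrow(graph2$nodes) - 1)
})

test_that("querying a non-drug concept is a usage error", {
  graph <- case_study_cpn()
  expect_error(
    infer_indications(graph, "gene:cyp1a1"),
    "not a drug"
  )
  expect_error(
    infer_indications(graph, "drug:nosuchdrug"),
    "not found"
  )
})
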