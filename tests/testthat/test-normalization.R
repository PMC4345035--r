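concepts_fixture <- function(names, ctypes) {
  tibble::tibble(
    key = concept_key(ctypes, names), name = names, ctype = ctypes
  )
}

test_that("tier precedence is source_provided > resolver_exact > manual", {
  concepts <- concepts_fixture(
    c("DrugTierOne", "DrugTierTwo", "DrugTierThree", "DrugNowhere"),
    rep("drug", 4)
  )
  entities <- tibble::tibble(
    source_id = "PA1", name = "DrugTierOne", ctype = "drug",
    vocabulary = "RxNorm", code = "101"
  )
  lexicon <- tibble::tibble(
    vocabulary = "RxNorm",
    code = c("999", "202"),
    preferred_name = c("DrugTierOne", "DrugTierTwo"),
    synonyms = c("", "")
  )
  overrides <- list(RxNorm = c(
    "drugtierone" = "888", "drugtiertwo" = "777", "drugtierthree" = "303"
  ))
  norms <- normalize_concepts(
    concepts, entities, lexicon_resolver(lexicon), overrides
  )
  get <- function(nm, col) norms[[col]][norms$name == nm]
  # tier 1 wins even though the resolver and overrides also know the name
  expect_equal(get("DrugTierOne", "method"), "source_provided")
  expect_equal(get("DrugTierOne", "code"), "101")
  expect_equal(get("DrugTierTwo", "method"), "resolver_exact")
  expect_equal(get("DrugTierTwo", "code"), "202")
  expect_equal(get("DrugTierThree", "method"), "manual")
  expect_equal(get("DrugTierThree", "code"), "303")
  expect_equal(get("DrugNowhere", "method"), "unmapped")
  expect_true(is.na(get("DrugNowhere", "code")))
})

test_that("packaged lexicon resolves published codes stably", {
  resolver <- lexicon_resolver(read_lexicon(default_lexicon_path()))
  expect_equal(resolver("Paclitaxel", "RxNorm"), "56946")
  expect_equal(resolver("paclitaxel", "RxNorm"), "56946")
  expect_equal(resolver("TAXOL", "RxNorm"), "56946")
  expect_equal(resolver("Alzheimer  Disease", "SNOMED-CT"), "26929004")
  expect_equal(resolver("Capecitabine", "RxNorm"), "194000")
  expect_true(is.na(resolver("Paclitaxel", "SNOMED-CT")))
  expect_true(is.na(resolver("not a drug", "RxNorm")))
})

test_that("genes and variants pass through with symbols and rsIDs as codes", {
  concepts <- concepts_fixture(
    c("cyp1a2", "rs1801133", "HAP*2"),
    c("gene", "variant", "haplotype")
  )
  norms <- normalize_concepts(concepts)
  expect_equal(norms$code[norms$ctype == "gene"], "CYP1A2")
  expect_equal(norms$vocabulary[norms$ctype == "gene"], "HGNC")
  expect_equal(norms$code[norms$ctype == "variant"], "rs1801133")
  expect_equal(norms$vocabulary[norms$ctype == "variant"], "dbSNP")
  expect_true(all(norms$method == "source_provided"))
})

test_that("unmapped names are categorised by failure pattern", {
  concepts <- concepts_fixture(
    c(
      "1-methyloxy-4-sulfone-benzene", "Analgesics and Anesthetics",
      "Substance-Related Disorders", "Therapy Related Acute Myeloid Leukemia",
      "PlainDrug"
    ),
    c("drug", "drug", "disease", "disease", "drug")
  )
  norms <- normalize_concepts(concepts)
  cat_of <- function(nm) norms$failure_category[norms$name == nm]
  expect_equal(cat_of("1-methyloxy-4-sulfone-benzene"), "chemical IUPAC name")
  expect_equal(cat_of("Analgesics and Anesthetics"), "drug class")
  expect_equal(cat_of("Substance-Related Disorders"), "too broad")
  expect_equal(
    cat_of("Therapy Related Acute Myeloid Leukemia"), "too narrow"
  )
  expect_equal(cat_of("PlainDrug"), "other")
})

test_that("override codes with wrong vocabulary syntax are a configuration error", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(RxNorm = list("some drug" = "RX-12a")), path)
  expect_error(read_manual_overrides(path), "invalid RxNorm")
  yaml::write_yaml(list(`SNOMED-CT` = list("some disease" = "12345")), path)
  expect_silent(ov <- read_manual_overrides(path))
  expect_equal(unname(ov$`SNOMED-CT`["some disease"]), "12345")
})

test_that("normalization is idempotent and deterministic", {
  concepts <- concepts_fixture(
    c("Paclitaxel", "Alzheimer Disease"), c("drug", "disease")
  )
  resolver <- lexicon_resolver(read_lexicon(default_lexicon_path()))
  n1 <- normalize_concepts(concepts, resolver = resolver)
  n2 <- normalize_concepts(concepts, resolver = resolver)
  expect_identical(n1, n2)
})

test_that("coverage report counts and percentages match hand counts", {
  concepts <- concepts_fixture(
    c(sprintf("Drug%02d", 1:10)), rep("drug", 10)
  )
  lexicon <- tibble::tibble(
    vocabulary = "RxNorm", code = as.character(1:7),
    preferred_name = sprintf("Drug%02d", 1:7), synonyms = ""
  )
  norms <- normalize_concepts(concepts, resolver = lexicon_resolver(lexicon))
  rep <- coverage_report(norms)
  expect_equal(rep$by_ctype$total, 10)
  expect_equal(rep$by_ctype$mapped, 7)
  expect_equal(rep$by_ctype$pct_mapped, 70.0)
  expect_equal(nrow(rep$unmapped), 3)
  empty <- coverage_report(normalize_concepts(concepts_fixture(
    character(0), character(0)
  )))
  expect_equal(nrow(empty$by_ctype), 0)
})
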