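test_that("relationships file parses with split PMIDs and canonical types", {
  rows <- read_pharmgkb_relationships(worked_example_path())
  expect_equal(nrow(rows), 4)
  expect_equal(lengths(rows$pmids), c(1, 1, 2, 2))
  expect_equal(rows$pmids[[1]], "18798002")
  expect_equal(rows$pmids[[3]], c("18496682", "19581389"))
  expect_setequal(
    unique(c(rows$entity1_type, rows$entity2_type)),
    c("disease", "variant", "gene", "drug")
  )
  expect_true(all(rows$source == "pharmgkb"))
})

test_that("relationship rows with missing names are dropped and counted", {
  path <- write_tsv_fixture(c(
    "Entity1_id\tEntity1_name\tEntity1_type\tEntity2_id\tEntity2_name\tEntity2_type\tPMIDs",
    "PA1\tDrugA\tDrug\tPA2\tGENE1\tGene\t111",
    "PA3\t\tDrug\tPA4\tGENE2\tGene\t222",
    "PA5\tDrugB\tDrug\tPA6\tNR\tGene\t333"
  ))
  rows <- read_pharmgkb_relationships(path)
  expect_equal(nrow(rows), 1)
  st <- drop_stats(rows)
  expect_equal(st$n[st$reason == "missing_entity_name"], 2)
  expect_equal(attr(rows, "rows_in"), nrow(rows) + sum(st$n))
})

test_that("relationships reader errors name the missing column", {
  path <- write_tsv_fixture(c(
    "Entity1_id\tEntity1_name\tEntity2_id\tEntity2_name\tEntity2_type\tPMIDs",
    "PA1\tDrugA\tPA2\tGENE1\tGene\t111"
  ))
  expect_error(read_pharmgkb_relationships(path), "Entity1_type")
})

test_that("header-only relationships file yields an empty table with a warning", {
  path <- write_tsv_fixture(paste(
    "Entity1_id", "Entity1_name", "Entity1_type",
    "Entity2_id", "Entity2_name", "Entity2_type", "PMIDs",
    sep = "\t"
  ))
  expect_warning(rows <- read_pharmgkb_relationships(path), "no data rows")
  expect_equal(nrow(rows), 0)
})

test_that("GWAS records expand into disease-gene, disease-SNP and gene-SNP pairs", {
  path <- write_tsv_fixture(c(
    "Disease/Trait\tReported Gene(s)\tSNPs",
    "bladder cancer\tGENE1, GENE2\trs1",
    "height\tGENE3\trs2",
    "bladder cancer\t\trs5"
  ))
  rows <- read_gwas_catalog(path, seeds = "bladder cancer")
  # 2 disease-gene + 1 disease-SNP + 2 gene-SNP from record 1, 1 disease-SNP
  # from record 3; the non-seed trait contributes nothing
  expect_equal(nrow(rows), 6)
  tab <- table(paste(rows$entity1_type, rows$entity2_type))
  expect_equal(unname(tab[["disease gene"]]), 2)
  expect_equal(unname(tab[["disease variant"]]), 2)
  expect_equal(unname(tab[["gene variant"]]), 2)
  expect_true(all(rows$source == "gwas"))
  st <- drop_stats(rows)
  expect_equal(st$n[st$reason == "trait_not_in_seeds"], 1)
})

test_that("GWAS seed matching ignores case and stray whitespace", {
  path <- write_tsv_fixture(c(
    "Disease/Trait\tReported Gene(s)\tSNPs",
    "Bladder  cancer \tGENE1\trs1"
  ))
  rows <- read_gwas_catalog(path, seeds = "bladder cancer")
  expect_equal(nrow(rows), 3)
})

test_that("malformed SNP ids are skipped with a warning", {
  path <- write_tsv_fixture(c(
    "Disease/Trait\tReported Gene(s)\tSNPs",
    "bladder cancer\tGENE1\trs1; chr7:12345"
  ))
  expect_warning(rows <- read_gwas_catalog(path, seeds = "bladder cancer"),
    "chr7:12345"
  )
  expect_equal(sum(rows$entity2_type == "variant" & rows$entity1_type == "gene"), 1)
  expect_equal(drop_stats(rows)$n[drop_stats(rows)$reason == "malformed_snp_id"], 1)
})

test_that("FDA reader keeps oncology rows and splits multi-gene cells", {
  path <- write_tsv_fixture(c(
    "Drug\tTherapeutic areas\tHUGO Symbol",
    "DrugA\tOncology\tG1; G2",
    "DrugB\tPsychiatry\tG3",
    "DrugC\toncology; Hematology\tG4"
  ))
  rows <- read_fda_biomarkers(path)
  expect_equal(nrow(rows), 3)
  expect_setequal(rows$entity2_name[rows$entity1_name == "DrugA"], c("G1", "G2"))
  expect_false("DrugB" %in% rows$entity1_name)
  expect_true(all(rows$entity1_type == "drug" & rows$entity2_type == "gene"))
})

test_that("predication reader deduplicates and drops blank predicates", {
  path <- write_tsv_fixture(c(
    "subject_name\tpredicate\tobject_name\tpmid",
    "GENE1\tASSOCIATED_WITH\tDiseaseX\t123",
    "GENE1\tASSOCIATED_WITH\tDiseaseX\t123",
    "GENE1\tASSOCIATED_WITH\tDiseaseX\t124",
    "GENE1\tASSOCIATED_WITH\tDiseaseX\t125",
    "GENE2\t\tDiseaseX\t126"
  ))
  rows <- read_predications(path)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$predicate[1], "ASSOCIATED_WITH")
  expect_equal(drop_stats(rows)$n[drop_stats(rows)$reason == "blank_predicate"], 1)
})

test_that("canonical dump and re-read reproduce the identical row multiset", {
  rows <- read_pharmgkb_relationships(worked_example_path())
  path <- tempfile(fileext = ".tsv")
  write_association_rows(rows, path)
  back <- read_association_rows(path)
  expect_equal(
    dplyr::arrange(as.data.frame(back), entity1_name, entity2_name),
    dplyr::arrange(
      as.data.frame(rows[names(back)]), entity1_name, entity2_name
    ),
    ignore_attr = TRUE
  )
})
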