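#' Configuration for the synthetic source-bundle generator
#'
#' Defines the shape of a generated five-file bundle: how many cancer
#' seeds, how many four-degree association chains are planted in the
#' PharmGKB-style relationships file, how many GWAS Catalog records and FDA
#' biomarker rows are emitted, how often GWAS/FDA endpoints reuse
#' PharmGKB-planted concepts (`overlap_fraction`), how often a planted
#' cross-resource pair receives a supporting semantic predication
#' (`evidence_fraction`), what fraction of drug and disease names are
#' deliberately unmappable (IUPAC-like chemical names, over-broad disease
#' groupings; `unmapped_fraction`), and how the mappable names are split
#' between the three normalization tiers.
#'
#' @param seed_count Number of cancer seed terms.
#' @param n_chains Number of planted degree-1..4 chains hanging off seeds.
#' @param chain_types Concept types at degrees 1..4 of each chain.
#' @param n_repurposing Number of planted drug-gene-disease repurposing
#'   paths (each contributes a drug at degree 2 with a known indication and
#'   a novel disease at path distance 2).
#' @param gwas_records Number of GWAS Catalog records.
#' @param fda_rows Number of oncology FDA biomarker rows.
#' @param overlap_fraction Probability a GWAS/FDA gene reuses a planted
#'   PharmGKB gene.
#' @param evidence_fraction Fraction of GWAS disease-gene and FDA drug-gene
#'   pairs given predication support.
#' @param unmapped_fraction Fraction of drug/disease names made
#'   unmappable.
#' @param p_source_provided,p_resolver Probabilities that a mappable
#'   drug/disease is normalized by a source-provided code or the exact-match
#'   resolver; the remainder are routed through the manual override file.
#' @param rng_seed Integer random seed; identical configuration and seed
#'   give byte-identical output files.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed_count = 3,
                         n_chains = 6,
                         chain_types = c("variant", "disease", "gene", "drug"),
                         n_repurposing = 2,
                         gwas_records = 5,
                         fda_rows = 4,
                         overlap_fraction = 0.5,
                         evidence_fraction = 0.5,
                         unmapped_fraction = 0.1,
                         p_source_provided = 0.5,
                         p_resolver = 0.3,
                         rng_seed = 1L) {
  cfg <- list(
    seed_count = as.integer(seed_count),
    n_chains = as.integer(n_chains),
    chain_types = chain_types,
    n_repurposing = as.integer(n_repurposing),
    gwas_records = as.integer(gwas_records),
    fda_rows = as.integer(fda_rows),
    overlap_fraction = overlap_fraction,
    evidence_fraction = evidence_fraction,
    unmapped_fraction = unmapped_fraction,
    p_source_provided = p_source_provided,
    p_resolver = p_resolver,
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c(
    cfg$overlap_fraction, cfg$evidence_fraction, cfg$unmapped_fraction,
    cfg$p_source_provided, cfg$p_resolver
  )
  if (any(fracs < 0 | fracs > 1) || cfg$p_source_provided + cfg$p_resolver > 1) {
    stop("fractions must lie in [0, 1] and tier probabilities sum to <= 1",
      call. = FALSE
    )
  }
  if (cfg$seed_count < 1 || any(c(
    cfg$n_chains, cfg$n_repurposing, cfg$gwas_records, cfg$fda_rows
  ) < 0)) {
    stop("counts must be non-negative (and at least one seed)", call. = FALSE)
  }
  if (cfg$overlap_fraction > 0 && cfg$n_chains == 0 &&
      (cfg$gwas_records > 0 || cfg$fda_rows > 0)) {
    stop(
      "infeasible config: overlap requested but no PharmGKB chains to overlap with",
      call. = FALSE
    )
  }
  if (!all(cfg$chain_types %in% CTYPE_LEVELS) || length(cfg$chain_types) < 1) {
    stop("chain_types must be concept types", call. = FALSE)
  }
  structure(cfg, class = c("synth_config", "list"))
}

# Disjoint name alphabets per concept type keep identity collisions
# impossible unless explicitly planted.
synth_name <- function(ctype, tag) {
  switch(ctype,
    drug = paste0("DRUG_", tag),
    gene = paste0("GENE", gsub("[^0-9A-Za-z]", "", tag)),
    disease = paste0("Disease_", tag),
    variant = paste0("rs", gsub("[^0-9]", "", tag)),
    haplotype = paste0("HAP*", tag)
  )
}

#' Generate a synthetic source bundle with ground truth
#'
#' Writes the five source files (PharmGKB-style relationships and entity
#' files, GWAS Catalog, FDA biomarker table, predication table) plus seed
#' list, lexicon, manual overrides, known indications and VIP pairs into
#' `out_dir`, and returns the ground truth for every planted fact: concept
#' degrees, planted pairs with their sources, expected normalization
#' methods, expected evidence attachments and planted repurposing
#' distances. Every planted fact is recoverable from the emitted files by
#' the parsing/expansion/normalization/evidence/repurposing pipeline.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `paths` (named file paths) and `truth` (ground-truth
#'   tibbles: `degrees`, `pairs`, `mapping`, `evidence`, `repurposing`,
#'   plus the `seeds` vector).
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$rng_seed)

  seeds <- sprintf("Cancer_%03d", seq_len(config$seed_count))
  pmid_counter <- 5e6
  next_pmid <- function() {
    pmid_counter <<- pmid_counter + 1
    as.character(pmid_counter)
  }

  rel_rows <- list()   # PharmGKB relationships file rows
  truth_deg <- list(
    tibble::tibble(name = seeds, ctype = "disease", degree = 0L)
  )
  truth_pairs <- list()

  add_rel <- function(n1, t1, n2, t2, pmid = next_pmid()) {
    rel_rows[[length(rel_rows) + 1]] <<- tibble::tibble(
      Entity1_id = paste0("PA", 400000 + length(rel_rows)),
      Entity1_name = n1,
      Entity1_type = ctype_label(t1),
      Entity2_id = paste0("PA", 500000 + length(rel_rows)),
      Entity2_name = n2,
      Entity2_type = ctype_label(t2),
      PMIDs = pmid
    )
    truth_pairs[[length(truth_pairs) + 1]] <<- tibble::tibble(
      key1 = concept_key(t1, n1), key2 = concept_key(t2, n2),
      source = "pharmgkb"
    )
  }

  # planted degree-1..4 chains off the seeds
  for (j in seq_len(config$n_chains)) {
    seed <- seeds[(j - 1) %% config$seed_count + 1]
    prev_name <- seed
    prev_type <- "disease"
    for (d in seq_along(config$chain_types)) {
      ct <- config$chain_types[d]
      nm <- synth_name(ct, sprintf("%02d%02d", j, d))
      add_rel(prev_name, prev_type, nm, ct)
      truth_deg[[length(truth_deg) + 1]] <- tibble::tibble(
        name = nm, ctype = ct, degree = as.integer(d)
      )
      prev_name <- nm
      prev_type <- ct
    }
  }

  # planted repurposing paths: seed - geneA - drug - geneB - novel disease
  truth_rep <- list()
  known_rows <- list()
  vip_rows <- list()
  for (k in seq_len(config$n_repurposing)) {
    seed <- seeds[(k - 1) %% config$seed_count + 1]
    ga <- sprintf("GENERP%02dA", k)
    gb <- sprintf("GENERP%02dB", k)
    dr <- sprintf("DRUG_RP%02d", k)
    nv <- sprintf("Disease_RP%02d_new", k)
    add_rel(seed, "disease", ga, "gene")
    add_rel(ga, "gene", dr, "drug")
    add_rel(dr, "drug", gb, "gene")
    add_rel(gb, "gene", nv, "disease")
    truth_deg[[length(truth_deg) + 1]] <- tibble::tibble(
      name = c(ga, dr, gb, nv),
      ctype = c("gene", "drug", "gene", "disease"),
      degree = 1:4
    )
    truth_rep[[k]] <- tibble::tibble(
      drug = concept_key("drug", dr),
      disease = concept_key("disease", nv),
      distance = 2L,
      novel = TRUE
    )
    known_rows[[k]] <- tibble::tibble(drug = dr, disease = seed)
    vip_rows[[k]] <- tibble::tibble(
      key1 = concept_key("gene", ga), key2 = concept_key("drug", dr)
    )
  }

  planted_genes <- unlist(lapply(truth_deg, function(t) t$name[t$ctype == "gene"]))
  planted_drugs <- unlist(lapply(truth_deg, function(t) t$name[t$ctype == "drug"]))

  # GWAS Catalog records (trait always a seed so the seed filter keeps them)
  gwas_recs <- list()
  evid_candidates <- list()
  for (g in seq_len(config$gwas_records)) {
    trait <- seeds[(g - 1) %% config$seed_count + 1]
    gene <- if (length(planted_genes) > 0 &&
                stats::runif(1) < config$overlap_fraction) {
      sample(planted_genes, 1)
    } else {
      sprintf("GENEGW%02d", g)
    }
    snp <- sprintf("rs9%05d", g)
    gwas_recs[[g]] <- tibble::tibble(
      `Disease/Trait` = trait, `Reported Gene(s)` = gene, SNPs = snp
    )
    evid_candidates[[length(evid_candidates) + 1]] <- tibble::tibble(
      name1 = trait, t1 = "disease", name2 = gene, t2 = "gene", source = "gwas"
    )
    truth_pairs[[length(truth_pairs) + 1]] <- tibble::tibble(
      key1 = concept_key("disease", trait), key2 = concept_key("gene", gene),
      source = "gwas"
    )
    truth_pairs[[length(truth_pairs) + 1]] <- tibble::tibble(
      key1 = concept_key("disease", trait), key2 = concept_key("variant", snp),
      source = "gwas"
    )
  }

  # FDA biomarker rows (plus one non-oncology decoy exercising the filter)
  fda_recs <- list()
  for (f in seq_len(config$fda_rows)) {
    drug <- if (length(planted_drugs) > 0 &&
                stats::runif(1) < config$overlap_fraction) {
      sample(planted_drugs, 1)
    } else {
      sprintf("DRUG_FDA%02d", f)
    }
    gene <- if (length(planted_genes) > 0 &&
                stats::runif(1) < config$overlap_fraction) {
      sample(planted_genes, 1)
    } else {
      sprintf("GENEFD%02d", f)
    }
    fda_recs[[f]] <- tibble::tibble(
      Drug = drug, `Therapeutic areas` = "Oncology", `HUGO Symbol` = gene
    )
    evid_candidates[[length(evid_candidates) + 1]] <- tibble::tibble(
      name1 = drug, t1 = "drug", name2 = gene, t2 = "gene", source = "fda"
    )
    truth_pairs[[length(truth_pairs) + 1]] <- tibble::tibble(
      key1 = concept_key("drug", drug), key2 = concept_key("gene", gene),
      source = "fda"
    )
  }
  decoy <- tibble::tibble(
    Drug = "DRUG_DECOY", `Therapeutic areas` = "Psychiatry",
    `HUGO Symbol` = "GENEDECOY"
  )

  # semantic predications supporting a fraction of cross-resource pairs
  predicates <- c(
    "AFFECTS", "ASSOCIATED_WITH", "AUGMENTS", "CAUSES", "COEXISTS_WITH",
    "INHIBITS", "INTERACTS_WITH", "PREDISPOSES"
  )
  pred_rows <- list()
  truth_evid <- list()
  for (cand in evid_candidates) {
    if (stats::runif(1) >= config$evidence_fraction) next
    pm <- next_pmid()
    pr <- sample(predicates, 1)
    pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
      subject_name = cand$name1, predicate = pr,
      object_name = cand$name2, pmid = pm
    )
    op <- orient_pair(
      cand$t1, concept_key(cand$t1, cand$name1),
      cand$t2, concept_key(cand$t2, cand$name2)
    )
    truth_evid[[length(truth_evid) + 1]] <- tibble::tibble(
      key1 = op$key1, key2 = op$key2, pmid = pm, predicate = pr
    )
  }

  # normalization plan: rename a fraction of drug/disease concepts to
  # unmappable forms, split the rest across the three tiers
  deg_tbl <- dplyr::bind_rows(truth_deg) |>
    dplyr::distinct(.data$name, .data$ctype, .keep_all = TRUE)
  mappable <- deg_tbl$ctype %in% c("drug", "disease") & deg_tbl$degree > 0
  rename_map <- character(0)
  n_unmap <- 0L
  methods <- rep(NA_character_, nrow(deg_tbl))
  draws <- stats::runif(nrow(deg_tbl))
  tier_draws <- stats::runif(nrow(deg_tbl))
  for (i in seq_len(nrow(deg_tbl))) {
    if (!mappable[i]) next
    if (draws[i] < config$unmapped_fraction) {
      n_unmap <- n_unmap + 1L
      new_name <- if (deg_tbl$ctype[i] == "drug") {
        sprintf("1-methyloxy-4-sulfone-benzene-%d", n_unmap)
      } else {
        sprintf("Group %d Related Disorders", n_unmap)
      }
      rename_map[[deg_tbl$name[i]]] <- new_name
      methods[i] <- "unmapped"
    } else if (tier_draws[i] < config$p_source_provided) {
      methods[i] <- "source_provided"
    } else if (tier_draws[i] < config$p_source_provided + config$p_resolver) {
      methods[i] <- "resolver_exact"
    } else {
      methods[i] <- "manual"
    }
  }
  # seeds are normalized via the resolver lexicon
  methods[deg_tbl$degree == 0] <- "resolver_exact"

  apply_rename <- function(x) {
    hit <- x %in% names(rename_map)
    x[hit] <- rename_map[x[hit]]
    x
  }
  deg_tbl$name <- apply_rename(deg_tbl$name)
  deg_tbl$key <- concept_key(deg_tbl$ctype, deg_tbl$name)

  empty_rel <- tibble::tibble(
    Entity1_id = character(0), Entity1_name = character(0),
    Entity1_type = character(0), Entity2_id = character(0),
    Entity2_name = character(0), Entity2_type = character(0),
    PMIDs = character(0)
  )
  rel_tbl <- dplyr::bind_rows(c(list(empty_rel), rel_rows)) |>
    dplyr::mutate(
      Entity1_name = apply_rename(.data$Entity1_name),
      Entity2_name = apply_rename(.data$Entity2_name)
    )
  rename_keys <- function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)
    vapply(parts, function(p) {
      nm <- p[2]
      for (old in names(rename_map)) {
        if (norm_name(old) == nm) nm <- norm_name(rename_map[[old]])
      }
      paste0(p[1], ":", nm)
    }, character(1))
  }
  empty_pairs <- tibble::tibble(
    key1 = character(0), key2 = character(0), source = character(0)
  )
  pair_tbl <- dplyr::bind_rows(c(list(empty_pairs), truth_pairs)) |>
    dplyr::mutate(
      key1 = rename_keys(.data$key1),
      key2 = rename_keys(.data$key2)
    ) |>
    dplyr::distinct()

  # renamed (unmappable) drugs may also appear in the FDA table, the
  # predication table, the known-indication list and the ground truth keys
  fda_recs <- lapply(fda_recs, function(r) {
    dplyr::mutate(r, Drug = apply_rename(.data$Drug))
  })
  pred_rows <- lapply(pred_rows, function(r) {
    dplyr::mutate(
      r,
      subject_name = apply_rename(.data$subject_name),
      object_name = apply_rename(.data$object_name)
    )
  })
  known_rows <- lapply(known_rows, function(r) {
    dplyr::mutate(r, drug = apply_rename(.data$drug))
  })
  truth_evid <- lapply(truth_evid, function(r) {
    dplyr::mutate(
      r,
      key1 = rename_keys(.data$key1), key2 = rename_keys(.data$key2)
    )
  })
  truth_rep <- lapply(truth_rep, function(r) {
    dplyr::mutate(
      r,
      drug = rename_keys(.data$drug), disease = rename_keys(.data$disease)
    )
  })
  vip_rows <- lapply(vip_rows, function(r) {
    dplyr::mutate(r, key1 = rename_keys(.data$key1), key2 = rename_keys(.data$key2))
  })

  # entity file, lexicon, overrides according to the planned tiers
  code_counter <- 0
  next_code <- function(ctype) {
    code_counter <<- code_counter + 1
    as.character((if (ctype == "drug") 100000 else 200000) + code_counter)
  }
  entity_rows <- list()
  lex_rows <- list(tibble::tibble(
    vocabulary = c("RxNorm", "SNOMED-CT", "RxNorm"),
    code = c("56946", "26929004", "194000"),
    preferred_name = c("Paclitaxel", "Alzheimer Disease", "Capecitabine"),
    synonyms = c("taxol", "alzheimer's disease", "")
  ))
  overrides <- list(`RxNorm` = list(), `SNOMED-CT` = list())
  for (i in seq_len(nrow(deg_tbl))) {
    m <- methods[i]
    if (is.na(m) || m == "unmapped") next
    ct <- deg_tbl$ctype[i]
    vocab <- if (ct == "drug") "RxNorm" else "SNOMED-CT"
    code <- next_code(ct)
    if (m == "source_provided") {
      entity_rows[[length(entity_rows) + 1]] <- tibble::tibble(
        Id = paste0("PA", 600000 + i), Name = deg_tbl$name[i],
        Type = ctype_label(ct),
        `SNOMED-CT` = if (vocab == "SNOMED-CT") code else "",
        RxNorm = if (vocab == "RxNorm") code else ""
      )
    } else if (m == "resolver_exact") {
      lex_rows[[length(lex_rows) + 1]] <- tibble::tibble(
        vocabulary = vocab, code = code,
        preferred_name = deg_tbl$name[i], synonyms = ""
      )
    } else {
      overrides[[vocab]][[deg_tbl$name[i]]] <- code
    }
  }

  truth_mapping <- tibble::tibble(
    key = deg_tbl$key, name = deg_tbl$name, ctype = deg_tbl$ctype,
    method = methods
  ) |>
    dplyr::filter(!is.na(.data$method))

  paths <- list(
    pharmgkb = file.path(out_dir, "pharmgkb_relationships.tsv"),
    entities = file.path(out_dir, "pharmgkb_entities.tsv"),
    gwas = file.path(out_dir, "gwas_catalog.tsv"),
    fda = file.path(out_dir, "fda_biomarkers.tsv"),
    predications = file.path(out_dir, "predications.tsv"),
    seeds = file.path(out_dir, "seeds.txt"),
    lexicon = file.path(out_dir, "lexicon.tsv"),
    overrides = file.path(out_dir, "overrides.yaml"),
    known = file.path(out_dir, "known_indications.tsv"),
    vip = file.path(out_dir, "vip_pairs.tsv")
  )
  write_or_empty <- function(tbl, empty, path) {
    out <- if (length(tbl) == 0) empty else dplyr::bind_rows(tbl)
    readr::write_tsv(out, path, progress = FALSE)
  }
  readr::write_tsv(rel_tbl, paths$pharmgkb, progress = FALSE)
  write_or_empty(
    entity_rows,
    tibble::tibble(
      Id = character(0), Name = character(0), Type = character(0),
      `SNOMED-CT` = character(0), RxNorm = character(0)
    ),
    paths$entities
  )
  write_or_empty(
    gwas_recs,
    tibble::tibble(
      `Disease/Trait` = character(0), `Reported Gene(s)` = character(0),
      SNPs = character(0)
    ),
    paths$gwas
  )
  readr::write_tsv(dplyr::bind_rows(c(fda_recs, list(decoy))), paths$fda,
    progress = FALSE
  )
  write_or_empty(
    pred_rows,
    tibble::tibble(
      subject_name = character(0), predicate = character(0),
      object_name = character(0), pmid = character(0)
    ),
    paths$predications
  )
  readr::write_lines(seeds, paths$seeds)
  readr::write_tsv(dplyr::bind_rows(lex_rows), paths$lexicon, progress = FALSE)
  yaml::write_yaml(
    lapply(overrides, function(v) if (length(v) == 0) NULL else v),
    paths$overrides
  )
  write_or_empty(
    known_rows,
    tibble::tibble(drug = character(0), disease = character(0)),
    paths$known
  )
  write_or_empty(
    vip_rows,
    tibble::tibble(key1 = character(0), key2 = character(0)),
    paths$vip
  )

  list(
    paths = paths,
    truth = list(
      seeds = seeds,
      degrees = deg_tbl[, c("key", "name", "ctype", "degree")],
      pairs = pair_tbl,
      mapping = truth_mapping,
      evidence = dplyr::bind_rows(truth_evid),
      repurposing = dplyr::bind_rows(truth_rep)
    ),
    config = config
  )
}

# Source-file spelling of a canonical concept type.
ctype_label <- function(ct) {
  c(
    drug = "Drug", disease = "Disease", gene = "Gene",
    variant = "Variant location", haplotype = "Haplotype"
  )[ct]
}
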