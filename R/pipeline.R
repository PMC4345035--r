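#' Path to the packaged worked-example relationships file
#'
#' A four-pair PharmGKB-style relationships file reproducing the published
#' worked example of the iterative expansion: starting from the seed
#' "Urinary bladder neoplasms", rs762551 is first degree, "Arthritis,
#' Rheumatoid" second, CYP1A2 third and olanzapine fourth.
#'
#' @return File path inside the installed package.
#' @export
worked_example_path <- function() {
  system.file("extdata", "pgx_worked_example.tsv",
    package = "cpnet", mustWork = TRUE
  )
}

#' Path to the packaged default lexicon
#'
#' A small exact-match lexicon carrying, among others, the published codes
#' Paclitaxel (RxCUI 56946), Capecitabine (RxCUI 194000) and Alzheimer
#' Disease (SNOMED-CT 26929004).
#'
#' @return File path inside the installed package.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "default_lexicon.tsv",
    package = "cpnet", mustWork = TRUE
  )
}

#' Read and validate a pipeline configuration
#'
#' A YAML file with input paths (`seeds`, `pharmgkb`; optionally
#' `entities`, `gwas`, `fda`, `predications`, `lexicon`, `overrides`,
#' `vip`, `known`), parameters (`max_degree`, `gwas_filter_mode`,
#' `validation`, `radius`, `query_drug`) and an `out_dir`. Referenced
#' input paths must exist at validation time.
#'
#' @param path Path to the YAML file.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(
    max_degree = 4, gwas_filter_mode = "any", validation = "strict",
    radius = 3, query_drug = NULL, out_dir = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in c("seeds", "pharmgkb")) {
    if (is.null(cfg[[nm]])) {
      stop("pipeline config is missing required input: ", nm, call. = FALSE)
    }
  }
  path_fields <- c(
    "seeds", "pharmgkb", "entities", "gwas", "fda", "predications",
    "lexicon", "overrides", "vip", "known"
  )
  for (nm in path_fields) {
    p <- cfg[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline config input does not exist: ", nm, " = ", p,
        call. = FALSE
      )
    }
  }
  if (!cfg$gwas_filter_mode %in% c("any", "both")) {
    stop("gwas_filter_mode must be 'any' or 'both'", call. = FALSE)
  }
  if (!cfg$validation %in% c("strict", "permissive")) {
    stop("validation must be 'strict' or 'permissive'", call. = FALSE)
  }
  cfg
}

#' Run the full CPN construction pipeline
#'
#' Executes the stages in order — parse, seed expansion, GWAS
#' co-occurrence filtering, normalization, evidence attachment, network
#' assembly and (when a query drug is configured) indication inference —
#' and returns a run manifest with per-stage counters. When `out_dir` is
#' set, degree records, the GraphML export, node/edge attribute TSVs, the
#' coverage report and candidate tables are written there.
#'
#' @param config A config list (see [read_pipeline_config()]) or a path to
#'   a YAML config file.
#' @return The run manifest: a list with `stages` (named counter lists),
#'   `outputs` (paths written) and the `graph`, `norms`, `report` and
#'   `candidates` objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  manifest <- list(stages = list(), outputs = character(0))
  count_drops <- function(rows) {
    list(
      rows_in = attr(rows, "rows_in") %||% nrow(rows),
      kept = nrow(rows),
      dropped = sum(drop_stats(rows)$n)
    )
  }

  seeds <- read_seed_list(config[["seeds"]])
  pharmgkb <- read_pharmgkb_relationships(config[["pharmgkb"]])
  manifest$stages$parse_pharmgkb <- count_drops(pharmgkb)

  expansion <- expand_from_seeds(pharmgkb, seeds, max_degree = config[["max_degree"]])
  manifest$stages$expand <- list(
    seeds = length(seeds),
    concepts = nrow(expansion$degrees),
    edges = nrow(expansion$edges),
    max_degree_seen = max(c(0L, expansion$degrees$degree))
  )

  gwas_rows <- NULL
  if (!is.null(config[["gwas"]])) {
    gwas_all <- read_gwas_catalog(config[["gwas"]], seeds)
    gwas_rows <- apply_gwas_cooccurrence_filter(
      gwas_all, expansion$degrees$key,
      mode = config[["gwas_filter_mode"]]
    )
    manifest$stages$gwas <- c(
      count_drops(gwas_all),
      list(kept_after_cooccurrence = nrow(gwas_rows))
    )
  }
  fda_rows <- NULL
  if (!is.null(config[["fda"]])) {
    fda_rows <- read_fda_biomarkers(config[["fda"]])
    manifest$stages$fda <- count_drops(fda_rows)
  }

  union_net <- associations_from_rows(dplyr::bind_rows(gwas_rows, fda_rows))
  concepts <- dplyr::bind_rows(
    expansion$concepts,
    dplyr::anti_join(union_net$concepts, expansion$concepts, by = "key")
  )

  entities <- if (!is.null(config[["entities"]])) {
    read_entity_records(config[["entities"]])
  }
  resolver <- if (!is.null(config[["lexicon"]])) {
    lexicon_resolver(read_lexicon(config[["lexicon"]]))
  }
  overrides <- if (!is.null(config[["overrides"]])) {
    read_manual_overrides(config[["overrides"]])
  }
  norms <- normalize_concepts(concepts, entities, resolver, overrides)
  report <- coverage_report(norms)
  manifest$stages$normalize <- list(
    concepts = nrow(norms),
    mapped = sum(norms$method != "unmapped"),
    unmapped = sum(norms$method == "unmapped")
  )

  evidence <- NULL
  if (!is.null(config[["predications"]])) {
    preds <- read_predications(config[["predications"]])
    lex <- if (!is.null(config[["lexicon"]])) read_lexicon(config[["lexicon"]])
    idx <- build_name_index(concepts, norms, lex)
    all_edges <- dplyr::bind_rows(expansion$edges, union_net$edges) |>
      dplyr::group_by(.data$key1, .data$key2, .data$pair_type) |>
      dplyr::summarise(
        sources = list(sort(unique(unlist(.data$sources)))),
        pmids = list(sort(unique(unlist(.data$pmids)))),
        .groups = "drop"
      )
    ev <- attach_evidence(all_edges, preds, idx)
    evidence <- ev$attachments
    manifest$stages$evidence <- list(
      predications = nrow(preds),
      edges_with_evidence = nrow(evidence),
      matched = ev$n_matched,
      unmatched = ev$n_unmatched
    )
  }

  vip <- if (!is.null(config[["vip"]])) read_vip_pairs(config[["vip"]])
  graph <- build_cpn(
    expansion,
    gwas_rows = gwas_rows, fda_rows = fda_rows,
    norms = norms, evidence = evidence, vip = vip,
    validation = config[["validation"]]
  )
  st <- cpn_stats(graph)
  manifest$stages$build <- list(n_nodes = st$n_nodes, n_edges = st$n_edges)

  candidates <- NULL
  if (!is.null(config[["query_drug"]])) {
    known <- if (!is.null(config[["known"]])) {
      read_known_indications(config[["known"]])
    } else {
      character(0)
    }
    candidates <- infer_indications(
      graph, config[["query_drug"]],
      radius = config[["radius"]], known = known
    )
    manifest$stages$repurpose <- list(
      candidates = nrow(candidates),
      novel = sum(candidates$novel)
    )
  }

  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
    degrees_path <- file.path(config[["out_dir"]], "degrees.tsv")
    readr::write_tsv(expansion$degrees, degrees_path, progress = FALSE)
    graphml_path <- file.path(config[["out_dir"]], "cpn.graphml")
    export_graph(graph, graphml_path, format = "graphml")
    tsv_paths <- export_graph(
      graph, file.path(config[["out_dir"]], "cpn"),
      format = "tsv"
    )
    coverage_path <- file.path(config[["out_dir"]], "coverage.tsv")
    readr::write_tsv(report$by_ctype, coverage_path, progress = FALSE)
    manifest$outputs <- c(degrees_path, graphml_path, tsv_paths, coverage_path)
    if (!is.null(candidates)) {
      cand_path <- file.path(config[["out_dir"]], "candidates.tsv")
      write_candidates(candidates, cand_path)
      manifest$outputs <- c(manifest$outputs, cand_path)
    }
  }

  manifest$graph <- graph
  manifest$norms <- norms
  manifest$report <- report
  manifest$candidates <- candidates
  manifest
}
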