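Package: cpnet
Title: Construction and Repurposing Analysis of Cancer Pharmacogenomics Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a cancer-centred pharmacogenomics network (CPN) from
    tabular association resources (a PharmGKB-style relationships file, the
    GWAS Catalog, an FDA biomarker table and a SemMedDB-style predication
    table). Starting from a seed list of cancer terms it performs a
    degree-limited breadth-first expansion with degree-dependent node
    weights, normalizes disease terms to SNOMED-CT and drug terms to RxNorm
    through a tiered lookup strategy, attaches PubMed evidence from semantic
    predications, assembles a typed heterogeneous graph, and infers
    candidate drug repurposing indications from bounded-length paths between
    drugs and diseases. A deterministic synthetic-data generator emulates
    all source formats with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
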