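# cpnet

Construction and repurposing analysis of cancer-centred pharmacogenomics
(PGx) networks in R.

Cancer pharmacogenomics resources — a PharmGKB-style relationships file,
the GWAS Catalog, the FDA table of pharmacogenomic biomarkers in drug
labeling, and SemMedDB-style semantic predications — describe overlapping
associations among drugs, genes, diseases, SNPs and haplotypes, but in
idiosyncratic formats and vocabularies. `cpnet` integrates them into a
single typed heterogeneous network (a cancer PGx network, CPN) and mines
it for drug-repurposing hypotheses. It is aimed at translational
informaticians who want a reproducible, testable version of this
integration recipe that runs on local tabular snapshots of the resources
(or on synthetic emulations of them) without any network access.

## What it computes

**Seed expansion with degree weights.** Starting from a seed list of
cancer terms, associations are extracted iteratively from the
relationships table: first-degree concepts are direct neighbours of a
seed, second-degree concepts are their neighbours, and so on, terminating
at the fourth degree. A concept's degree *d* is its minimum edge distance
from any seed, and it receives the weight score

```
w(d) = 5 - d        (d = 1..4  ->  w = 4, 3, 2, 1; seeds sit at d = 0)
```

encoding the assumption that seed-proximal concepts are more strongly
cancer-associated. GWAS Catalog associations are not expanded; they are
kept only where they co-occur with the PharmGKB-derived concept set, and
the FDA table contributes oncology drug–gene pairs directly.

**Tiered normalization.** Disease terms map to SNOMED-CT and drugs to
RxNorm through three tiers tried in order — codes provided by the source
entity files, an exact-match lexicon resolver (the packaged stand-in for
an ontology annotation service queried with `isexactmatch = 1`), then a
manual override file — with the winning tier recorded per concept. Genes
and SNPs already arrive as HUGO symbols and rsIDs. Unmapped names stay in
the network and are categorised (chemical IUPAC name, drug class, too
broad, too narrow).

**Evidence attachment.** Associations lacking source PubMed IDs are
joined against a subject–predicate–object predication table; a
predication supports an edge when its subject and object names resolve to
the edge's endpoints in either order, contributing its PMID and predicate.

**Path-based repurposing.** For a query drug, every disease node within 3
edges is a candidate indication. Simple paths up to the radius are
enumerated and candidates ranked by (path length ascending, node-weight
sum descending, VIP-pair count descending), then flagged as novel against
a known-indication list.

A deterministic synthetic-data generator (`synth_config()`,
`generate_bundle()`) emulates all five source formats with planted
chains, cross-resource overlaps and repurposing paths, and returns ground
truth for every planted fact, so the whole pipeline is testable end to
end.

## Worked example

The package ships a four-pair relationships file reproducing the
published expansion example:

```r
library(cpnet)
rows <- read_pharmgkb_relationships(worked_example_path())
ex <- expand_from_seeds(rows, "Urinary bladder neoplasms", max_degree = 4)
ex$degrees
#> # A tibble: 5 × 5
#>   key                               name                      ctype   degree weight
#>   <chr>                             <chr>                     <chr>    <int>  <int>
#> 1 disease:urinary bladder neoplasms Urinary bladder neoplasms disease      0      5
#> 2 variant:rs762551                  rs762551                  variant      1      4
#> 3 disease:arthritis, rheumatoid     Arthritis, Rheumatoid     disease      2      3
#> 4 gene:cyp1a2                       CYP1A2                    gene         3      2
#> 5 drug:olanzapine                   olanzapine                drug         4      1
```

The seed sits at degree 0; the SNP rs762551 is first-degree (weight 4),
rheumatoid arthritis second (3), the gene CYP1A2 third (2) and the drug
olanzapine fourth (1) — the chain of four printed association pairs.

Repurposing on a small case-study network:

```r
# graph: a CPN built with build_cpn() containing, among others, the pairs
# Capecitabine--CYP1A1 and CYP1A1--"Urinary Bladder Neoplasms"
cand <- infer_indications(graph, "drug:capecitabine", radius = 3)
cand$shortest_path[1]
#> [1] "drug:capecitabine>gene:cyp1a1>disease:urinary bladder neoplasms"
```

i.e. the shortest drug–gene–disease path connecting Capecitabine to
urinary bladder neoplasms, a distance-2 candidate indication.

Full runs are orchestrated by `run_pipeline()` from a YAML config (or the
thin CLI at `inst/scripts/cpn.R`), producing a manifest of per-stage
counters plus GraphML/SIF/TSV exports for Cytoscape.

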