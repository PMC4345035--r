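---
title: "Building and mining a cancer pharmacogenomics network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and mining a cancer pharmacogenomics network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpnet)
```

## The problem

Pharmacogenomics (PGx) resources record associations among drugs, genes,
diseases, SNPs and haplotypes, each in its own tabular format and
vocabulary. For cancer-orientated questions — above all, *which existing
drugs might treat which cancers?* — these fragments are far more useful
once merged into a single typed network whose nodes are normalized
concepts and whose edges carry provenance and literature evidence.
`cpnet` implements that integration and the path-based repurposing
analysis it supports, together with a synthetic generator that emulates
all source formats so every stage can be validated against planted ground
truth.

## The model

### Concept identity

A concept is identified by its type plus its case- and
whitespace-normalized name, e.g. `gene:cyp1a2`. All merging across
resources, seed matching, lexicon lookup and predication joining go
through this one normalization (`norm_name()`). Vocabulary codes obtained
during normalization decorate nodes but never replace the key: the key
must be stable whether or not normalization has run, and the sources
share surface names, so name-based identity merges exactly the concepts
a code-based identity would on these inputs. A name observed with two
different types is treated as an integration error rather than silently
forked.

### Seed expansion and degree weights

The expansion is a breadth-first search over the undirected association
graph from the set of seed concepts (cancer terms). The degree of a
concept is its *minimum* edge distance to any seed — the only reading
consistent with the premise that shorter distance means stronger
cancer association when a concept is reachable at several depths — and
the search retains concepts up to `max_degree = 4` by default. Weights
follow the line `w = 5 - d`: degree 1 scores 4 down to degree 4 scoring
1. Seeds themselves are assigned degree 0 and weight 5, continuing the
same line; no published value exists for seed weight, and the choice
only affects path weight sums by a constant when paths start at a
non-seed drug. Seed terms that match no concept in the table are kept as
isolated degree-0 disease nodes (with a warning) rather than rejected,
so an empty neighbourhood is an observable outcome, not an error.

Duplicate unordered pairs are merged (PMID lists and source sets
unioned) and self-loops dropped. Degree assignment is invariant to row
order and to swapping a row's two entities; the test suite checks
equivalence against an independent Bellman–Ford oracle on exhaustive
small graphs and random larger ones.

The GWAS Catalog is deliberately not expanded: its rows pass a
co-occurrence filter requiring at least one endpoint (configurably both)
to be already known to the PharmGKB-derived concept set. The sentence
this rule comes from is ambiguous between "any" and "both"; `any` is the
default because the catalog's traits are themselves seeds, making `both`
equivalent to requiring the gene/SNP side to be known — which remains
available as `mode = "both"`.

### Normalization tiers

Diseases normalize to SNOMED-CT, drugs to RxNorm, through three tiers
tried in order, first hit recorded: `source_provided` codes from entity
files, `resolver_exact` via an exact-match lookup, `manual` overrides.
The resolver is an interface contract (exact, case-insensitive match on
preferred names or synonyms, mirroring an annotation service queried
with its exact-match flag); the default implementation is a flat
packaged lexicon, so no build step ever requires network access. A live
REST client could satisfy the same contract. Genes and variants pass
through as HUGO symbols and rsIDs; haplotype names have no target
vocabulary. Unmapped drug/disease names stay in the network flagged
`unmapped` and are binned by name-pattern rules into the observed
failure modes: chemical IUPAC names absent from RxNorm, drug-class
names, and disease names too broad or too narrow for SNOMED-CT. The
packaged `default_lexicon.tsv` carries the three published codes used in
the worked examples (Paclitaxel 56946, Capecitabine 194000, Alzheimer
Disease 26929004) plus two synthetic stand-in disease codes.

### Evidence

Edges that lack source PMIDs can gain them from a semantic predication
table: a predication supports an edge when its subject and object names
each resolve — by the same exact name normalization, extended with the
preferred names of assigned codes — to the edge's two endpoints in
either order. Predicate strings are kept verbatim (including `NEG_`
prefixes); the package records them without interpreting polarity.
Matching is by name, not concept identifiers, because the sources carry
names; this is a documented interpretation, and the preferred-name
index is there to recover synonym matches that raw names would miss.
Evidence only decorates existing edges; it can never create one.

### Network assembly and the pair-type matrix

`build_cpn()` merges nodes by key and edges by unordered pair across the
three resources and validates each edge against a per-source matrix of
allowed pair types (PharmGKB: ten drug/disease/gene/variant/haplotype
combinations; GWAS: disease–gene, disease–SNP, gene–SNP; FDA:
drug–gene). The published table of allowed types is typographically
ambiguous in its check-mark layout, so the matrix is a configurable
argument and validation has a `strict` (error) and `permissive`
(warning) mode, defaulting to strict. GraphML is the canonical
attribute-preserving export (round-trip tested); SIF is provided for
Cytoscape convenience, attribute-free by the format's design.

### Repurposing

"Disease nodes at most 3 nodes away" is read as *edge distance at most
3*: the case-study figures show drug–gene–disease and
drug–SNP–disease hops, i.e. distance-2 paths. This is stated
prominently because "nodes away" could also be read as a count of
intermediate nodes. For a query drug, all simple paths (cycles excluded)
of length up to the radius are enumerated per candidate disease, capped
shortest-first by `max_paths_per_disease`. The rank score
operationalizes the published ranking ingredients — degree-based weight
scores, path length, VIP pairs — for which no formula is given, as the
ordered tuple (shortest-path length ascending, node-weight sum of the
best path descending, VIP-edge count descending, then lexicographic
disease key so ties are deterministic). VIP flags come from an optional
edge-annotation file; with none supplied every path has `vip_count = 0`.
Novelty is a flag against a user-supplied per-drug known-indication
list, emulating product-label indications; the package never fetches
labels.

## The synthetic generator

`generate_bundle()` emulates the five source formats with planted
structure and returns ground truth for every planted fact. Defaults are
chosen once as a desk-scale emulation of the published structures: 3
seed terms; 6 chains per bundle following the worked example's
disease–SNP–disease–gene–drug degree template; 2 planted repurposing
paths (seed–gene–drug–gene–novel-disease, so the drug sits at degree 2,
has a known indication at distance 2 and a novel disease at distance
2); 5 GWAS records and 4 FDA rows with a 0.5 chance of reusing a planted
PharmGKB concept (exercising cross-resource merging); evidence coverage
0.5; 10% of drug/disease names made deliberately unmappable; mappable
names split 0.5/0.3/0.2 across the source-provided/resolver/manual
tiers. Names are drawn from disjoint per-type alphabets (`DRUG_…`,
`GENE…`, `rs…`, `Disease_…`, `HAP*…`) so identity collisions are
impossible unless planted. Identical config and seed give byte-identical
files.

What the generator does *not* emulate — realistic degree distributions,
shared hub genes between chains, noisy spellings, the scale of the real
resources (thousands of nodes) — bounds what passing tests show: they
validate the algorithms' correctness on structurally faithful inputs,
not the biological or statistical properties of a network built from
real snapshots.

## Numerical and degenerate-input choices

* Distances are unweighted BFS distances (igraph); ties in degree are
  impossible by definition of minimum distance.
* Candidate ordering and path ordering always end in a lexicographic
  key tie-break, making every output deterministic.
* Header-only source files parse to empty tables with a warning; every
  dropped row is counted by reason (`drop_stats()`), so record-level
  parsing satisfies `rows_in = kept + dropped`.
* Multi-valued cells split on both `,` and `;` (the sources are
  inconsistent and the delimiters unstated); placeholder names
  (`NR`, `intergenic`) are dropped and counted.
* Curly quotes are normalized to ASCII on read.
* Coverage percentages are reported to one decimal.

## Problem sizes used in the test suite

The suite validates the expansion against the brute-force oracle on
roughly two hundred exhaustively small random graphs (up to 12 nodes)
plus one hundred graphs up to 60 nodes, and runs the full pipeline
against ground truth on twenty generated bundles with deterministically
varied configurations. These sizes give complete coverage of the
degree/distance logic at desk scale; the algorithms themselves are
linear-time BFS and scale to resource-sized inputs.

## Known limitations

* Indication vs adverse-event direction of drug–disease edges is not
  disambiguated; both enter the network as associations.
* Ranking is the tuple above; PageRank-style or GWAS p-value-weighted
  ranking is out of scope.
* The resolver performs exact matching only — no fuzzy matching, and no
  MeSH/UMLS target vocabularies.
* Evidence matching by name will miss predications phrased with
  synonyms absent from the lexicon.
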