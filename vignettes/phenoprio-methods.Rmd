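---
title: "Cross-species phenotype mapping and candidate gene prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species phenotype mapping and candidate gene prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprio)
```

## The problem

A clinician describes a patient's disease as a set of phenotype terms from
a human phenotype ontology. Most experimental evidence about gene function,
however, lives on the model-organism side: mouse genes annotated with terms
of a mammalian phenotype ontology. `phenoprio` bridges the two vocabularies
so that a human clinical description can be turned into a ranked list of
candidate genes, optionally restricted to a chromosomal interval implicated
by linkage analysis or CGH, and so that the quality of such rankings can be
judged against an analytic chance baseline.

## The Entity–Quality mapping cascade

Phenotype terms carry machine-readable logical definitions that decompose a
phenotype into a *quality* (how something is abnormal; a term of a quality
ontology shared by both species) and one or more *entities* (the affected
anatomical structures, drawn from species-specific anatomy ontologies). Two
phenotype terms from different species are considered equivalent when

1. their qualities are identical, or one quality is an `is_a` ancestor of
   the other (so "abnormal morphology" matches its specializations, but
   unrelated sibling qualities never match), and
2. at least one entity on each side is linked through a species-neutral
   bridge anatomy whose terms cross-reference both species' anatomy
   ontologies (existential matching: any bridged entity pair suffices;
   conjunctive semantics over multi-entity definitions is deliberately not
   imposed).

`map_term()` applies a three-stage cascade and stops at the first stage
that produces at least one mapping:

* **eq_exact** (weight 1.0): target terms whose definition matches the
  source definition under the rule above.
* **eq_inherited** (weight 1.0): when the source term has no usable
  definition (or its definition matches nothing), its `is_a` ancestors are
  walked breadth-first by increasing depth; at the first depth where any
  ancestor maps, the union of those ancestors' targets is inherited.
  Equally close annotated ancestors are unioned rather than broken by an
  arbitrary tie rule.
* **keyword** (weight `w_kw`, default 0.5): a manually curated index
  relating phenotypes of the same organ or function across species. The
  stage is down-weighted because keywords are far less precise than
  definition matching; the exact multiplier is a free parameter of the
  engine, exposed as `w_kw`, since only the principle (lower weight) is
  established, not a value.

A result never mixes stages, and inheritance happens on the source side
only — targets are taken as annotated, not expanded through their own
ancestors (expanding both sides would conflate term granularity with
mapping confidence).

## Queries, scores and ranks

Gene retrieval follows the true-path rule throughout: a gene annotated to
a term is implicitly annotated to every ancestor of that term, so querying
a coarse term captures finely annotated genes. Only `is_a` edges drive
closure; other relationship types present in source files are ignored
(whether `part_of` should contribute is an open modelling choice; the
restriction to `is_a` is the conservative one and is applied uniformly).

The query language combines atoms — `GO("...")`, `PHENO("...")`,
`PATHWAY("...")`, `IP("...")`, `OMIM("...")`, `SPECIES("...")`,
`REGION("chrom:start-end")` — with `and`, `or`, `not` and `[` `]`
grouping, `not` binding tightest. `X not Y` is accepted as sugar for
`X and not Y`. Evaluation is pure set algebra over the store's gene
universe; `not` complements within the *whole* universe (all species), so
users scope negations explicitly with `SPECIES(...)` — the simplest
semantics that composes.

A weighted query set scores each gene by the sum of the weights of the
queries it satisfies; with unit weights the score is the number of
conditions met. Ties are broken by ascending gene id so output is
deterministic.

`prioritize()` turns one disease into such a query set: each phenotype
feature becomes one query (an `or` over all its mapped target terms — the
feature fires if any mapped target matches), weighted by

* a **specificity weight**: the information content `-log2 f(t)` where
  `f(t)` is the fraction of corpus diseases annotated to the term or one
  of its descendants, clamped below at `1/(2 * corpus size)` so unseen
  terms stay finite. The principle (frequent features say little) is
  fixed; the concrete transform is the engine's main open design choice —
  `-log2 f` was chosen over alternatives such as `1 - f` or rank-based
  weights because it is unbounded for genuinely rare features and additive
  across independent features. Features whose weight is not positive
  (present in essentially every disease) carry no information and are
  dropped with a report.
* the **method weight** of the mapping stage (1.0 or `w_kw`).

Weights are not normalized per disease; scores are comparable within one
disease's ranking, which is the only place they are used. Disease-side
frequency qualifiers ("frequent", "occasional", ...) are parsed and
exposed to an optional multiplier hook but ignored by default.

With a region constraint, the candidate universe becomes the
model-species orthologs of the genes overlapping the interval (1-based
closed coordinates, overlap rather than containment — the natural
semantics for CGH/linkage intervals whose boundaries are themselves
fuzzy). Region genes without orthologs, and candidates without phenotype
annotation, are reported as *unscorable* rather than silently dropped.

## The chance-expectation null

To judge a benchmark ranking, `chance_expectation()` computes, from the
profile of candidate-region sizes \(n_j\), the expected number of true
genes found at each rank under the null that every region's candidates
are ordered uniformly at random:

\[
E_i \;=\; \sum_{j\,:\,n_j \ge i} \frac{1}{n_j},
\qquad
C_k \;=\; \sum_{i \le k} E_i .
\]

A region with \(n_j\) candidates places its true gene at any rank
\(i \le n_j\) with probability \(1/n_j\); summing over regions that are
large enough to have a rank \(i\) gives \(E_i\), and
\(\sum_i E_i\) equals the number of regions exactly (every true gene
lands somewhere) — an identity the tests assert to machine precision,
alongside Monte-Carlo agreement at \(10^5\) random orderings.

In the benchmark (`run_benchmark()`), windows of configurable width are
centered on the true gene's midpoint (an offset fraction is available for
sensitivity checks), the disease is prioritized within the window, and
the rank of the true gene's ortholog is recorded **conservatively**: a
tied true gene takes the worst rank within its tie group, and a true gene
with no matching feature takes the last rank of its universe. This
deliberately differs from the display order of the query engine, so the
evaluation can never flatter the method. Cases with no mappable feature
are excluded from rank statistics but always reported as an unanalyzable
fraction.

## What the synthetic universe emulates

`generate_fixture()` builds, deterministically from one seed, every input
the engine consumes: layered random phenotype DAGs (depth 5) for the two
species with planted Entity–Quality correspondences (each planted pair
shares a quality and one anatomy concept unique to it, so stage-1
recovery is exact by construction), an anatomy bridge covering a
configurable fraction of concepts, a curated keyword index, two species
of genes laid out one per 100 kb in 20 kb spans on multi-gene
chromosomes, a 1:1 (partially incomplete) orthology, background GO-like
and phenotype annotations, and a disease corpus whose causal genes carry
exactly the model annotations their features map to.

Default conditions: 40 diseases of 5 features each, 80% definition
coverage, 90% bridge coverage, 60% keyword coverage, 150 genes per
species, a 0.1 decoy sharing rate and, unless stated otherwise, no
description noise. The gene layout (1 gene per 100 kb) approximates
mammalian gene density, so a 1 Mb window holds ~10 candidates and a 10 Mb
window ~100, which is the regime where positional information matters.

Three structural guarantees make the planted truth exact rather than
merely probable:

* every mappable disease carries one *private* leaf feature whose target
  term is annotated to its causal gene alone;
* decoy genes pick up individual feature annotations at the configured
  rate but never a disease's complete profile;
* background annotations are drawn outside the target subtrees of
  disease features.

Consequently, in noise-free conditions the causal gene strictly outscores
every other candidate, and the ledger the generator writes (expected
scores computed by construction-side bookkeeping, not by running the
engine) is exact at any noise level. Description noise `q` replaces each
feature independently by a random unrelated term; median achieved rank
degrades monotonically in `q`, which the acceptance suite checks
directionally.

What the fixture does **not** emulate: realistic term-frequency
distributions of clinical vocabularies, realistic chromosome lengths or
gene-size variation, many-to-many orthology, and annotation noise on the
model-organism side. Passing tests therefore demonstrate algorithmic
correctness and calibration, not the absolute recovery rates achievable
on real corpora — those depend on the density and quality of curation in
ways a synthetic universe cannot represent.

## Statistics

Enrichment uses the exact one-sided hypergeometric tail (computed through
the log-space routines of `stats::phyper`), with the direction chosen
from the observed proportions (`enriched` when `k/n >= K/N`); the
direction is reported so users preferring a two-sided convention can
double the p post hoc — the sidedness convention is exposed rather than
hidden because either choice is defensible. The correction family is the
set of terms actually tested within the namespace (terms with at least
one propagated reference annotation), not the whole ontology. Bonferroni
and Benjamini–Hochberg adjustments are delegated to `stats::p.adjust` and
cross-checked against their textbook definitions in the tests.
Conditional probabilities between two terms are plain propagated-set
ratios, with an explicit error (never a silent `NaN`) when the
conditioning set is empty.

## Numerical and interface choices

* Coordinates are 1-based closed intervals everywhere inside the store;
  conversion to BED's 0-based half-open convention happens only at the
  export boundary.
* All tabular IO is headered, tab-delimited UTF-8; ontologies are read
  and written in the OBO 1.2 flat dialect (recognized tags only;
  qualifiers, comments and synonym scopes stripped; obsolete terms kept
  for id lookup but excluded from closures so annotations to dead terms
  surface instead of vanishing).
* Logical definitions may come from OBO `intersection_of` lines (first
  term-only line = quality, relation-bearing lines = entities) or a
  three-column TSV sidecar; the sidecar wins on conflict because it is
  the more deliberate input.
* Label resolution is exact, case-insensitive and
  whitespace-normalized, names before synonyms; ambiguity is an error
  listing candidates. CURIE-shaped labels resolve by id only.
* Every sort is radix (byte) order so results do not depend on the
  locale; fixture output is byte-identical across runs with one seed.
* The test and acceptance suites run the benchmark at 40–200 diseases,
  60–400 term ontologies and 150–400 genes per species — sizes chosen so
  the full suite exercises every code path at meaningful scale while a
  complete run stays interactive.

## Known limitations

* Mapping inheritance considers the source side only; a source term can
  never inherit a target's descendants.
* `not` over large universes is exact but can be slow on stores orders
  of magnitude larger than the fixture scale; the engine is designed for
  desk-scale curated stores, not population-scale variant data.
* The information-content specificity weight depends on the corpus
  supplied; weights from different corpora are not comparable.
* Keyword mappings are only as good as the curated index; the engine
  deliberately refuses to guess beyond it (no fuzzy label matching).
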