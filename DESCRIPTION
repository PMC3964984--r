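Package: phenoprio
Title: Cross-Species Phenotype-Based Candidate Disease Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for prioritizing candidate disease genes from clinical
    phenotype descriptions using cross-species phenotype-ontology mapping.
    Parses OBO ontologies into is_a term graphs, aligns phenotype terms
    between species through Entity-Quality logical definitions bridged by a
    species-neutral anatomy ontology (with closest-annotated-parent and
    down-weighted keyword fallbacks), evaluates weighted Boolean queries over
    gene annotation stores, restricts candidates to chromosomal intervals,
    performs hypergeometric enrichment and depletion tests with Bonferroni
    and Benjamini-Hochberg corrections, and computes the analytic chance
    expectation for ranks of true genes drawn uniformly within candidate
    regions. A seeded synthetic-fixture generator builds complete test
    universes (ontologies, logical definitions, anatomy bridge, genes,
    annotations, orthology, disease corpora with planted causal genes) so the
    whole pipeline is reproducible without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
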