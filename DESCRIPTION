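Package: interologr
Title: Interolog-Based Protein-Protein Interaction Prediction and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts genome-scale protein-protein interaction (PPI) networks for
    a target species by interolog transfer: interactions observed in template
    species are projected through alignment-filtered ortholog maps (identity,
    query coverage and e-value thresholds applied to BLASTp tabular output).
    Predicted edges are scored with a composite confidence value combining
    cross-species interolog support with domain-domain interaction (DDI)
    enrichment, tiered by percentile rank, validated against protein presence
    and time-series co-expression evidence (Pearson correlation), and
    characterized with scale-free / small-world topology statistics against
    matched Erdos-Renyi references. A seeded synthetic-data generator with
    planted ground truth supports end-to-end recovery testing, and a pipeline
    orchestrator runs the full procedure from flat-file inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
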