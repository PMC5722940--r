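---
title: "Interolog PPI prediction: models, scoring and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interolog PPI prediction: models, scoring and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interologr)
```

## The problem

Protein–protein interaction (PPI) maps are experimentally thin in most
non-model organisms. The interolog method fills that gap by projection: if
proteins A and B interact in a well-studied template species, and the target
species carries orthologs a of A and b of B, the pair {a, b} is predicted to
interact. `interologr` implements that transfer together with the downstream
machinery a practical screen needs — confidence scoring against domain–domain
interaction (DDI) catalogues, expression-based validation, and network
topology checks — in a species-agnostic form driven by flat tabular inputs.

## Ortholog admission

Orthology is operationalized purely from BLASTp tabular output. A
(template, target) pair is admitted when at least one hit satisfies all of

* percent identity >= 60,
* query coverage >= 80, where coverage = 100 × aligned query span / query
  length,
* e-value <= 1e-10,

with boundary values inclusive. Coverage is defined over the *query*
(template) protein because that is the only side whose length is available
from tabular output plus a length table, and because templates are the
queries of the screen. Orthology is one-way and many-to-many: no
reciprocal-best-hit filtering, no HSP merging. All three thresholds are
arguments of `filter_orthologs()`, so stricter conventions are one call away.

## Transfer and provenance

`transfer_interactions()` emits the full ortholog cross-product for every
template interaction: with A → {a1, a2} and B → {b}, both {a1, b} and
{a2, b} are predicted. A best-hit-only rule would forbid the map from
expanding, which contradicts how many-to-many ortholog maps behave in
practice; the cross-product is also the only rule that makes the planted
recovery tests exact. Predictions arising repeatedly are merged, and every
(species, evidence method, source database, template pair) witness is
retained in a provenance table. Template interactions with an unmapped
endpoint are counted and skipped — with sparse ortholog maps that is the
expected fate of most of them, not an error.

## Confidence model

Each prediction is scored by

CV = CV_interolog × CV_DDI,

with

* CV_interolog = Σᵢ Sᵢ Mᵢ / N over the N distinct supporting species. The
  existence factor Sᵢ is identically 1 (orthologs are established before an
  edge enters the network). Mᵢ is 1 for experimentally measured and 0.5 for
  computationally predicted source interactions; when one species supplies
  both kinds of witness for the same pair, the experimental evidence
  dominates (Mᵢ = 1), since a measurement subsumes a prediction of the same
  edge.
* CV_DDI = d × D, where D = (matched DDI rules between the two domain sets) /
  (n_dom_a × n_dom_b) and d = 0.5 when *both* proteins carry exactly one
  domain, else 1. The both-proteins reading was chosen because only there is
  D forced into {0, 1}, which is the "probability bias" the correction
  exists to damp; `compute_d()` is documented and tested so the alternative
  either-protein reading is a one-line change. Domain sets are sets (repeat
  accessions collapse), a rule matched in both orientations counts once, and
  proteins without domain annotation give D = 0.

A useful algebraic consequence, asserted in the tests and recomputed by the
acceptance script: when every witness is computational, CV_interolog = 0.5
and CV_DDI <= 1, so no configuration of species counts, domain counts and
DDI counts can push CV above 0.5.

## Tiers

Edges without any DDI support form the Basal (B) tier. DDI-supported edges
are ranked by the percentile of their CV within that supported population
and split into H1 (rank > 80), H2 (50 <= rank <= 80) and H3 (rank < 50).
The percentile rank is the Hazen definition, 100 × (rank − 0.5) / n with
average ranks for ties. This choice was genuinely open; Hazen was adopted
because (i) it reproduces the canonical 2/3/5 split of ten distinct scores,
(ii) ties always share a tier, and (iii) it is invariant under duplicating
the population, so tier assignments do not depend on accidental edge
multiplicity. Cut points are arguments.

## Expression validation

Three levels of evidence are used:

1. **Presence.** A protein seen in any presence dataset, or any gene whose
   mean expression lies strictly above its dataset's 80th-percentile cutoff
   (inverse-ECDF quantile), counts as expressed. The mean was chosen as the
   per-gene summary because no aggregation rule is canonical; `max` is
   available as an option. An edge is expression-supported only when *both*
   endpoints are expressed.
2. **Co-expression.** On time-series datasets, each edge with both profiles
   available gets a Pearson correlation and a two-sided p-value from the t
   transform (df = n − 2). An edge is co-expressed when *any* dataset gives
   PCC > 0.9 and p < 0.1, strict inequalities. With 3–5 time points this
   test is deliberately underpowered — that mirrors the scale of real
   time-course datasets in non-model crops, and it is why the p threshold
   is as loose as 0.1.
3. **Group shapes.** Connected components of the co-expressed edge set are
   classified as heterodimeric (2 proteins), linear multimeric (>= 3,
   acyclic) or circular multimeric (any cycle). Branched acyclic components
   are reported as linear with a `branched` flag rather than inventing a
   fourth class.

## Topology

`network_stats()` reports the degree histogram, a power-law exponent fitted
by ordinary least squares on log10 P(k) vs log10 k (the straight-line
practice of network-analysis GUIs; it needs >= 3 support points), the
average shortest-path length over *connected* pairs only (unreachable pairs
are excluded from numerator and denominator, which is the only convention
under which a disconnected network has a finite L), the mean local
clustering coefficient with C_i = 0 for degree < 2 nodes, and the diameter.
`small_world_report()` compares L and C against seeded Erdős–Rényi G(n, m)
references matched on node and edge counts — G(n, m) rather than G(n, p)
because the comparison is defined by equal edge counts, not equal edge
probability. Self-loops count once toward degree and are ignored by path
and clustering statistics.

## The synthetic world

`generate_world()` builds a fully seeded test world: a preferential-
attachment master structure over ortholog groups (so topology tests see
scale-free inputs), per-species interaction sets sampled from it with
log-spread counts (one species dominating, as public plant PPI repositories
do), alignment statistics drawn *inside* the admission region for conserved
proteins and built to fail at least one threshold for decoys, domain
annotations with planted DDI rules, and expression data in which planted
co-expressed pairs share a latent Gaussian random-walk profile plus
independent noise (profiles are offset and floored at zero so expression
stays non-negative; at noise 0 both members are identical and PCC = 1
exactly). Every expected score component is recomputed by plain loops inside
the generator, independent of the pipeline's vectorized code, so recovery
tests can demand exact equality.

Default sizes (3–7 species, tens to hundreds of template edges per species,
4 time points) keep a full world under a second to generate; the test suite
runs hundreds of such worlds. What the generator does *not* emulate:
realistic sequence evolution, Pfam architecture correlations, shared
orthologs between groups, or expression normalization artefacts — so
passing recovery tests demonstrate correctness of the machinery, not
biological accuracy of any particular prediction.

## Degenerate inputs and numerical choices

* Unordered pairs are canonicalized lexicographically everywhere;
  self-interactions are legal and retained.
* Missing expression cells are rejected at load (no imputation rule exists
  worth defaulting to); zero-variance profiles make an edge non-co-expressed
  in that dataset rather than erroring the run.
* r = ±1 maps to p = 0 directly, avoiding the singular t transform.
* Empty networks, all-Basal networks, empty ortholog maps and header-only
  files all flow through without special casing.

## Limitations

The package predicts *candidate* interactions; the confidence value ranks
plausibility but is bounded by the quality of template data, and tier
boundaries are population-relative (percentiles), so they are not
comparable across networks. GO enrichment, visualization and database
retrieval are out of scope — exports (SIF, GraphML, edge tables) are
provided for downstream tools instead.
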