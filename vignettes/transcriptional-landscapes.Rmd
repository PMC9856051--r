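---
title: "Mapping transcriptional landscapes from ranked gene-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptional landscapes from ranked gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The method

`enrichscape` turns a gene-by-sample count matrix from a multi-group bulk
RNA-seq study into a clustered *landscape network* of gene sets, and overlays
further group comparisons and a ligand/receptor interactome on top of it. The
intended setting is a three-group design — two disease groups and one
control, as in glomerular transcriptomics of minimal change disease (MCD) and
membranous nephropathy (MN) against normal-histology controls — but nothing
in the code is specific to kidney biology.

The pipeline composes six stages:

1. **Differential expression.** Counts are normalized by median-of-ratios
   size factors (each sample's median ratio to the gene-wise geometric-mean
   reference over genes detected in every sample). Per gene and contrast we
   report the log2 fold change of group-mean normalized counts (with a
   pseudocount), a Welch test on `log2(normalized + c)` (default) or a
   negative-binomial Wald fit (optional), and Benjamini–Hochberg adjusted
   p-values.
2. **Shrinkage and ranking.** Fold changes are shrunk towards zero with a
   normal-prior ridge factor `tau2 / (tau2 + se^2)`; the prior variance is
   moment-matched as `max(0, var(lfc) - mean(se^2))`. Genes are ranked by
   the shrunken fold change (slfc), with ties broken by the test statistic
   and then the gene identifier, giving a strict, reproducible total order.
3. **Preranked enrichment.** For every gene set in a size-filtered GMT
   collection (strictly more than 10 and fewer than 500 members), the
   classic weighted Kolmogorov–Smirnov running sum is evaluated on the
   ranked list: hits add `|score|^p / sum|score|^p` (default `p = 1`),
   misses subtract `1/(N - n)`. The enrichment score (ES) is the signed
   maximal deviation; the leading edge is the member genes at or before the
   peak (at or after the trough for depletion). Significance comes from a
   gene-sampling permutation null (one shared null per distinct set size),
   sign-partitioned in the standard GSEA manner, with the +1-smoothed
   estimator and BH adjustment across all tested sets.
4. **Network construction.** A set becomes a node when its adjusted p-value
   is below 0.001 *and* at least 33.34% of its members in the ranked
   universe lie in its leading edge. An edge joins two nodes when their
   leading edges share at least 5% of the smaller member set; the edge
   weight is the member-overlap coefficient
   `|A ∩ B| / min(|A|, |B|)` (Jaccard optional). Enriched and depleted
   nodes coexist; direction is an attribute, never a filter.
5. **Markov clustering and projection.** The weighted network is clustered
   with an implemented Markov Cluster algorithm (expansion 2, inflation
   2.0, pruning 1e-5). The scaffold is then frozen: the remaining
   comparisons are *projected* onto it — every node gains that
   comparison's adjusted p-value, direction and significance tier — and
   per-cluster summaries report signed `-log10(padj)` values (positive for
   enrichment, negative for depletion, magnitudes capped at 16).
6. **Interactome overlay.** A curated ligand→receptor pair table is
   annotated per comparison with gene-level volcano classes (adjusted
   p < 0.05 and a 2-fold shrunken-change criterion). Pairs where the
   receptor is up but the ligand is not are flagged as *receptor-only
   activation* — the paracrine signature the projection is designed to
   surface — and both-up pairs as *autocrine candidates*.

# Parameters that matter

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `pseudocount` | 0.5 | normalized counts | keeps `log2` finite for zero counts without dominating moderately expressed genes |
| `node_padj` | 0.001 | BH-adjusted p | strict node gate; separates scaffold membership from the milder 0.05 gene-level gate |
| `node_le_frac` | 0.3334 | fraction of members | at least a third of a set must drive its signal, excluding sets carried by a few extreme genes |
| `le_gate` | 0.05 | fraction of smaller member set | minimum leading-edge sharing for an edge |
| `weight_denom` | `"min"` | — | overlap coefficient; `"union"` (Jaccard) available and logged in export metadata |
| `inflation` | 2.0 | — | canonical MCL default; common alternative 2.5 reachable via config |
| `nperm` | 50000 (pipeline), 10000 (`run_enrichment`) | permutations | see below |
| `weight_p` | 1 | — | conventional GSEA weighting |
| `gene_padj`, `gene_fc` | 0.05, 2 | — | gene-level volcano criterion |

**Why 50,000 permutations in the pipeline.** With the +1-smoothed
estimator and a sign-partitioned null, the attainable p-value floor is about
`2/nperm`. BH adjustment over a few hundred sets multiplies the smallest
p-values by roughly `n_sets / rank`; with ~10 true positives among 200 sets
that factor is ~20, so clearing the 0.001 node gate needs
`40000/nperm < 0.001`, i.e. `nperm` around 50,000. The cost is small because
one null is shared per distinct set size and the sampler is compiled.

**Fold-change criterion reading.** A "greater than 2" shrunken fold-change
criterion is ambiguous between a linear 2-fold change (`|slfc| >= 1` in log2
units) and a literal 2 log2 units (4-fold). The default is the linear
reading, which treats up- and down-regulation symmetrically at 2-fold;
`fc_mode = "log2"` selects the literal reading.

**Edge definition.** The gate is computed on leading-edge intersections and
the weight on full member-set overlap, both normalized by the smaller member
set. This split follows the reading that attraction should reflect overall
membership overlap while the gate asks whether the *active* portions of two
sets coincide. Both denominators are configurable and recorded in the export
headers, since reasonable maps can be built either way.

# The synthetic-data generator

`simulate_study()` emulates a three-group bulk study: gene base means are
log-normal (`meanlog 4`, `sdlog 1.5` — median around 55 normalized counts
with a realistic dynamic range), dispersions follow the common decreasing
trend `phi = phi0 + a/mu` (`phi0 = 0.05`, `a = 1`), library-size factors are
log-uniform within 0.7–1.4, and group sizes default to 8 per group (the size
of the smallest group in the motivating study, whose groups were 14, 12 and
8). Planted signals shift `round(responder_fraction × size)` member genes of
a set by `2^member_effect_lfc` in the affected groups; planted sets receive
disjoint members so the ground truth is unambiguous, while null sets are
drawn uniformly from the whole universe (and may therefore graze responder
genes, as real overlapping pathways would).

The packaged demo truth (`fixture_signals()`) plants ten sets of 50 genes at
effect size 1 log2 unit and responder fraction 0.5: five specific to disease
group A versus control and five shared by both disease groups, each mix of
enriched and depleted. This reproduces, in silico, the shared-versus-specific
dichotomy that projection onto a fixed scaffold is meant to expose: specific
sets stay significant in the disease-vs-disease comparison, shared sets do
not.

What the generator does *not* model: batch structure is absent by default
(an optional known two-batch log-scale offset can be planted to exercise the
known-covariate adjustment; there is no surrogate-variable estimation),
there are no composition effects beyond what median-of-ratios absorbs, no
gene–gene correlation within sets beyond the planted mean shifts, and no
degradation artifacts of archival FFPE material. Passing tests on this
generator therefore demonstrate the statistical machinery and its
calibration, not robustness to those real-data complications.

# Numerical choices and degenerate inputs

- **ES ties.** Running-sum deviations that tie in magnitude (within 1e-9)
  resolve to the earliest walk position, making ES sign, peak and leading
  edge deterministic; exact rational ties reached through different
  floating-point paths resolve identically.
- **All-zero ranking metric.** Under a pure null study the moment-matched
  prior variance is 0 and every slfc collapses to exactly 0. The weighted
  ES is then taken at its uniform-hit-weight limit (the unweighted KS
  form), with a warning; the ranking order itself remains informative via
  the deterministic tie-breaks. A single set whose members alone score zero
  within a non-degenerate ranking is skipped instead.
- **MCL.** Column renormalization resurrects fully pruned columns as
  self-flow; convergence is declared when the iteration changes no entry by
  more than 1e-8; attractor overlap resolves to the lowest cluster index;
  non-convergence within `max_iter` returns the current partition with a
  warning.
- **Underflow.** Adjusted p-values are floored at 1e-16 before the signed
  log transform, capping theme magnitudes at ±16.
- **Size factors.** When no gene is detected in every sample the
  median-of-ratios reference is undefined; the code falls back to
  total-count factors scaled to geometric mean 1, with a warning.
- **Seeds.** Every stochastic stage takes an explicit seed; the pipeline
  derives stage seeds as `seed + stage index` and records every parameter
  and input/output checksum in a JSON manifest, so a run is reproducible
  byte for byte.

# Design decisions taken where the design was open

- The differential-expression stage is a deliberately simple, documented
  estimator (median-of-ratios + Welch-on-log2 + ridge shrinkage) rather
  than a full shrinkage-estimation framework: the acceptance surface of the
  pipeline is recovery of planted pathway-level truth and calibration under
  the null, which this estimator meets (type-I error within [0.04, 0.06]
  and KS-uniform p-values on null studies at the packaged problem sizes).
  It is not a drop-in reimplementation of any published DE tool.
- Surrogate-variable batch correction is out of scope; a known batch
  covariate can be planted and removed by per-batch centering.
- The permutation p-value uses plain subset sampling with +1 smoothing
  rather than adaptive multilevel refinement; at the thresholds the
  pipeline uses (0.001 and 0.05) the extra resolution of multilevel
  estimation is unnecessary once `nperm` is set as above, and the simple
  estimator can be validated directly against exhaustive enumeration on
  small universes.
- The multiple-testing procedure is Benjamini–Hochberg throughout.
- Cluster label suggestion is token-frequency only; naming a biological
  theme remains an analyst's judgement.

# Problem sizes used by the test-suite

Unit and end-to-end tests run on studies of 300–5,000 genes with 8 samples
per group, collections of 200 sets, enumeration universes of up to 12 genes
(where exhaustive subset enumeration is feasible as an oracle), and 10–20
replicate seeds for recovery and calibration properties. These sizes were
chosen so that every statistical property is measurable with meaningful
power while a full suite completes in minutes on one CPU.

# Known limitations

- Gene identifiers are opaque strings; no alias or ortholog resolution.
- Phenotype-permutation GSEA and single-sample variants are out of scope.
- The curated interleukin/interferon pair table shipped under
  `inst/extdata/` is a hand-compiled static snapshot of well-established
  HGNC-family and literature pairings, not a live database export.
- Network export is GraphML plus TSV twins; layout and interactive
  exploration belong to downstream viewers.
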