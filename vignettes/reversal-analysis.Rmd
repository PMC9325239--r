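---
title: "Transcriptomic reversal analysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic reversal analysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The analytical model

`sigreverse` operationalizes a simple therapeutic hypothesis: genes that
a drug regulates in the direction *opposite* to a disease signature are
candidate mediators of its clinical effect. The pipeline integrates two
very different kinds of evidence:

1. a **disease signature** — a summary table (gene, log2 fold change,
   p, BH-adjusted q) from a large case–control cohort, taken as given;
2. **drug signatures** — estimated here from raw drug-versus-vehicle
   count matrices of a cell-line experiment with a handful of
   replicates per group.

A gene is *reversed* by a drug when it is significant on both sides
(`q ≤ 0.1` for the disease, `q ≤ 0.05` for the drug) and the product of
its two log fold changes is strictly negative. Zero log fold change on
either side never counts, so the rule has no tie ambiguity. Both
thresholds compare with `≤`. The disease threshold of 0.1 follows the
convention of large post-mortem cohort analyses; the drug-side threshold
is a package default (0.05) and configurable, since small in-vitro
designs are usually held to the conventional level.

Genes reversed by *all* drugs form the common set on which the
downstream biology is read out. Because each common gene must oppose the
single disease sign, all of its drug fold changes share one sign — the
pipeline asserts this invariant rather than assuming it, and derives the
consensus direction and unweighted mean drug logFC from it.

## Per-drug differential expression

The DE step is deliberately minimal and fully documented:

- **Filtering.** A gene is kept when its CPM is at least `min_cpm`
  (default 1) in at least `n` samples, `n` being the size of the
  smallest group — the standard rule for small two-group designs. A
  second rule (CPM strictly above the threshold in strictly more than a
  given fraction of samples) matches the convention used for large
  cohort tables, and is what the synthetic disease table emulates. The
  strict/non-strict inequalities differ between the two rules on
  purpose; both are tested at their boundaries.
- **Normalization.** Weighted trimmed mean of M-values with the
  method's published trim fractions (30% on M, 5% on A), precision
  weights equal to inverse asymptotic variances of M, reference sample
  chosen by the upper-quartile rule, and factors rescaled to geometric
  mean 1. The implementation is the package's own; the test suite
  cross-checks it against `edgeR::calcNormFactors` and against a
  step-by-step evaluation of the trimmed weighted mean on a
  composition-biased instance.
- **Testing.** A per-gene Welch (unequal-variance) test on normalized
  log2-CPM, with a pseudo-count of 0.5 on counts and +1 on the
  effective library size. This is a deliberate desk-scale substitute
  for a negative-binomial framework: it is dependency-free,
  transparent, and calibrated (empirical type-I error 0.044 at nominal
  0.05 over ~19,000 null genes in the test suite). It sacrifices the
  power gain of variance moderation; with 6 replicates per group and
  cell-line-grade dispersion this costs little. Degenerate genes (zero
  within-group variance) are handled explicitly: p = 1 when the means
  agree, smallest representable p plus a flag otherwise.
- **Multiple testing.** Benjamini–Hochberg throughout, validated
  against an independent step-up implementation to 1e-12.

## The synthetic study and what it does (not) emulate

The generator plants complete ground truth, so detection performance is
measurable end to end. Defaults describe the emulated study at desk
scale and are fixed once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 20,000 | expressed-gene count of a brain cohort table |
| `frac_disease_de` | 0.05 | yields ~5% of genes at FDR < 0.1, mirroring 794/16,423 |
| `disease_effect_scale` | 1 | post-mortem contrasts are subtle; mean absolute logFC 1, minimum 0.25 (shifted gamma, shape 2) |
| `drug_effect_scale` | 2 | acute compound exposure of a clonal line produces much larger fold changes than a tissue contrast |
| `reversal_prob` / `concordant_prob` | 0.6 / 0.1 | per-drug reversal of ~60% of disease genes reproduces the observed per-drug set sizes proportionally |
| `reps_per_group` | 6 | upper end of the emulated 4–6 replicate design |
| `nb_dispersion` | 0.01 | biological CV 0.1, the standard figure for genetically identical cell-line replicates |
| `n_modules` × `module_size` | 2 × 10 | two dense interaction clusters planted among commonly reversed genes |

The disease table draws `logFC = direction × |effect| + ε` with
`ε ~ N(0, 1/√50)` and computes a two-sided normal p-value from the same
noise model, so effect size and significance are coupled by
construction. Drug arms are negative-binomial counts over log-normal
baselines (`meanlog` 5, `sdlog` 1.5, i.e. libraries of ~9M reads), with
the drug group's mean multiplied by `2^(direction × |effect|)`.

Deliberate non-goals of the generator: gene–gene expression
correlation, batch effects, drug–drug correlation (each drug responds
independently given the disease sign), dose–response structure, and
read-level simulation. Consequently, passing tests demonstrate that the
*algorithms* recover planted structure under clean sampling noise; they
do not certify performance on real data, where correlated counts make
BH less conservative, composition bias can be stronger, and drug
responses are correlated (the emulated study's common set — 218 of 886
at cohort scale — is proportionally larger than the independence model
produces).

Determinism: every generator operation derives its own substream from
the master seed, so a parameter object reproduces every table, GMT,
edge list and JSON byte for byte, regardless of which subset of
operations is called.

## Enrichment and network statistics

**Over-representation.** Exact hypergeometric upper-tail p-values (via
`phyper`, verified against direct binomial-coefficient enumeration for
every argument tuple with `N ≤ 60`), BH across the collection. Sets are
size-filtered (in-universe size within [10, 500]) *before* testing, so
the BH family contains only testable sets. The default universe is the
intersection of genes present in the disease table and in every drug
analysis after filtering — the measured background — rather than all
annotated genes; both choices are available. Ties in the result
ordering are broken by overlap size, then set id, making output order
reproducible.

**Network clusters.** "Clusters" are connected components of the
query-induced subgraph at combined score ≥ 0.7 (the high-confidence
preset, inclusive), among nodes that carry at least one edge; isolated
query genes are retained in the data but flagged, matching the usual
drawing convention. Components are reported sorted by size with a
lexicographic tie-break, and the partition is verified against a
breadth-first-search oracle.

**Edge enrichment.** The published analogue of this statistic comes
from a web service whose formula is not public, so the package defines
an explicit, testable substitute: the null distribution of induced edge
counts over uniform random gene sets of the same size drawn from the
declared background, with the +1 pseudo-count empirical p-value. This
asks exactly "is this gene set unusually connected?" without modelling
degree structure; a degree-preserving null is out of scope. Calibration
is checked by construction: on a heterogeneous-degree background the
p-value distribution under random queries is uniform (KS statistic
0.03 at 500 replicates in the test suite). The heterogeneous background
matters for the *check*, not the method: on near-regular graphs the
induced-edge count is heavily tied, and tied counts make the empirical
p conservative (stochastically larger than uniform), which a KS test
against the uniform would flag even though the estimator is doing
exactly what it should.

## Numerical and interface choices

- Gene identifiers are matched exactly after upper-casing and
  whitespace stripping; no alias or ortholog resolution. Duplicate
  records collapse to the smallest q (then largest |logFC|, then first
  occurrence).
- STRING-style scores on the 0–1000 integer scale are auto-detected
  (any value > 1) and divided by 1000; duplicate undirected pairs keep
  the maximum score; self-loops are dropped with a warning.
- The generator quantizes edge scores to the 0–1000 grid at write time
  (flooring, so background scores stay strictly below 0.7), making the
  file round-trip lossless.
- Empty results are legal everywhere (empty filter output, empty
  reversal sets, empty common set): the pipeline completes with the
  degenerate summary rather than failing, and the network stage is
  skipped with `enrichment_p = NA` when there is no query.
- Report writing is atomic (write-then-rename) and refuses to
  overwrite an existing report directory unless forced.

## Problem sizes used in validation

The test suite validates oracle equivalences at small, exhaustive sizes
(all hypergeometric tuples with `N ≤ 60`; 1,000 random BH vectors; 100
random 50-node graphs; all 220 or 495 subsets for exact permutation
enumeration), parameter recovery at 2,000 genes over 20–50 seeds
(per-drug precision and recall of planted reversal events both exceed
0.8 under the defaults with `disease_effect_scale = 1`), and end-to-end
determinism at the full default scale of 20,000 genes with 10,000
permutations. These sizes are the package's validation design: large
enough for the distributional checks to bind, small enough to run
routinely.

## Known limitations

- The Welch substitute has less power than moderated negative-binomial
  tests at 2–4 replicates; below 4 replicates per group its q-values
  should be treated cautiously.
- The permutation null ignores degree bias: a query of hub genes will
  look enriched. Interpret the p-value as connectivity relative to a
  *uniform* gene draw from the stated background.
- ORA treats gene sets as flat and independent; ontology hierarchy and
  set redundancy are not modelled.
- The generator's independence assumptions (across genes and across
  drugs) make the synthetic common set conservative relative to real
  correlated drug responses.
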