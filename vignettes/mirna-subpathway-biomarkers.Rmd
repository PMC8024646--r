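---
title: "Methods: miRNA-mediated subpathway biomarkers by directed random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mediated subpathway biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsubpath)
```

## The model

miRNAs act by repressing target genes, so a disease-relevant miRNA should
show expression changes *opposite* to those of its responsive targets. The
unit of analysis in this package is the **miRNA-mediated subpathway**: a
differentially expressed miRNA together with its significantly
differentially expressed, sign-discordant target genes that lie inside a
global directed pathway network (GDPN). Summarising each subpathway into a
per-sample activity value yields a feature space that is more reproducible
than single molecules, because it pools evidence over several genes and
weights them by their topological importance.

Three modelling ingredients:

**Topological gene weights.** The GDPN merges all supplied pathway edge
lists into one directed gene graph; a virtual node connected to and from
every gene keeps the transition matrix well defined (no empty rows). Gene
weights are the stationary distribution of a random walk with restart,
$P_{t+1} = (1-r)\,M^\top P_t + r\,P_0$, seeded by absolute t-scores of a
cancer-vs-normal differential test. The walk runs on the *edge-reversed*
graph relative to PageRank: mass flows from a gene's downstream targets
back to it, so regulators of large downstream programs gain weight even
when their own expression change is modest — the usual behaviour of hub
regulators.

**Inverse-regulation filter.** A target gene enters miRNA $j$'s subpathway
only if the gene is differentially expressed ($p < 0.05$), the miRNA is
differentially expressed ($p < 0.05$), the products of their t-scores is
negative, and the gene is a GDPN node. The sign constraint is the model's
core biological assumption: only targets consistent with repression count.

**Activity.** For subpathway $j$ with genes $g_1..g_{n_j}$,
$$a(miR_j) = \frac{\sum_i P_\infty(g_i)\,\mathrm{sgn}(t(g_i))\,z(g_i)}
                 {\sqrt{\sum_i P_\infty(g_i)^2}},$$
with $z(g_i)$ the z-scored expression row. The sign correction makes all
member genes contribute in the same direction, so activity differences
between groups accumulate rather than cancel.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r` | 0.7 | restart probability; the walk mixes local topology (small `r`) against the differential seeds (large `r`). Results are insensitive to moderate changes; the iteration contracts at rate `1 − r`. |
| `tol` | 1e-10 | max-norm convergence threshold of the walk. |
| `alpha_gene`, `alpha_mir` | 0.05 | raw two-sided p-value thresholds for genes and miRNAs. No multiplicity correction, by design: the filter is a screening step whose false positives are pruned later by classifier selection frequency. |
| `K` | 50 | candidate cap for greedy selection, ranked by activity t-test p-value. |
| `risk_threshold` | instances/3 | strict lower bound on selection frequency; 50 when there are 150 classifier instances. |

## Numerical and procedural choices

- **Welch t-test** by default (pooled-variance optional): expression
  variances routinely differ between tumour and normal groups. Orientation
  is cancer minus normal; the sign of an exactly-zero t is fixed at +1
  (such features never pass the p filter anyway).
- **z-scores** use the sample (n−1) standard deviation; constant rows are
  dropped with a warning. Degenerate (zero-variance-in-both-groups)
  features are flagged and excluded.
- **Activity denominator**: the L2 norm $\sqrt{\sum P_\infty^2}$, which
  makes activity invariant to rescaling of the walk weights — only their
  relative sizes can matter, since the stationary vector's absolute scale
  is an artefact of probability normalisation. A `sum_sq` variant (no
  radical) is exposed for comparison.
- **Node order** is sorted gene ids with the virtual node last, and all
  p-value ties break lexicographically by id, so every run is
  bit-reproducible from its seed.
- **Initial weights**: genes present in the network but unmeasured in the
  expression matrix get seed 0 yet remain walkable, so network topology
  does not shrink with measurement coverage. The virtual node's seed is 0.
- **Greedy acceptance is strict** (`AUC` must increase, not merely not
  decrease): on an AUC plateau nothing is added, which prevents unbounded
  accretion and means an exact duplicate feature can never enter.
- **SVM contract**: radial kernel with library defaults (cost 1,
  gamma = 1/#features), features z-standardised with training-fold
  statistics only, AUC computed from continuous decision values by the
  rank statistic with ties counted half (hard labels would make AUC
  degenerate).
- **Folds** are stratified (per class, shuffle and deal round-robin), so
  class proportions differ by at most one sample per fold; unstratified
  splitting frequently produces single-class folds under the strong
  imbalance typical of tumour cohorts.
- **Folds with no surviving subpathway** contribute an *uninformative
  classifier* (AUC 0.5, majority-class accuracy, empty selection) rather
  than an error. On signal-free data this is the expected outcome of an
  honest filter and is what makes null calibration computable.

## Evaluation protocols

The within-dataset protocol follows the nested design: five stratified
parts; parts 1–4 are the training set, split into three subparts; rotating
the tuning subpart yields three optimised classifiers per repetition; each
is scored on all five parts, giving 15 classifier-by-part instances per
repetition (150 for ten repetitions). Two modes are provided:

- `strict` (default): differential statistics, walk seeds and subpathway
  definitions are recomputed from the build subpart only, and the
  aggregate AUC averages only instances whose test part is the held-out
  fifth. This is an honest generalisation estimate.
- `pooled`: statistics computed once on the full dataset and all
  15 instances averaged, including parts overlapping the classifiers' own
  training data. This matches the literal protocol of the method this
  package implements, is optimistic, and is flagged `leaky` in reports.

Frequency counting uses classifier-by-test-part instances in both modes,
so one classifier's features are counted once per evaluation instance.

The cross-dataset protocol intersects the gene/miRNA feature spaces of two
bundles, derives subpathway definitions from the training bundle, applies
them to the test bundle's own z-scores, and scores five rotating-tune
classifiers per repetition on the entire external bundle (50 instances for
ten repetitions).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` produces a directed preferential-attachment graph
with randomised edge orientation (heavy-tailed degrees, like merged
curated pathways), a uniform many-to-many target map, and two-group
Gaussian expression on the z scale: each signal miRNA is shifted by
`mirna_effect_size` within-group standard deviations in a random
direction, and each of its planted targets by `gene_effect_size` in the
opposite direction.

Defaults describe the study conditions used throughout the package's tests
and acceptance script: 500 genes, 100 miRNAs, 60+60 samples, 10 signal
miRNAs, effect sizes 1.5 SD, unit noise. Two generator-specific choices
deserve justification:

- **`targets_per_mirna = 3`.** This is the number of *strongly responsive*
  planted targets per miRNA, not the size of a curated target list: miRNA
  repression at the mRNA level is mostly mild, and only a handful of
  targets shift enough to pass a p < 0.05 screen with sign discordance.
  Small target sets also keep a single subpathway from being a
  near-perfect classifier on its own, which keeps selection-frequency
  ranking informative. Planted target sets of distinct signal miRNAs are
  disjoint so planted effects never conflict, and planted targets are
  always graph members so they survive the network filter.
- **`structure_seed`.** The regulatory structure (graph, target map,
  signal identities and directions) and the sampling noise are seeded
  separately, with `structure_seed` defaulting to `seed`. Two bundles
  sharing `structure_seed` but differing in `seed` represent two cohorts
  of the same disease — the situation cross-dataset validation assumes.
  Independent structures would make cross-cohort transfer impossible by
  construction, which tests nothing about the method.

Not emulated: count-based noise models, normalisation artefacts, batch and
platform effects, correlated co-expression beyond the planted shifts, and
partial overlap of regulatory programs between cohorts. Passing tests on
this generator therefore demonstrate correctness of the algorithmic
machinery and recoverability of clean planted signal — not robustness to
the messiness of real sequencing data.

## Known limitations

- **Frequency concentration under strong signal.** With clearly separable
  planted effects, the tuning AUC of a one- or two-feature classifier is
  often exactly 1 on a 40-sample tuning set. The strict-increase greedy
  rule then stops, selected sets stay small, and selection frequency
  concentrates on whichever subpathways rank first per fold: a handful of
  planted subpathways exceed the frequency threshold while the rest trail
  below it, even though the held-out AUC is near 1. The frequency
  criterion is thus a *stability* statement, informative mainly in the
  regime where single features are imperfect classifiers; under very
  strong signal it understates how many true biomarkers exist.
- The literal nested protocol evaluates classifiers on parts overlapping
  their training data; use `strict` mode for generalisation estimates.
- Raw accuracy is reported alongside class-wise sensitivity/specificity
  because imbalanced cohorts make raw accuracy alone misleading.
- Dense transition matrices are used up to 2000 nodes and sparse ones
  above, with identical results; networks beyond ~50k nodes have not been
  profiled.

## Problem sizes used by the test-suite

Unit tests run on graphs of 20–200 nodes (where the walk can be checked
against a direct linear solve) and expression fixtures of ≤300 features.
Protocol-level checks use the default 500-gene bundle: ten-repetition
within-dataset runs (150 instances), ten-repetition cross-dataset runs
(50 instances), twenty signal-free label-permuted runs for null
calibration, and three deletion re-samples per fraction for the
edge-deletion robustness curve. These sizes were chosen so the full
pipeline is exercised end-to-end at the documented study scale.
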