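---
title: "Factorial BeadChip differential expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial BeadChip differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadanova)
```

`beadanova` analyses replicated 2×2 factorial BeadChip experiments:
two sexes crossed with two genotypes (wild type vs a tissue-specific
knockout), n = 4 biological replicates per cell, the 16 arrays split
across two chips. This vignette explains the statistical machinery, the
choices made where the method left room, and what the synthetic
benchmarks do and do not establish.

## The per-probe model

Each probe's log2 intensity is fitted with a three-way fixed-effects
ANOVA with interaction — sex, genotype, chip (batch) and sex:genotype —
by least squares on effect-coded factors. Because one model matrix
serves every probe, all probes are fitted in a single pass of matrix
least squares; per-term sums of squares come from the drop-one-term
residual comparison, which in the balanced layout coincides with every
classical ANOVA type. Assumptions are the usual ones: additive effects
on the log2 scale, homoscedastic Gaussian noise within a probe, and
independence across arrays. A probe with zero residual variance gets
p = 1 for every term rather than an undefined statistic.

Group comparisons are Fisher LSD contrasts: the difference of group
means divided by its standard error from the pooled residual mean
square, referred to a t distribution on the full model's residual
degrees of freedom (11 in the default design). No multiplicity
adjustment happens at the contrast step; the Benjamini–Hochberg step-up
is applied downstream, separately within the genotype-contrast family
and the sex-contrast family, because the two gene lists are reported
and interpreted independently. Contrast p-values, not omnibus F
p-values, feed the FDR call, since results are reported as directional
fold changes per contrast. Fold changes are the antilog of the log2
difference with the negative-reciprocal convention (−2.0 means halved).

Probes are collapsed to genes by the rule "a symbol is significant if
any of its probes is", reporting the fold change of the most significant
probe (ties broken by larger |FC|, then probe id, for determinism).
This is the only mapping consistent with reporting both probe-set and
unique-gene counts for the same threshold.

## Preprocessing

**Detection filter.** A probe is retained when at least one of the four
sex×genotype groups has `min_detected` (default 3) samples with
detection p below `alpha` (default 0.05). We deliberately read the
filter as *detected at p < 0.05* — a filter that kept probes whose
detection p-values exceed 0.05 would retain exactly the unexpressed
probes it exists to remove. Filtering precedes normalization so the
quantile anchors are not distorted by background-level noise probes.

**Cubic-spline normalization.** The exact spline used by the vendor
software is unpublished, so the package specifies a deterministic,
testable construction with the same intent: the reference profile is
the per-quantile mean of the sorted sample columns; each sample is
mapped through a monotone shape-preserving (Hyman-filtered) piecewise
cubic fitted through anchor pairs at `n_anchors` (default 13) evenly
spaced probabilities. Anchors are inverse-ECDF (type 1) quantiles —
actual order statistics — so a monotone map carries them exactly onto
the reference anchors, within-sample ranks are preserved, and the
operation is idempotent to floating-point precision. Constant columns
degenerate to a mean shift.

**Batch assessment and adjustment.** The chip term's per-probe p-values
are inspected; in `auto` mode adjustment triggers when the fraction
below 0.05 exceeds the 99th percentile of the null binomial fraction
(so a null data set triggers ~1% of the time). Adjustment subtracts
each probe's per-chip mean deviation from its grand mean, which leaves
grand means untouched and, in the balanced layout, leaves the other
factors' statistics unchanged. A chip perfectly confounded with a
design cell is an error, not a silent adjustment.

## Permutation calibration

The whole analysis is re-run on `k` (default 20) random re-combinations
of the sex×genotype labels. "Re-combination" is read as re-assignment
of the group labels to samples with the chip layout fixed: chips are
the nuisance stratum, and freezing them preserves the meaning of the
batch term under the null. Draws are uniform over assignments
preserving the 4/4/4/4 group sizes, without replacement, and never
equal to the real design. Two summaries are produced: fold-change
histograms of probes with contrast p < 0.05, binned by |FC| in steps of
0.1 from 1.0 (real analysis vs permutation mean), and counts of
significant unique genes across an FDR grid, with the recommended
operating level defined as the largest grid level at which every
permutation stays empty, capped at the conventional 0.05 when 0.05
itself qualifies.

## Enrichment, clustering, networks

Gene-set enrichment uses the hypergeometric upper tail
P(X ≥ k) for an overlap of k query genes with a set of size K in a
universe of size N. The default universe is the detection-filtered gene
list, not the whole genome — testing against the genome would reward
sets of well-expressed genes. BH runs across the sets of one
collection. Symbols are matched case-insensitively everywhere (mouse
vs human symbol case is the common failure mode).

Clustering z-scores each probe (mean 0, sd 1) and merges
agglomeratively under complete linkage — cluster distance equals the
distance of the two furthest members. The linkage is part of the
method; the metric is not stated by it, so Euclidean distance, the
default of the tools this workflow descends from, is used and is
configurable in spirit (the z-scored matrix is returned for reuse).
Zero-variance rows have no z-score and are excluded with a warning.
Dendrograms serialize to Newick with merge heights as branch lengths.

For transcription-factor networks, a TF qualifies by having a direct
`tf_target` edge into the root (significant) gene list, a receptor by
having a direct root-list neighbor, and each TF's subnetwork is the
union of *all* shortest directed paths to *every* eligible receptor at
the minimal distance; ties are kept, unreachable TFs are reported. The
source method's description of TF eligibility mentions both "direct
ligand(s)" and "direct target(s)"; a TF with a direct *target* in the
root list is the reading adopted, since TFs have targets, not ligands.
Traversal follows edge direction (TF→target, ligand→receptor);
self-loops never count as paths. The commercial scoring formula behind
such networks is proprietary, so subnetworks are scored by the
documented hypergeometric saturation tail — the probability of the
observed root-gene count in a node set of that size — which is *not*
numerically identical to the commercial score, only analogous.
The receptor view keeps root-list receptors and ligands with the
ligand→receptor edges among them, annotated up/down from the result
table.

## The synthetic generator

`effect_spec()`/`simulate_experiment()` generate the study conditions:
16 samples in the 2×2 layout with n = 4, dealt across 2 chips so every
cell is balanced within chips; per-probe baselines N(8, 1.5²) on the
log2 scale (log-normal intensities); additive spiked effects of
sign-mapped size log2|FC| (positive raises KO over WT and female over
male; interaction effects act only in the female-KO cell — the minimal
unambiguous parameterization); probe-specific chip shifts N(0, 0.1²);
residual noise sd 0.25, optionally probe-specific via
`residual_sd_range` since real array noise is probe-dependent; and 48%
of probes unexpressed, consistent with the roughly half of probes that
survive detection filtering on whole-genome expression arrays.
Detection p-values are generated marginally — Uniform(0, 0.049) for
expressed, Uniform(0.06, 1) for unexpressed probes — because the filter
only consumes threshold crossings; spiked probes are always expressed,
since an effect on an unexpressed probe is contradictory. Everything is
reproducible bit-for-bit from one integer seed.

What the generator does *not* emulate: intensity-dependent
mean–variance trends, probe cross-hybridization, correlated gene
modules, bead-level variance, or multi-probe genes (symbols map 1:1 to
probes). Consequently the passing benchmarks demonstrate correctness
and calibration of the *machinery* — uniform null p-values, controlled
FDR, accurate effect recovery — not robustness to every pathology of
real arrays. On real data the cubic-spline construction here will also
differ numerically from the vendor's unpublished one, which is why
reanalyses of deposited data should start from the deposited normalized
matrix.

## Numerical choices and problem sizes

Degenerate inputs: zero residual variance ⇒ p = 1; zero-variance rows
excluded from clustering; empty contrast groups, aliased model terms,
confounded batches, malformed files and out-of-range p-values are
errors with named causes rather than silent coercions. The benchmark
suite runs at desk scale, chosen to finish in minutes on one CPU while
keeping Monte-Carlo error small: 2,000 probes per simulated experiment
(4,000 for the histogram benchmark, where bins need occupancy), 50–100
simulation seeds for error-control summaries, 20 permutations per
ensemble, and brute-force oracle comparisons (explicit sums of squares,
step-up enumeration, exact tail sums, naive agglomeration,
breadth-first search) at sizes where the oracle is unquestionably
correct.

## Limitations

No empirical-Bayes variance moderation (each probe stands on its 11
residual df — limma-style shrinkage would help at n = 4 but is a
different method); fixed effects only; no background subtraction or
variance-stabilizing transform; the GEO reader handles the
series-matrix layout, not full SOFT; and deposited matrices may be raw
or normalized — the reader cannot tell, so the scale tag is the
caller's responsibility.
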