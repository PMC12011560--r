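---
title: "Methods: repertoire analytics and the stacked ensemble classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire analytics and the stacked ensemble classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tcrstack` analyses T-cell receptor (TCR) repertoires given as clonotype
tables — one row per unique CDR3 amino-acid rearrangement with its V/J genes,
read count and clone fraction — and classifies samples into two groups with a
two-layer stacked ensemble built on motif and sequence-descriptor features.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, so that results can be interpreted and
reproduced.

## Input model and clean-up contract

A repertoire is a tibble of clonotypes with attributes `sample_id`, `chain`
(TRB/TRD/TRG, derived from the V-gene prefix) and an optional group `label`.
On load (`read_clonotype_table()`, `as_repertoire()`):

* CDR3 sequences containing characters outside the 20-letter amino-acid
  alphabet are dropped. MiXCR marks out-of-frame and stop-containing
  junctions with `_` and `*`; such sequences cannot be k-merised or encoded,
  so removal is the only consistent treatment.
* Duplicate CDR3s are merged: counts and fractions are summed and the V/J
  genes of the most abundant contributor are kept. The same rule is applied
  by the read simulator when it regroups sampled reads, so real and
  simulated inputs are treated identically.
* Fractions are renormalised to sum to 1, rows are sorted by descending
  fraction, and `clone_id` is reassigned as the 0-based rank.

Counts are accepted as reals because some exporters emit fractional weights;
the simulator always emits integers.

## Diversity statistics

For clone fractions $p_i$ (summing to 1):

* Shannon diversity $H = -\sum_i p_i \ln p_i$ (natural logarithm; zero
  fractions contribute 0).
* Simpson diversity implemented as the Gini–Simpson index
  $D = 1 - \sum_i p_i^2$, the probability that two random reads come from
  different clones. The label "Simpson diversity" is used
  inconsistently across the field; the Gini–Simpson form is the standard
  estimator and the one this package computes.
* Richness $R$ = number of distinct clonotypes; evenness $E = H / \ln R$,
  defined as 0 when $R = 1$.
* Top clone fraction $\max_i p_i$; clones-to-half = the smallest $k$ such
  that the $k$ largest fractions sum to strictly more than 0.5.

All metrics are tested against independent brute-force summation to 1e-12.

## Group-level descriptive features

**V-J usage.** Clonotypes are tallied per (V, J) pair and group; pairs
supported by fewer than `min_clones` (default 100) clonotypes across the
cohort are excluded, and the remaining per-group frequencies are
renormalised to sum to 1. Between-group preference is
$\log_2(f_A + \epsilon) - \log_2(f_B + \epsilon)$ with $\epsilon = 10^{-6}$;
the pseudocount avoids infinities for pairs absent from one group while
barely perturbing common pairs, and computing the difference of logs (rather
than the log of the ratio) makes the map bit-exactly antisymmetric under
group swap.

**Positional composition.** For clones with CDR3 length in [5, 24], the
clone-fraction-weighted frequency of each amino acid at each 1-based
position; each position column is normalised over the clones long enough to
reach it. Preferences between groups use the same log2 contrast.

**CDR3 length.** The per-sample statistic is the unweighted mean CDR3 length
over distinct clonotypes; chains are compared between groups with a Welch
two-sided t-test. When both groups have zero variance the statistic
degenerates to 0 (equal means, p = 1) or ±Inf (p = 0).

**Motifs.** Overlapping 5-mers are counted over all clonotype CDR3s. Each
distinct clonotype contributes once by default; clone-count weighting is
available (`weighted = TRUE`) because either convention is defensible
for abundance weighting. The raw per-sample total is therefore
$\sum_c \max(0, \mathrm{len}(c) - 4)$ — a conservation law the tests check.
Differential motifs are found one-vs-rest per group after library-size
normalisation (counts scaled to 10,000 per sample, then log1p): a two-sided
Wilcoxon rank-sum test per motif, retaining motifs with raw p < 0.01,
in-group detection ≥ 10% and average log2 fold-change ≥ 0.25. These
defaults mirror the Seurat marker-detection pipeline the analysis is modelled
on; only the p threshold is exposed as the headline parameter. No
multiple-testing correction is applied, matching the `return.thresh`
semantics of that pipeline. The Wilcoxon p-value is computed by full
enumeration of the $\binom{n}{n_1}$ label assignments whenever both groups
have at most 8 samples (valid under ties, using midranks), and by the normal
approximation with tie and continuity corrections otherwise.

**Overlap.** The repertoire-overlap matrix uses the Jaccard index on CDR3
amino-acid sets by default (an `overlap` coefficient is available); Jaccard
is the most common default for repertoire sharing. Motif-overlap curves rank each group's motifs by
fraction (ties broken lexicographically so rankings are reproducible) and
report $|top_n(A) \cap top_n(B)| / n$.

## Sequence encoding

No pretrained protein language model is bundled: instead the package
defines a pluggable encoder interface
(`encoder_spec()`) with a deterministic default, and the pipeline contract —
select the 100 most abundant CDR3s per sample, encode each, aggregate,
reduce by PCA to 50 components — is preserved around whichever encoder is
plugged in. The default descriptor encoder is a 41-dimensional deterministic
map: 20 amino-acid composition frequencies, the 5 Atchley-factor means over
the whole sequence, the 5 Atchley-factor means over each of the N-terminal,
central and C-terminal segments, and the length. Terminal segments take
$\min(3, \lfloor L/2 \rfloor)$ residues so that even very short sequences
retain N- versus C-terminal contrast; the central segment is the remainder
and contributes zeros when empty. Aggregation over the top sequences is an
unweighted mean by default (a fraction-weighted mean is available); the
unweighted mean keeps the embedding insensitive to the steepness of the clone-abundance
distribution.

## PCA

Feature columns are centred and scaled to unit variance (constant columns
get unit scale so they map to zeros). Components come from the SVD of the
standardised matrix — computed via the eigendecomposition of the n×n Gram
matrix when features outnumber samples, which is exact and much faster for
motif-scale matrices. The number of components is
$\min(50, n_{samples}-1, n_{features})$. Signs follow a deterministic
convention (the largest-magnitude loading of each component is positive) so
repeated fits are identical. Projection aligns columns by name, so column
order never matters; PCA is always fitted on training samples only and
applied to held-out samples.

For the classifier's motif block, motifs detected in fewer than
`min_motif_samples` (default 2) training samples are excluded before PCA:
a k-mer seen in a single sample carries no between-sample information, and
on synthetic cohorts ~85% of the 5-mer vocabulary are such singletons, which
would otherwise dominate the computation as pure noise dimensions.
Library-size normalisation still uses every motif the sample contains.

## The two-layer stacked ensemble

Two feature blocks enter the first layer separately: the PCA-reduced motif
block and the PCA-reduced CDR3-embedding block. Four base families are
fitted over hyperparameter grids on each block:

* **GLM** — elastic-net logistic regression (`glmnet`); `alpha` ∈
  {0, 0.2, 0.4, 0.6, 0.8, 1} mixes L2 and L1 penalties; the penalty strength
  is chosen by internal cross-validation on class-stratified inner folds.
* **XGBoost** — `nrounds` ∈ {100, 200}, `max_depth` ∈ {3, 6}, `eta` ∈
  {0.01, 0.1}, `gamma` ∈ {0, 0.1}, `subsample` ∈ {0.7, 0.8, 0.9}
  (48 points).
* **Random forest** — `mtry` ∈ {2, 4, 6}, `ntree` ∈ {500, 1000}. The small
  `mtry` values are kept deliberately even though each block has ~50
  features.
* **Neural network** — single hidden layer (`nnet`) with logistic output,
  `size` ∈ {3, 4, 5}, `decay` ∈ {0.001, 0.01, 0.1}, 2000 iterations.

That is 69 grid points per block. Every point is scored by stratified
5-fold cross-validated AUC on the training set; out-of-fold scoring is the
choice that avoids selection bias. The 5 best points per family per block
are kept — 4 families × 2 blocks × 5 = 40 models. Ties are broken by the fixed family order GLM, XGB, RF, NN and
then by grid order. The 40 out-of-fold score columns form the second-layer
design matrix, so stackers never see scores produced by models trained on
the same sample; the 40 selected models are refitted on the full training
set for prediction time. The second layer fits the same grids on the
40-column matrix and keeps the 10 points with the best cross-validated AUC
overall; the second-layer grids default to the first-layer grids. The final
score is the arithmetic mean of the 10 stacker probabilities, and a sample
is called positive when the score is strictly above the threshold
(default 0.5; stricter cut-offs such as 0.75 are a parameter, not a
default).

Degenerate fits (e.g. an all-constant design) fall back to a constant
predictor at the class base rate rather than erroring, so resampling
harnesses never abort mid-run.

**Reduced grid profiles.** `model_grids("fast")` and
`model_grids("minimal")` shrink the grids (every family keeps at least 5
points so the selection arithmetic is unchanged) and lighten the fitting
controls (shorter neural-network optimisation, shorter glmnet lambda paths,
3 inner folds). They exist for repeated-refit harnesses and quick runs; the
`"full"` profile is the default everywhere.

**Determinism.** Every stochastic step receives a seed derived
deterministically from the pipeline seed (fold assignment, each model fit,
bootstrap and resampling draws), so identical seeds give identical model
selections and scores.

## Evaluation

AUC is the rank (Mann–Whitney) estimate — ties get half credit — with ROC
points at every distinct threshold. Confusion statistics use the strict
threshold rule; accuracy, sensitivity and specificity carry exact
Clopper–Pearson intervals and the AUC a stratified bootstrap percentile
interval (2,000 resamples, seeded). Two resampling harnesses are provided: repeated stratified
down-sampling of a fitted model's predictions (default fraction 0.8, exposed as a
parameter), and repeated stratified
train/test splits with a full pipeline refit per split (default 70/30). The split harness
accepts reduced grid profiles because refitting the full grids 1,000 times
is not a desk-scale computation.

## Read-level simulator

From a source repertoire: keep $\lceil \mathrm{keep\_frac} \cdot R \rceil$
uniformly random clones (default 50%), renormalise their fractions, draw
`n_reads` (default $10^6$) reads as a single multinomial draw — equivalent
in distribution to n independent categorical draws, but far faster — group
the reads by CDR3, recompute fractions as count/n_reads, sort and re-rank.
Clones drawn zero times are absent from the output, counts sum to exactly
`n_reads`, and the V/J genes of a regrouped CDR3 come from its most
abundant contributor. Group-level simulation pools all samples with the
requested label into one source table (fractions summed then renormalised,
weighting samples equally) before simulating, treating the group as one
concatenated table. Per-sample simulation can be had by passing a
single-sample cohort.

## Synthetic cohorts

`generate_cohort()` plants controllable group differences so every stage is
testable without external data:

* Clone abundances follow a Zipf law $p_i \propto i^{-s}$ with exponent 1.2
  by default — a standard heavy-tailed model for clonal repertoires.
* CDR3s are random amino-acid strings with canonical C…F anchors, lengths
  from a discretised normal (sd 1.5) centred in the configured range
  (default 8–20, within the 5–24 band of the positional analyses); a length
  shift moves the target group's mean.
* Planted 5-mers are inserted at a random interior position of a clone with
  probability `base_motif_rate` (default 0.05) times the enrichment factor
  in the target group.
* V-J pairs are drawn from a categorical distribution over the configured
  gene pools, tilted by $2^{\mathrm{effect}}$ for skewed pairs in the
  target group.

The generator reproduces byte-identical cohorts under a fixed seed, and
`planted_effect_report()` measures the realised effect sizes. What it does
**not** emulate: V(D)J recombination statistics (no insertion/deletion
machinery, no germline-templated sequence), public clones shared between
samples, chain-specific length and gene-usage structure, or sequencing
error. Passing tests on these cohorts therefore demonstrates that the
machinery recovers planted signal of the stated magnitude at the stated
sample sizes — not that real tumour cohorts carry such signal.

## Problem sizes used by the test-suite

The test suite and the acceptance script exercise the full pipeline at
60 vs 60 samples with 300 clonotypes each and a 3× planted motif
enrichment, training on a stratified 70% split with the `fast` grid
profile, and run the resampling harnesses at 25 iterations with the
`minimal` profile; these sizes keep a complete run within a typical CI
budget on one CPU while leaving the selection arithmetic (69 grid points
per block, 40 + 10 selections) identical to the full configuration.
Determinism is verified by refitting at identical seeds; statistical
fidelity of the simulator is verified against 3σ binomial bounds over 100
seeded runs.

## Known limitations

* The default encoder is a fixed physicochemical descriptor, not a learned
  representation; plugging in a protein language model is supported through
  `encoder_spec(fn = ...)` but no weights are shipped or downloaded.
* Scores are not calibrated probabilities; the averaging of heterogeneous
  stacker outputs preserves ranking far better than calibration.
* Multiclass tasks are out of scope; staging-type questions must be reduced
  to binary contrasts.
* Exact Wilcoxon enumeration is limited to groups of at most 8 samples;
  beyond that the corrected normal approximation is used.
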