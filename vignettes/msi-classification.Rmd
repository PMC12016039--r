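---
title: "Classifying microsatellite instability from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microsatellite instability from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiRNA)
```

## The problem

Microsatellite instability (MSI) — hypermutability of short tandem repeats
caused by deficient mismatch repair — is a pan-cancer biomarker for
immunotherapy response. It is conventionally typed from DNA, but mismatch
repair loss also leaves a transcriptional footprint, so MSI status can be
called from the expression data that many studies already have: microarray
intensities, bulk RNA-seq (FPKM/TPM/RSEM), or single-cell RNA-seq. msiRNA
implements such a transcriptome-based classifier end to end: informative-gene
selection, an SVM that emits MSI probabilities, a Youden-index decision
threshold, and a single-cell pathway that aggregates per-cell scores into a
sample-level call.

Because all expression units are accepted "as given", every observation
(sample or cell) is first placed on a common scale: values are shifted by 1
and log2-transformed, then each observation's profile is standardized to mean
0 and standard deviation 1. Standardization uses the population form of the
standard deviation (divisor = number of genes) so the unit-variance
postcondition is exact rather than approximate; this is a pure convention —
any downstream rank statistic is unaffected.

## Informative-gene selection

Given a labeled training cohort (m samples, n of them MSI), genes pass
through four gates:

1. **Blacklist and expression floor.** Ribosomal (`RPL/RPS/MRPL/MRPS`) and
   mitochondrially encoded (`MT-`) genes are removed by symbol prefix, as are
   genes with mean raw expression below `low_expr_min_mean` (default 1.0, the
   conventional 1-FPKM expressed/not-expressed boundary; the value is a flag
   because the appropriate floor depends on the unit of the input matrix).
2. **Rank-sum test.** A two-sided Wilcoxon rank-sum test on the z-scored
   values, keeping genes with `p < 0.01`. The exact null distribution is used
   when both groups have at most 8 tie-free values; otherwise the normal
   approximation with tie and continuity correction.
3. **Fold change.** The absolute log2 ratio of MSI to MSS group means must
   exceed 0.5. This statistic needs strictly positive means, which per-sample
   z-scores cannot guarantee, so it is evaluated on the log2(x+1) scale
   *before* standardization. This is a deliberate reading of an ambiguous
   step: computing a ratio of group means on a mean-centered scale is
   undefined whenever a group mean is non-positive, and the log2(x+1) scale
   is the closest well-defined one in the transformation chain.
4. **Per-gene AUC.** The rank-based (Mann–Whitney) AUC of the gene for
   separating MSI from MSS, folded as `max(a, 1 - a)` so up- and
   down-regulated genes are treated symmetrically, must exceed 0.65.

Genes surviving all four gates are *candidates*. Each candidate is then
scored by the mean held-out accuracy of two single-feature classifiers — an
RBF-kernel SVM and a 100-tree random forest — over stratified 10-fold
cross-validation (folds are reduced to the minority-class size when that is
smaller, and the same seeded fold assignment is reused for every gene so
scores are comparable). The candidates are ranked by each score
(descending, gene id as the deterministic tiebreak) and the final informative
set is the intersection of the top `ceiling(top_quantile * n_candidates)`
genes of the two rankings, with `top_quantile = 0.25` by default.

A structural consequence worth stating plainly: the final set can never
exceed a quarter (at defaults) of the candidate list. When the candidate
list is small — as in simulations where only the planted genes carry signal —
the selected set is correspondingly small. The intersection buys specificity,
not sensitivity: in the package's simulations it has never admitted a
false-positive gene, but it also caps how many true genes can be returned.
With `top_quantile = 1` the final set equals the candidate list.

The cross-validation metric is mean accuracy; this is an assumption (the
ranking criterion is otherwise underdetermined), and because the CV stage is
only a ranking, any monotone accuracy-like metric would produce similar sets.

## Classifier

Cancer cohorts are MSI-imbalanced (MSI fractions of 5–30% are typical), so
the training features — z-scored values of the informative genes — are first
balanced by SMOTE: synthetic minority samples are drawn as
`x + u (x_nn - x)` with `x` a random minority sample, `x_nn` one of its
`k = 5` nearest minority neighbors (Euclidean; `k` is clamped to minority
size − 1), and `u ~ Uniform(0,1)`. Majority and original rows are never
modified.

The classifier is a C-SVM with RBF kernel, `C = 1`, and kernel width
`gamma = 1 / (p * var(X))` (the standard scale heuristic over the `p`
features of the balanced training matrix). Probabilities come from a Platt
sigmoid `P(MSI | f) = 1 / (1 + exp(A f + B))` fitted on decision values `f`
collected over stratified 5-fold cross-validation of the balanced training
set, with Platt's regularized targets; the sigmoid is optimized by BFGS from
a fixed starting point, so the entire training path is deterministic given
the seed. Fitting the calibration ourselves (rather than using the SVM
library's built-in probability machinery, which draws from a C-level random
stream that cannot be seeded from R) is what makes retraining with the same
seed byte-identical on disk, and lets the model file inline every learned
constant — support vectors, dual coefficients, intercept, sigmoid — as plain
JSON numbers that round-trip across languages.

The MSI/MSS cutoff is the Youden-index threshold: the cutpoint `t`
maximizing `J(t) = sensitivity(t) + specificity(t) - 1` by exhaustive search
over the midpoints of adjacent distinct scores plus the 0/1 boundaries, with
ties broken toward the larger `t` (higher specificity). Two choices here are
deliberate:

* The threshold is calibrated on the **original, pre-SMOTE** training
  samples. Synthetic minority points would inflate the apparent sensitivity
  of low cutoffs and distort the operating point.
* Calibrating on training rather than held-out data is an assumption; the
  alternative would leak test labels into the decision rule.

A score exactly equal to the threshold calls MSI (determinism at the
boundary).

At prediction time the model applies its recorded preprocessing recipe —
log2 and per-sample z-score computed over **all** genes present in the input
matrix — and only then restricts to its gene panel. This mirrors training
but means a sample's score depends (through its own standardization) on the
full gene panel of the matrix it arrives in; matrices measured on very
different panels are therefore not strictly comparable, which is inherent to
per-sample standardization and not correctable post hoc. Up to 10% of model
genes may be missing from the input, in which case their z-scores are imputed
as 0 — the cohort-neutral value — with a warning; beyond 10% the panel is
considered mismatched and prediction refuses with the missing genes named.

## Single-cell pathway

Cells of one sample are processed as:

1. **Quality filter:** keep cells with at least 20% of genes detected
   (value > 0). If fewer than 20 cells pass, keep the top
   `min(20, n_cells)` cells by detected fraction instead (stable sort,
   original column order as tiebreak). The 20%/20-cell defaults are the
   method's stated operating point and are exposed as recipe parameters.
2. **Dropout imputation:** within each cell, zeros are replaced by the mean
   of that cell's detected (nonzero) values. The description this rule comes
   from is ambiguous on two axes — whether the averaged values include the
   zeros being replaced, and whether "sample" means the cell or the whole
   scRNA-seq sample — so both alternatives are available via the `mean_of`
   and `per` arguments of `impute_dropouts()`; the default (nonzero,
   per-cell) avoids the self-referential reading and is the standard
   detected-gene surrogate. Imputation happens on the raw scale, before the
   log2/z-score chain, so bulk and single-cell observations share one
   transformation path.
3. **Scoring and aggregation:** each retained cell is scored by the bulk
   model exactly as a bulk sample would be, and the sample-level MSI score is
   the arithmetic mean of the cell scores. The sample status applies the bulk
   model's Youden threshold to that mean; no separate single-cell threshold
   is introduced.

## The simulator

`simulate_bulk()` and `simulate_single_cell()` generate the labeled cohorts
used by the test suite and the acceptance script. Baseline expression is
log-normal — gene `g` has raw value `exp(N(mu_g, sigma_g)) - 1` clamped at 0,
`mu_g ~ N(2, 1)`, `sigma_g = 1` on the natural-log scale — an FPKM/TPM-like
continuous scale chosen to match the log2 transformation chain (a
negative-binomial count model would add realism for UMI counts but none of
the pipeline's statistics consume counts). Planted informative genes shift
their log-mean by `delta * sigma_g` in MSI observations; half of them are
down-regulated so the AUC direction folding is always exercised. Single-cell
samples draw each cell as MSI-like with the sample's MSI-like fraction as
probability, apply independent per-entry dropout, and force a fraction of
cells to ~10% detected genes so the quality filter has real work.

Gene-level parameters (baselines, planted set, directions) are a function of
the configuration seed alone, while sampling noise takes a separate cohort
seed — so train and test cohorts, or bulk and single-cell cohorts, can share
one gene panel with independent noise.

The reference study conditions — used by default and throughout the
acceptance checks — are 500 genes with 20 planted informative genes at
`delta = 2`, 60 MSI / 90 MSS bulk samples (a 40% MSI fraction keeps SMOTE
active without making the problem degenerate), and single-cell cohorts of
10 MSI-type samples (70–95% MSI-like cells) plus 10 MSS-type samples (0–10%),
200 cells each, 30% dropout, 10% low-quality cells. The acceptance script
additionally runs ten independent train/test replicates (150 training / 100
test samples each) for held-out performance and three `delta = 0` replicates
for null calibration; these sizes make the whole script run in well under a
minute per replicate while leaving the binomial noise in each estimate far
smaller than the margins being checked. Under `delta = 0` the selection
stage correctly finds nothing (it raises an empty-intersection error), so
the null check trains on the planted gene ids directly and verifies the
*classifier* is calibrated at chance (held-out AUC 0.5).

What the simulator does **not** emulate — and hence what passing tests do
not establish about real tumors: gene–gene correlation (each gene is
independent given its label), batch and platform effects, cell-type
composition structure within samples, and count-level noise. The simulation
validates the machinery (selection specificity, calibration, determinism,
aggregation), not clinical performance.

## Numerical choices and degenerate inputs

* Zero-variance observations standardize to all-zero with a warning rather
  than erroring (the z-score limit as spread vanishes, in the mean-centered
  sense); constant-score Youden inputs resolve by the boundary rule.
* Zero-denominator confusion metrics (e.g. precision with no positive calls)
  report 0 with a warning instead of NaN, keeping reports machine-parseable.
* Duplicate gene symbols on input collapse to the highest-mean row (probe
  sets map many-to-one; keep-max preserves signal).
* All ranking ties (CV scores, QC fractions) break deterministically —
  lexicographic gene id, original column order — so identical inputs and
  seeds reproduce outputs byte for byte.
* Score round-trips through the JSON model file are exact to well below
  1e-9; all learned constants are written at full double precision.

## Known limitations

* **Threshold transfer to single cells.** Dropout plus mean-imputation
  compresses per-cell z-scores relative to the bulk profiles the model was
  trained on, so mean cell scores are shrunk toward the middle. In the
  reference simulation the ranking of samples is perfect (sample-level AUC
  1.0 and scores strictly increasing in the MSI-like cell fraction), but the
  bulk-calibrated threshold sits above all MSI-type sample means, i.e.
  absolute single-cell calls are conservative. The package intentionally
  does not introduce a separate single-cell threshold; users comparing
  cohorts should work with the scores.
* **Panel dependence.** Per-sample standardization ties a score to the gene
  panel of its matrix (see above).
* **Small selected sets.** The top-quantile intersection bounds the
  informative-set size by `ceiling(top_quantile * candidates)`; with few
  candidates, expect few genes (raise `top_quantile` if recall matters more
  than specificity).
* The blacklist is prefix-based on human gene symbols; other organisms or
  probe-level identifiers need a custom pattern set.

## Session info

```{r}
sessionInfo()
```
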