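---
title: "Methods: building aging clocks from circulating small noncoding RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building aging clocks from circulating small noncoding RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncclock)
```

# The problem

Extracellular small noncoding RNAs (sncRNAs) — miRNAs, tRNA fragments,
piRNAs, snRNAs, snoRNAs, scRNAs — circulate in plasma and serum and their
abundance profile shifts with chronological age. `sncclock` implements a
complete analysis path from a gene × sample count matrix to an "aging
clock": sample quality control, TMM-scaled CPM normalization,
empirical-Bayes batch correction, a maximal-information-coefficient (MIC)
screen for linear *and* nonlinear age association, cross-validated age
regression with five model families, and a rank-sum consensus over the
tree ensembles' impurity importances that names the core age-related
sncRNAs.

Because public exRNA compendia are controlled-access and batch-ridden, the
package is built around a synthetic-cohort generator with complete ground
truth; every stage is validated against that truth or an independent
oracle.

# The synthetic cohort

`simulate_cohort()` draws counts for gene $g$ in sample $s$ as

$$K_{gs} \sim \mathrm{NB}\!\left(\mu = L_s\, p_{gs},\ \phi\right),
\qquad p_{gs} = \mathrm{softmax}_g(\eta_{gs}),$$

where $L_s$ is a log-normal library size and the natural-log expression
score decomposes as

$$\eta_{gs} = b_g + f_g(z_s)\,[\text{gender matches}] + \gamma_{g,b(s)}
+ \sigma_\varepsilon\, c_{b(s)}\, \varepsilon_{gs}.$$

Design choices worth stating explicitly:

* **Standardized age** $z = (\text{age} - 59.5)/22.9$: the midpoint of the
  20–99 year range and the standard deviation of a uniform age
  distribution over it, so one unit of effect size means the same
  log-expression change for every response shape.
* **Response shapes** $f_g$: linear ($z$), monotone-saturating
  ($\tanh z$), quadratic ($z^2 - \overline{z^2}$, centred so the Pearson
  correlation with age is ≈ 0 while the association is strong — this is
  what the MIC screen exists to catch), and step ($\mathbf{1}[z>0]-0.5$).
* **Effect sizes**: magnitudes are drawn as
  $|N(\text{effect\_size\_sd},\ \text{effect\_size\_sd}/3)|$ with a random
  sign and floored at 10% of the scale. The scale parameter names the
  *typical* slope rather than the standard deviation of a zero-centred
  draw; a zero-centred draw would label genes "age-linked" whose effect is
  numerically negligible, contradicting the ground-truth contract that
  age-linked genes are detectably age-linked.
* **Batch effects** are additive per gene per batch on the log scale
  (location) while batch scale factors multiply the residual log-noise —
  deliberately the generative model that ComBat assumes, so batch-effect
  recovery is a fair test of the correction, not of model mismatch.
* **Compositional coupling**: the softmax makes expression proportions sum
  to one per sample, as CPM data do; an abundance gain in one gene
  depresses all others. The miRNA-down / tRNA-up composition trend with
  age (0.25 natural-log units per standardized age, applied to baselines)
  reproduces the aggregate biotype shift reported for circulating sncRNA.
* **Defaults** (300 donors, 1000 genes, 4% age-linked, dispersion 0.2,
  residual log-noise 0.3, three batches, library sizes ~2M reads): chosen
  once as a realistic desk-scale cohort; real per-gene dispersions and
  library-size distributions for the public exRNA data are not published,
  so these are conventional RNA-seq values, not calibrated ones.

What a green test on this generator does *not* establish: adapter/alignment
artifacts, zero-inflation beyond the NB, gene–gene correlation structure
other than compositional coupling, and non-uniform age distributions are
not emulated.

# Quality control and normalization

`qc_filter()` retains a sample iff transcriptome-aligned reads ≥ 100,000
(inclusive) and transcriptome/total read ratio > 0.5 (strict) — the
printed inclusivities of the ERCC-style criteria are honoured exactly.

`tmm_factors()` implements trimmed-mean-of-M-values normalization from
scratch: reference sample = the one whose 75th-percentile count fraction
is closest to the mean; per sample, gene-wise log-ratios M and average
log-abundances A over doubly-positive genes; 30%/5% two-sided trims on M
and A; inverse-asymptotic-variance weighted mean of surviving M values;
factors rescaled to geometric mean one. The test suite demands agreement
with edgeR's implementation to 1e-6 — edgeR is the oracle, never the
implementation. Whether the original analysis applied TMM factors or raw
library sizes to CPM is not documented; both are supported and TMM is the
default (`use_tmm` in `pipeline_config()`).

`detection_filter()` reads "within an age group" existentially: a gene is
expressed if *some* age group shows ≥ `min_cpm` CPM in ≥ 30% of its
samples (young 20–30, adult 31–60, aged 61+, ages integral, intervals
closed). An `all_groups` scope is available. Expressed (≥ 1 CPM) is by
construction a superset of highly expressed (≥ 10 CPM).

# Batch correction

`combat_correct()` is the parametric empirical-Bayes location/scale model:
per-gene standardization against the batch-weighted grand mean and pooled
variance, per-batch method-of-moments priors (normal for location,
inverse-gamma for scale), iterated conditional EB updates to convergence
(`tol` = 1e-4 relative), then back-transformation. Correction operates on
`log2(CPM + 1)` by default — the additive scale the model assumes — and
maps back by exponentiation floored at zero; `scale = "raw"` exists for
sensitivity analysis. No biological covariate is protected by default
(the original analysis does not state that age was protected);
`protect_age_group = TRUE` or an explicit covariate data frame adds a
protected design.

Two numerical caveats discovered while validating:

* **Exact idempotence is unattainable.** The EB prior always re-shrinks
  the residual sampling noise of batch means, so running the correction
  twice moves entries by a small fraction (~2–5%) of the first pass, not
  by < `tol`. The tests assert the honest version: a second pass changes
  at most 5% of the first pass's largest change.
* **A batch shift that is constant across genes** is absorbed into the
  batch-level prior mean and removed, but each gene keeps roughly half its
  sampling noise (shrinkage weight ≈ ½ when the across-gene variance of
  batch effects is pure noise). Per-gene *heterogeneous* shifts give
  shrinkage weights ≈ 1 and post-correction batch-mean differences below
  0.05 — that is the regime the recovery test checks.

`pca_diagnostic()` reports sample scores on the first two principal
components and the share of PC1 variance explained by batch, the standard
before/after figure of merit.

# The MIC/TIC screen

`characteristic_matrix()` computes, for every grid shape $(k, l)$ with
$kl \le B(n) = \lceil n^{0.6} \rceil$ and $k, l \ge 2$, the maximal mutual
information of a $k \times l$ grid normalized by $\log_2 \min(k, l)$. One
axis is equipartitioned (never splitting ties); the other is optimized by
a dynamic program whose cut points are restricted to *clump* boundaries —
maximal runs of points sharing an x value or falling in the same y row.
That restriction is lossless (an optimal column boundary never splits a
clump); the only approximation is merging clumps into at most $c \cdot k$
superclumps ($c = 15$) when there are more. Both axis orientations are
computed and the elementwise maximum taken, which makes MIC symmetric.
The DP exploits the decomposition
$I(P;Q) = H(Q) + \sum_{\text{columns}} g(\text{col})$ with the global
sample size as denominator, so each column's contribution is independent
and prefix-optimal substructure holds exactly.

MIC = the maximum entry. TIC is reported two ways: the **mean** over
computed entries (a [0,1] statistic, used for thresholding) and the raw
**sum**. The screen keeps genes with MIC ≥ 0.7 *and* TIC ≥ 0.7
(inclusive; a `strict` flag gives the strictly-greater reading, since the
two printed sources disagree on inclusivity). It runs on the expressed
(≥ 1 CPM) set after batch correction.

**A structural property worth knowing.** Because a mean never exceeds a
maximum, mean-TIC ≤ MIC always, so the dual threshold is effectively a
TIC threshold. For a *symmetric non-monotone* response the $(k, 2)$ grid
shapes carry almost no information (the two age halves have identical
expression distributions), capping mean-TIC near 0.70 even for a
noiseless quadratic. The consequence — quadratic and step genes pass on
MIC but fail the dual screen once any noise is present — is measured and
documented in the tests rather than hidden: the end-to-end screen
sensitivity on the committed strong-signal cohort is ~0.68 against a 0.8
aspiration, with zero false positives. Users wanting the nonlinear genes
the MIC was chosen to find should screen on MIC alone or use the raw-sum
TIC; both are one argument away.

Validation is oracle-first: the characteristic matrix is checked (i) to
machine precision against an exact brute-force maximizer over *all*
contiguous partitions at small n, where the clump DP is provably exact,
and (ii) to 1e-6 against an independently coded pure-R implementation on
50 random pairs at n = 200. Invariance under strictly increasing
transforms, orientation symmetry, and budget monotonicity are asserted
exactly.

# The clock

`stratified_age_folds()` assigns folds round-robin within each age group
after a seeded shuffle, so per-group fold sizes differ by at most one —
the stratification that keeps small aged groups represented in every
training split.

`fit_predict_cv()` trains on k−1 folds and predicts the held-out fold;
reported R² (1 − SSE/SST on held-out predictions), RMSE and MAE (years)
are out-of-fold averages. A train/test-split reading of the published
numbers is possible but the out-of-fold average is the default, being the
stabler quantity. Five model families are supported: ordinary least
squares; elastic net (glmnet, scikit-learn's penalty parameterization,
standardized features); and three tree ensembles built on an exact greedy
CART regression tree implemented in C++ — random forest (bootstrap
aggregation, unrestricted depth), least-squares gradient boosting
(depth 3, learning rate 0.1), and AdaBoost.R2 (depth 3, linear loss,
weight-resampled training, weighted-median prediction). No R tree-ensemble
package is assumed to exist in the runtime environment, which is why the
trees are first-party code; defaults mirror the mainstream ML-library
conventions (100 estimators; only the estimator count was tuned in the
original analysis, and its tuned values are not published). Impurity
importance is the split-wise weighted variance reduction, summed per
feature from a full-data refit (matching the single published rank per
method) and normalized to sum to one; `fold_importance = TRUE` averages
over fold fits instead.

`cross_gender_eval()` trains on one gender and tests on the other, in
both directions — the transfer test that exposes gender-specific clocks.
On gender-agnostic simulations the transfer costs little; when effects
are simulated male-only, male→female transfer collapses by construction.

# Consensus

`importance_ranks()` ranks genes per ensemble (rank 1 = largest
importance), excluding zero-importance genes — "overlapped in all three
methods" is read as *nonzero impurity importance in all three models*,
the only reading under which the core set is smaller than the input set.
Ties break lexicographically by gene id so output is deterministic (the
published tables print tied rank sums without disambiguation).
`rank_sum_core()` sums the three ranks; the minimum possible sum of 3 is
attained exactly by a gene ranked first everywhere. The core set is the
genes ranked by all three methods, optionally truncated to `top_n`.

# Orchestration and determinism

`run_pipeline()` chains simulate/load → qc → normalize → detect → correct
→ screen → clock → consensus, records a manifest (stage, status, records
in/out, elapsed), writes every intermediate as tab-delimited text, and
aborts with the offending stage's name on error, leaving a `FAILED`
marker. One global seed fans out by fixed offsets (+1 simulation, +200
folds, +300 models), so stages are independently reproducible and two
runs under the same seed produce byte-identical artifacts.

# Known limitations

* The mean-TIC ceiling for symmetric non-monotone responses, above.
* The AdaBoost.R2 stop rule (average loss ≥ 0.5) can end training early
  on hard problems; the fit keeps the estimators accumulated so far.
* The generator's gender assignment of biofluid and batch is independent
  of age; confounded designs must be built by hand.
* Elastic-net regularization strength is fixed (default 1.0), not
  cross-validated; the clock comparison concerns model families, not
  tuned performance.
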