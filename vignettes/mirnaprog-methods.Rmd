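---
title: "Models and methods behind mirnaprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirnaprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`mirnaprog` implements the analytical-validation and prognostication
workflow for probe-level miRNA microarray data from FFPE non-small cell
lung cancer specimens: per-array QC with background-based detection
calls, self-self correlation and regression machinery for
analytical-condition comparisons, probe-set summarization, PCA-based
quantification of between-kit variance, a t-statistic/SVM recurrence
prognosticator evaluated by two cross-validation schemes, call-robustness
reports under analytical perturbations, and Kaplan-Meier/log-rank
survival separation of predicted groups. Because the deposited real
arrays are not bundled, every analysis runs on a synthetic-cohort
generator whose defaults are calibrated to the published QC summaries of
the platform; the generator is first-class, tested code, not a fixture.

# The signal model of the generator

The generator is lognormal on the log2 scale. An array carries
`n_probesets` measurement probe sets (`probes_per_set` probes each; a
fraction `frac_human` human) and `n_background_probes` anti-genomic
background probes.

* **Expression structure.** Each probe set is expressed with probability
  `frac_expressed`; unexpressed sets sit at background level (absent
  molecules, no biological variation). Expressed sets have a fixed
  baseline shared across specimens, with per-specimen biological
  deviations of sd `bio_log2_sd` around it; the marginal per-specimen
  spread across sets is `expressed_log2_sd`, so the baseline spread is
  `sqrt(expressed_log2_sd^2 - bio_log2_sd^2)`. The shared baseline makes
  specimens correlate the way real cohorts do, while the deviation
  component carries all between-specimen information.
* **Probe level.** A probe's log2 value is its set's latent mean plus
  fixed per-probe kit offsets (below), plus a fixed per-probe input
  sensitivity times `log2(input_ng / 600)` (sd `input_probe_sd`;
  labeling efficiency responds to input amount in a sequence-specific
  way), plus replicate noise of sd
  `noise_log2_sd_base + noise_input_coeff / sqrt(input_ng)` (low-input
  hybridizations are noisier). The shared input-sensitivity term is what
  makes two arrays of the same sample decorrelate in proportion to
  their |log2 input ratio|: additive independent noise alone cannot do
  it, because the Pearson r of a pair then depends on the *sum* of the
  two noise variances, which is not monotone in the input ratio (an
  80 vs 160 ng pair is noisier overall than 80 vs 640 ng).
* **RNA input.** Above-background linear signal is scaled by
  `1 + input_response_slope * (input_ng - 600)` relative to the 600 ng
  reference. The default slope (0.00012/ng) is calibrated so that the
  induced regression of mean signal intensity on input amount is about
  0.03 intensity units per ng at the reference intensity scale. The
  response is deliberately gentle: the assay's calls are expected to
  withstand input variation, while detection counts still rise with
  input in expectation.
* **Kits.** The HighPure extraction kit multiplies above-background
  signal by `extraction_hp_scale` (default 0.72, the above-background
  mean ratio implied by the published kit means) and adds fixed per-probe
  offsets of sd `extraction_probe_sd`. The old FlashTag labeling kit
  compresses above-background signal as
  `bg + labeling_f_compression * (x - bg)` (default 0.24, the ratio of
  published above-background means of the two labeling kits) and adds
  per-probe offsets of sd `labeling_probe_sd`. Offsets are drawn once
  per cohort (batch structure, shared across arrays) and are
  mean-corrected on the linear scale so kit-level mean ratios equal the
  configured factors exactly.
* **ATP dilution and chip lot** add replicate noise only. This is a
  deliberate modelling commitment — the validation experiments found no
  effect of either — so users who want to study sensitivity to these
  conditions must inject effects themselves.
* **Outcomes.** Recurrence is Bernoulli(`p_recurrence`); the
  `n_signature` planted probe sets (default 12) shift by `+effect_delta`
  log2 units in recurrence cases. Event times are exponential with rate
  `hazard_recurrence`; recurrence-free cases are censored uniformly on
  `min_followup_months + [0, 36]`, reflecting a cohort followed for at
  least 32 months. Exponential-plus-uniform-censoring is the simplest
  model consistent with that design; no covariate-dependent hazards are
  attempted.

## Calibration

Default dimensions are 2,000 human + 500 non-human probe sets with 4
probes each and 200 background probes — far smaller than the real array,
for desk-scale speed; all dimensions are configurable. With the default
condition (600 ng, RecoverAll, FlashTag HSR, ATP 1:50), the expressed
mean/sd and background mean/sd are set so that the linear-scale
expectations land on the published reference values: mean probe signal
~349, mean background ~89.3, and roughly 2.4k detected probe sets at
alpha 0.06 (the acceptance checks allow 15%/15%/20%). The per-probe
noise and input-sensitivity defaults reproduce replicate self-self
correlations near 0.99 at 600 ng and input-series correlations spanning
~0.94-0.98, decreasing in the |log2 input ratio|. The published tables
provide means and standard errors only, no per-probe variance
components, so the noise decomposition (baseline vs input-dependent, and
the biological split `bio_log2_sd`) is our choice of a realistic
structure, not a fitted one.

The per-probe kit offset scales deserve a note. After RMA-style quantile
normalization any array-wide monotone kit effect is removed by
construction, so kit separation in principal-component space can only
come from probe-specific (sequence-specific) effects. Published kit
comparisons for FFPE miRNA work report several-fold per-species signal
differences between extraction and labeling chemistries; the default
labeling offset sd of 2.0 log2 units (typical per-probe factor ~4x) is
at the strong end of that range and makes the labeling kit dominate PC1,
as observed for the real assay, while the extraction offset sd of 0.5
leaves extraction-kit separation visible mainly on the raw scale.

## What the generator does not emulate

No image-level simulation, no spatial artifacts, no cross-hybridization,
no RNA-degradation kinetics, no probe-set-size heterogeneity, and no
feature-feature correlation beyond the planted signature. Passing tests
therefore demonstrate that the *pipeline* behaves correctly under a
plausible statistical structure — not that the real assay attains any
particular accuracy. The published real-cohort accuracies (63%/73%
nested LOOCV, 60.0%/62.6% Monte-Carlo) require the deposited arrays and
are out of scope.

# QC metrics and detection

`qc_report()` computes, per array: arithmetic mean intensity over
measurement probes and over background probes (linear scale), detected
probes, and detected probe sets. The exact detection algorithm of the
vendor QC tool is unpublished, so the package commits to a fully
specified dialect: a probe is detected when its one-sided empirical
p-value against the array's background-probe distribution,
`(1 + #{bg >= x}) / (1 + #bg)`, is below `alpha`; a probe set is
detected when the one-sided Wilcoxon rank-sum test of its probes against
the background probes has `p < alpha`. Alpha defaults to 0.06, the
conventional default for this array family. The rank-sum test uses exact
enumeration of the permutation distribution (midranks, ties exact) when
the combined size is at most 20, and the midrank normal approximation
with tie correction and a 0.5 continuity correction otherwise; an
exhaustive-enumeration oracle pins the exact path in the tests.

Self-self correlations are Pearson on log2 intensities of all
measurement probes, without background subtraction (background
subtraction was reported not to change these results).
`correlation_vs_input_deviation()` regresses pairwise correlations on a
deviation measure; the default is `|log2(input_A / input_B)|`, which
makes 80→160 ng and 320→640 ng equivalent deviations, with absolute
difference and a 0/1 mismatch indicator (for categorical covariates such
as the chip lot) available. Group comparisons default to equal-variance
t/ANOVA, matching the original analysis; Welch is available by flag.

# Summarization

`avg_diff_raw()` is the classifier's default input: the arithmetic mean
of a set's perfect-match probes on the linear scale, with no background
correction and no cross-array normalization. The platform has no
mismatch probes, so the historical "average difference" reduces to the
plain probe mean — the only coherent reading on this array.
`rma_like()` is the correlation/PCA default: log2, probe-level quantile
normalization across arrays (ties receive the mean of the reference
quantiles they span), and per-set median polish (tolerance 1e-6, at most
20 sweeps), the expression index being overall plus array effect. The
RMA convolution background step is omitted — the prognostic pipeline is
explicitly background-correction-free, and keeping both summarization
modes background-free makes them directly comparable. A single array
skips quantile normalization with a warning.

# PCA and between-kit variance

`pca()` centers features (no scaling by default — conventional for
expression matrices; `scale. = TRUE` is available), decomposes by SVD,
and fixes signs deterministically (largest-|loading| entry positive).
"Variance assigned to" a kit is operationalized as eta² = between-group
/ total sum of squares of a component's scores, which the original
report presented only visually. `paired_kit_analysis()` compares, in the
space of the first two components, the mean distance between a
specimen's two arrays under different kits against the mean pairwise
distance between specimens within a kit; a ratio above 1 is the
quantitative form of "a sample is further from itself across kits than
from other samples within a kit".

# The prognosticator

Features are ranked by the pooled-variance two-sample t statistic
(decreasing |t|, ties broken by feature id; a zero-variance feature with
differing means ranks first with infinite |t|, with equal means last at
t = 0). The classifier is a linear-kernel SVM with cost 1 on features
z-scored with training-set statistics; kernel and cost were not
published, and a linear kernel with unit cost is the reproducible,
convex default for p >> n expression signatures (both are exposed).
Samples exactly on the decision boundary are called 0 ("no
recurrence") — an explicit tie rule so predictions are a function.

Two evaluation schemes:

* **Monte-Carlo.** A uniform random two-thirds training split
  (unstratified — splits are re-drawn, with a count, only if a class
  drops below 2 training arrays); within the training portion a
  leave-one-out loop records each fold's top-k features and the k most
  frequent across folds (ties by higher mean |t|, then id) form the
  consensus profile, k = 30 by default; an SVM trained on the consensus
  is scored on the held-out third; repeated R times. The 95% CI is
  `mean ± 1.96 sd / sqrt(R)` over replicate accuracies — the only
  reading consistent with a CI of width ±0.5 percentage points at
  R = 1000. Two evaluations are compared by a Welch t-test on their
  replicate accuracy vectors (the original test statistic was not
  named; this is our declared dialect). The inner leave-one-out loop
  re-ranks features only; the SVM is trained once per replicate on the
  consensus, matching the published description of the procedure.
* **Nested LOOCV.** The outer loop holds one sample out; the inner loop
  runs plain LOOCV on the remaining N-1 (ranking on N-2) to score each
  candidate signature size in `k_grid` (default {5, 10, 15, 20, 25, 30,
  40, 50}, bracketing the fixed k = 30); the best size (ties to the
  smallest) classifies the outer sample; the final profile size is the
  modal per-fold choice (ties to the smallest) and the final features
  are the top-k ranking on all samples. Inside folds a class reduced to
  a single array still contributes its mean to the pooled t (zero sum of
  squares); only folds that lose a class entirely are skipped, and more
  than 20% skipped folds aborts. Every ranking and every
  standardization uses only the fold's training portion; permuted-label
  calibration tests verify the absence of selection bias, and an
  independent naive triple-loop implementation reproduces the fast
  moment-based implementation exactly.

The cross-validation drivers compute per-fold t statistics and
standardization from class-wise sums and sums of squares with held-out
columns subtracted; this is algebraically identical to recomputation
from scratch and keeps the full nested scheme on a 60-sample, 2000-probe
set cohort around half a minute on one CPU. The tests and the acceptance
script run nested LOOCV at n = 60 and the Monte-Carlo scheme at
R = 100-200, the sizes used throughout the package's own evaluation.

# Robustness and survival

`robustness_calls()` predicts condition-perturbed replicate arrays of a
panel of specimens (each replicate must differ from the reference
condition in exactly one covariate) and reports per-condition
concordance with the call on the specimen's reference array. Concordance
— not accuracy — is the metric, because most technical replicates in
such panels have no outcome label. With generator defaults, calls are
expected to be concordant under input, ATP, lot and extraction
perturbations and to flip for at least one panel specimen under the
labeling-kit change, reproducing the published robustness pattern.

`km_estimate()` and `logrank()` wrap the survival package's
product-limit estimator and unweighted (Mantel-Haenszel) log-rank test,
with events processed before censorings at tied times and explicit
hand-computed O/E/V oracles in the tests. No Cox or multivariate
modelling is included; the original multivariate covariate analysis is
out of scope.

# Numerical and design notes

* One integer seed drives everything; sub-streams are derived per stage
  (cohort structure, per-sample draws, per-array rendering, replicate
  rendering, Monte-Carlo splits) so regenerating any subset reproduces
  it bit-identically. Nested LOOCV is fully deterministic.
* All tie-breaks (feature ranking, consensus, signature size) are
  deterministic and documented above.
* Intensities are floored at 2^-4 after kit/input scaling so matrices
  stay strictly positive.
* The intensity writer prints 17 significant digits so write→read is an
  exact identity on doubles.
* Known limitations: probe sets have homogeneous size; the latent
  biological covariance is diagonal; kit offsets are independent across
  probes rather than sequence-clustered; the input-response is linear in
  ng. Each is a simplification chosen for transparency over fidelity.
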