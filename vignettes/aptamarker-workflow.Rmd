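---
title: "Predicting brain amyloid status from aptamer qPCR panels"
author: "aptamarkers package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Predicting brain amyloid status from aptamer qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptamarkers)
```

## The measurement idea

Aptamers — short single-stranded oligonucleotides selected for binding
affinity — can act directly as biomarkers: after a single round of
selection against an individual's plasma, the frequency of an aptamer in
the recovered library is a surrogate for the concentration of whatever it
binds.  A panel of such "Aptamarkers" is then quantified per sample by
qPCR, and the pattern of quantification cycles (Cq) is used to predict a
binary phenotype — here, brain amyloid-β status, defined by thresholding
an amyloid-PET standardized uptake value ratio (SUVR) at 0.79.

The package implements the full analysis chain and a synthetic-data
generator with the statistical structure the chain assumes, so every
stage can be exercised and validated end to end without patient data.

## Candidate discovery from selection libraries

Each library read is a 40-mer random region between two constant flanks
(`aptamer_flanks()`).  `extract_random_regions()` accepts a read iff both
flanks match at their fixed positions within `max_mismatch` substitutions
(default 0 — substitution tolerance is assay-dependent and off unless
requested), and always partitions its input:
`n_reads = n_extracted + n_rejected_flank + n_rejected_length`.  Reads
whose random region contains a non-ACGT character violate the 40-mer
contract and are counted with the length rejections.

`count_frequencies()` computes relative frequencies against the
per-sample total of *extracted* reads, so the later
`top_n_matrix()` truncation (default top 10,000 by copy number summed
over samples, ties broken lexicographically) does not distort
frequencies.  `select_candidate_aptamers()` standardizes the
frequencies, fits the sparse PLS-DA below, and — because this step is
known to be unstable when variables far outnumber samples — reports the
achieved leave-one-out sensitivity/specificity rather than promising a
fixed panel size.  By default keepX grows along a grid until LOO
sensitivity and specificity both reach 1, mirroring how a working panel
would be frozen for synthesis.

## Cq calling

Cq values are called from the raw amplification curve by a
derivative-threshold rule.  With the first-difference derivative
$d(c) = F(c) - F(c-1)$ (first differences avoid special-casing the end
cycles), the threshold is

$$T = \bar d_{3..10} + k\, s_{3..10}, \qquad k = 6,$$

the mean plus six sample standard deviations (denominator $n-1$; the
choice of denominator is a documented convention) of the derivative over
baseline cycles 3–10.  The crossing cycle $c^*$ is the first cycle
*after* the baseline window with $d(c^*) > T$ — the search starts at
cycle 11 so no call can land inside the window that defined the
threshold — and the fractional Cq linearly interpolates $d$ across $T$,
so the call is continuous in the data.  A pure integer-cycle mode is
available (`interpolate = FALSE`).  A curve whose derivative never
exceeds the threshold is a *no-call*, flagged rather than thrown.

Two numerical properties are worth knowing.  Adding any constant to the
fluorescence leaves calls unchanged (only differences enter).  And for a
*noise-free* smooth sigmoid the baseline-window derivative is the curve's
own exponential tail, so the 6-SD threshold tracks that tail and the
crossing lands just after the window regardless of the midpoint: the
rule positions calls meaningfully only when the baseline is dominated by
flat noise, which is the realistic instrument regime (and the one the
generator produces).  Translation equivariance is therefore exact when
the baseline-window content is fixed, and approximate otherwise; the
test suite checks the exact form.

PCR efficiency is a QC output only (it never enters the classifier): a
least-squares line on $\log_{10}(F(c) - \text{baseline fluorescence})$
from $\lceil \mathrm{cq} \rceil$ to the maximum-derivative cycle, returning
$10^{\text{slope}} - 1$, i.e. 1.0 for perfect doubling.  The log-linear
fit is the standard exponential-phase model; a raw linear-slope mode
exists for diagnostics.  Points at or below the baseline after
subtraction are excluded; windows with fewer than two usable points give
an undefined, flagged efficiency.

## Features: Cq values plus one-direction ratios

`build_features()` combines all panel Cq columns with the pairwise
ratios $\mathrm{Cq}_i/\mathrm{Cq}_j$ for $i < j$ in panel order — one
direction only, so a panel of $p$ aptamers yields exactly
$p + p(p-1)/2$ features (990 for $p = 44$).  The direction convention
(numerator lexicographically earlier) is arbitrary but deterministic and
serialized with the model.  No-call Cqs propagate into every feature
involving the aptamer; the default policy drops such samples with a
warning, with per-aptamer median imputation available.

Standardization is always fitted on the training split only
(`fit_standardizer()`), storing per-feature mean and sample SD;
`apply_standardizer()` transforms test samples with the *training*
parameters, never recentring them on themselves.  Zero-variance features
are dropped by name.

## Sparse PLS-DA

The class factor is coded as a centred $-1/+1$ column $y$, giving a
scalar predicted value per sample (equivalent to a two-column dummy for
two classes, and matching a single decision axis).  Per component,
NIPALS iterates

$$u \propto \mathrm{soft}_{\lambda}(X^\top y_{\text{score}}), \qquad
  t = X u,$$

where the soft-threshold operator keeps the `keepX` largest-magnitude
entries, shrinks them by $\lambda$ (the largest magnitude outside the
kept support), and rescales to unit norm.  Exact ties at the support
boundary resolve to the first index; tied entries shrink to exactly
zero, so the nonzero count can fall below `keepX` under ties (and if the
entire support ties away it is kept unshrunk).  $X$ and $y$ are deflated
by regression on $t$ between components.  For one component this is
closed form; NIPALS (tolerance $10^{-9}$, 500 iterations) is kept for
multi-component generality.  The component-1 sign is fixed so the
positive class has the larger training-score mean.

`filter_by_loading()` implements the post-hoc model reduction: loadings
with $|u_j| \le$ cutoff (default 0.04) are zeroed on the unit-norm fitted
loadings, the vector is renormalized, and training scores and class
statistics are recomputed.  `tune_keepx()` offers leave-one-out tuning
over a grid (default $\{10, 25, 50, 100, 250, 500, 961, p\}$); when
`keepX` is unset, `splsda_fit()` fits dense, leaving tuning explicit.

## Nearest-zero classification and validation

Training yields per-class mean and SD of the component-1 scores.  A new
sample with predicted score $s$ gets

$$z_c = \frac{s - \mu_c}{\sigma_c}, \quad c \in \{\text{neg}, \text{pos}\},$$

and is called to the class with the smaller $|z_c|$.  An exact tie — a
probability-zero event for continuous scores — goes to `pos`, since a
screening test prefers sensitivity.  The rule is invariant to any common
affine rescaling of scores and class statistics.

`evaluate_predictions()` reports the confusion matrix with sensitivity,
specificity and accuracy at three decimals, leaving rounding to callers.
`roc_curve()` sweeps thresholds over the unique scores and integrates by
the trapezoidal rule.  `cross_validate()` repeats the entire chain —
split, fit standardizer on train, transform test with training
parameters, fit, filter if requested, classify — over seeded random
splits (default 5 repeats of 54 train / 15 test); splits leaving a class
empty on either side are redrawn with a warning, surfacing the
unbalanced-split failures this design is prone to.

## The synthetic-data generator

`simulation_config()` defaults encode the cohort the analysis was
designed around: 69 usable samples split 31 negative / 38 positive at
SUVR 0.79 (positive count = `round(n * pos_fraction)`), a 44-aptamer
panel read over 30 cycles, and 22 selection libraries (11 per class).
Specifics, with reasons:

* **SUVR**: negatives Uniform(0.60, 0.78), positives Uniform(0.80, 1.20).
  Only the threshold relationship matters downstream, so no attempt is
  made to model the real SUVR distribution.
* **Curves**: $F(c) = \text{baseline} + \text{plateau}/(1 +
  e^{-k(c - c_0)}) + \varepsilon$, the standard qPCR sigmoid, with
  baseline 50 RFU, plateau 1000 RFU, $k = 0.7$ per cycle (a per-cycle
  gain of $e^{0.7} \approx 2$, i.e. near-perfect doubling in the
  exponential phase) and noise SD 1 RFU — a clean instrument regime in
  which the 6-SD rule calls every curve.  Per-aptamer base crossing
  cycles are drawn Uniform(21.5, 25.5), placed so every crossing
  (including class-shifted ones) falls strictly inside the searchable
  cycle range; informative aptamers amplify
  `cq_shift` cycles earlier in positives (more bound target), plus
  per-curve Gaussian noise `cq_noise_sd` on every aptamer.
* **Libraries**: every read is flank + 40-mer + flank (86 nt); a shared
  200-sequence background pool with `n_enriched_sequences` members
  sampled `enrichment_fold`-fold more often in positive libraries.
  Quality strings are constant Q40 because quality is never used.
  Read depth and pool diversity are placeholders, not estimates of real
  runs, which are undisclosed.
* **Determinism**: all generators run under `withr::with_seed` on
  offsets of the config seed; identical config and seed give
  byte-identical outputs, and ground truth (true crossing cycles,
  enriched sequences) is always emitted for parameter-recovery tests.

What the generator does *not* emulate: plasma composition and binding
kinetics, PCR inhibition and efficiency drift, sequencing errors,
between-plate effects, and any correlation structure among aptamers
beyond the class signal.  Passing recovery tests therefore show that the
chain is correct and sensitive under its own assumptions — not that the
assay achieves any particular performance on real plasma.

One property of the feature space deserves emphasis: for an informative
aptamer with standardized effect $d$, each of its ratios with a
class-independent aptamer carries effect exactly $d/\sqrt{2}$ (the ratio
scales signal and noise by the same denominator and adds one equal-sized
noise term).  With ~40 such ratios per informative aptamer, the upper
tail of their sample correlations overlaps the raw-Cq correlations at
cohort sizes near 70, so top-loading lists mix raw Cqs with ratios of
the strongest aptamers rather than cleanly listing one feature per
informative aptamer.  Interpretation of loading rankings should happen
at the aptamer level, over all features mentioning an aptamer.

## Validation problem sizes

The shipped tests validate the Cq caller against an independently coded
exhaustive-scan oracle on 1000 random noisy logistics, the dense
one-component fit against the SVD of $y^\top X$ on 100 random 20×8
instances (and against an independent sPLS-DA implementation where
available), the feature-count identity for panels up to 50, the
confusion metrics against direct counting on all small matrices, and
full-pipeline parameter recovery on five seeded replicates of the
default cohort (5 × 54/15 cross-validation) plus five replicates of the
22-library NGS selection at 10,000 reads per library.

## Known limitations

* Two classes only; no covariate modelling (age, sex, APOE are carried
  as metadata but never modelled — cohorts of this size cannot support
  it).
* The candidate-selection step inherits the instability of
  variables ≫ samples; its LOO metrics are reported, not guaranteed.
* Efficiency estimates are diagnostic; no efficiency-corrected
  quantification, melt curves, standard curves or inter-plate
  calibration.
* The nearest-zero rule is not a calibrated probability; ROC/AUC on
  15-sample test sets is reported but inherently unstable.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- list(seed = 7,
            simulate = list(n_samples = 24, panel_size = 6,
                            n_informative = 3, pos_fraction = 0.5),
            model = list(n_train = 16, n_test = 6),
            crossval = list(n_repeats = 2, n_train = 16, n_test = 6))
manifest <- run_pipeline(cfg, out_dir = tempfile("run"))
manifest
```
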