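# aptamarkers

Aptamer qPCR panels for predicting brain amyloid status from plasma.

## What this is for

Aptamers — short single-stranded oligonucleotides selected for binding —
can serve *directly* as biomarkers ("Aptamarkers"): after one round of
selection against an individual's plasma, an aptamer's frequency in the
recovered library tracks the concentration of whatever it binds. A panel
of such aptamers is quantified per sample by qPCR, and the pattern of
quantification cycles (Cq) predicts a binary phenotype — here, brain
amyloid-β status defined by thresholding the amyloid-PET standardized
uptake value ratio (SUVR) at 0.79 in cognitively normal elderly
individuals.

The package is for biostatisticians and assay developers who want to run,
stress-test or extend this analysis chain. It implements every stage:

1. **NGS candidate discovery** — extract 40-mer random regions between
   the constant library flanks from per-sample FASTQ files, count
   frequencies, keep the top-N by copy number, and select discriminating
   candidates by sparse PLS-DA with leave-one-out validation.
2. **Cq calling** — a derivative-threshold rule: the call is where the
   first-difference derivative first exceeds
   `mean + 6 sd` of the derivative over baseline cycles 3–10, with
   fractional interpolation; PCR efficiency (`10^slope − 1` on the
   log-linear exponential phase) as QC.
3. **Feature engineering** — all panel Cq values plus one-direction
   pairwise ratios `Cq_i/Cq_j` (i < j in panel order):
   `p + p(p−1)/2` features, 990 for a 44-aptamer panel; standardization
   fitted on training data only.
4. **Sparse PLS-DA** — written from scratch: centred −1/+1 response,
   NIPALS with soft-thresholded unit-norm loadings (`keepX` variables
   per component), deflation, a ±0.04 loading filter, JSON model
   serialization.
5. **Classification & validation** — the nearest-zero z-score rule
   (`z_c = (score − μ_c)/σ_c` against each training class; smaller |z|
   wins, ties to positive), confusion-matrix metrics, trapezoidal ROC,
   and repeated 54/15 hold-out cross-validation.
6. **Synthetic data** — seeded generators for cohorts, sigmoid
   amplification curves with class-dependent Cq shifts, and
   class-enriched selection-library FASTQ files, with ground truth
   emitted for parameter-recovery testing.

`run_pipeline()` chains the stages from a YAML config;
`inst/scripts/aptamarker-pipeline.R` is a thin shell wrapper.

## Worked example

Simulate the default emulated cohort (69 samples, 31 negative / 38
positive, 44 aptamers of which 5 carry a 2-cycle class shift), call Cq
values, build features, and cross-validate:

```r
library(aptamarkers)

cfg    <- simulation_config(seed = 7)
cohort <- simulate_cohort(cfg)
curves <- simulate_amplification_curves(cohort, cfg)
cq     <- call_cq_table(curves)
head(cq, 3)
#>   sample_id aptamer_id       cq called efficiency
#> 1      S001      APT01 14.76613   TRUE  0.7804050
#> 2      S001      APT02 14.56512   TRUE  0.7577069
#> 3      S001      APT03 17.20391   TRUE  0.7731211

fm     <- build_features(cq_wide(cq))
labels <- cohort$amyloid_class[match(fm$sample_ids, cohort$sample_id)]

cross_validate(fm, labels, n_repeats = 5, n_train = 54, n_test = 15,
               seed = 11)
#> repeated hold-out CV: 5 repeats of 54 train / 15 test
#>  repeat_id sensitivity specificity  accuracy
#>          1       1.000           1 1.0000000
#>          2       0.875           1 0.9333333
#>          3       1.000           1 1.0000000
#>          4       1.000           1 1.0000000
#>          5       1.000           1 1.0000000
#> means: sensitivity 0.975 | specificity 1.000 | accuracy 0.987

model <- splsda_fit(fit_standardizer(fm)$values, labels)
model
#> sparse PLS-DA model: 1 component(s), 990 features
#>   nonzero loadings per component: 990
#>   training scores (comp 1): neg -11.150 +/- 4.472, pos 9.096 +/- 3.348

filter_by_loading(model, 0.04)$n_retained
#> [1] 200
```

Each `cq` row is one (sample, aptamer) amplification curve: the
fractional quantification cycle, whether the derivative threshold was
crossed at all, and the exponential-phase efficiency (1.0 would be
perfect doubling). The cross-validation table is one row per random
54/15 split, with the test-set sensitivity/specificity/accuracy of the
nearest-zero classifier; the model summary shows the per-class
training-score statistics that rule uses. The 0.04 loading filter keeps
200 of 990 variables here while the confusion matrix is unchanged.

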