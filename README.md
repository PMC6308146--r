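# radrecur

Radiomics and dosimetric analysis of recurrence patterns after
intensity-modulated radiotherapy (IMRT) for nasopharyngeal carcinoma
(NPC), for radiation-oncology and imaging researchers studying
radioresistance.

Most NPC treatment failures after IMRT are *in-field*: the tumor regrows
inside the region that received the prescribed dose, pointing to intrinsic
radioresistance rather than a geographic miss. `radrecur` implements both
halves of the corresponding analysis:

* **Recurrence-pattern classification from dose.** For a recurrent tumor
  volume V<sub>recur</sub> registered to the planning dose grid, the
  package evaluates the fraction of V<sub>recur</sub> receiving at least
  95 % of the prescription dose (the DVH of V<sub>recur</sub> at the 95 %
  isodose) and classifies the failure:

  - *in-field* if that fraction ≥ 0.95,
  - *marginal* if 0.20 ≤ fraction < 0.95,
  - *out-of-field* if fraction < 0.20.

* **An MRI radiomics pipeline** that asks whether pre-treatment
  SPAIR-T2W texture separates tumors that later recur in-field (IFR) from
  non-progressing tumors (NPD): isotropic 1 mm³ resampling → ROI gray-level
  normalization to [m − 3s, m + 3s] with 64-level quantization → 11 derived
  images (Laplacian-of-Gaussian at σ = 0.5/1.5/2.5 mm, 8 undecimated
  Coiflet-1 wavelet sub-bands) → **1117 features** per case (13 shape + 18
  first-order + 74 texture on the original image; 92 per derived image)
  → a selection cascade (ICC(2,1) reproducibility filter at 0.8, greedy
  |PCC| ≥ 0.8 redundancy pruning, Kruskal–Wallis with Benjamini–Hochberg
  correction at α = 0.05, per-feature ROC with Hanley–McNeil standard
  errors) → PCA to ≥ 85 % cumulative variance → stratified 10-fold
  cross-validation of ANN / KNN / linear-SVM classifiers with pooled
  confusion-matrix metrics (TP rate, FP rate, precision, F-measure, MCC,
  accuracy).

Because the underlying patient images are not public, the package includes
a synthetic cohort generator (11 IFR + 16 NPD by default) whose tumors are
Gaussian random fields with class-specific correlation lengths — a
controlled stand-in for intratumoral heterogeneity — plus simulated
second-observer contours and dose grids with known isodose-coverage ground
truth. See the methods vignette (`vignettes/radrecur-methods.Rmd`) for the
model and every numerical convention.

## Worked example

```r
library(radrecur)

# --- dosimetric half: the packaged 20-patient recurrence table -----------
clinical <- read_clinical_table(
  system.file("extdata", "table2_clinical.csv", package = "radrecur"))
tabulate_cohort(clinical)
#> <cohort_summary> n = 20
#> patterns: in_field=18, marginal=1, out_of_field=1
#> sites:    local=9, regional=8, local_regional=3
#> time to failure: median 26.5 (range 8 - 65 ) months

# --- radiomics half: full pipeline on the synthetic cohort ---------------
res <- run_pipeline(default_config(seed = 1))
res$selection
#> <selection_report>
#>  features in:        1117
#>  after ICC filter:   1117
#>  after PCC pruning:  199
#>  significant (BH):   48
glance(res$pca)
#> # A tibble: 1 × 3
#>       k cum_var n_features
#>   <int>   <dbl>      <int>
#> 1    10   0.867         48
tidy(res$cv)
#> # A tibble: 3 × 8
#>   model tp_rate fp_rate precision f_measure   mcc accuracy flagged
#>   <chr>   <dbl>   <dbl>     <dbl>     <dbl> <dbl>    <dbl> <lgl>
#> 1 ann         1       0         1         1     1        1 FALSE
#> 2 knn         1       0         1         1     1        1 FALSE
#> 3 svm         1       0         1         1     1        1 FALSE
```

Reading the output: 20 recurrent patients tally to 18 in-field, 1 marginal
and 1 out-of-field failure (90 % in-field), with median time to failure
26.5 months (range 8–65). On the synthetic cohort the planted texture
difference survives the whole selection cascade — 48 features remain
significant after BH correction, e.g. `ngtdm_Contrast` with adjusted
p ≈ 4 × 10⁻⁴ and AUC 1.0 — ten principal components reach 86.7 %
cumulative variance, and all three classifiers separate the two phenotypes
perfectly under cross-validation. The synthetic separation is deliberately
strong; clinical effect sizes are weaker (see the vignette's discussion of
what the generator does and does not emulate).

`autoplot()` methods produce the standard figures: `autoplot(res$selection)`
(per-feature AUC with 95 % CI), `autoplot(res$pca)` (scree/cumulative
variance), `autoplot(res$cv)` (metric-by-model bars).

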