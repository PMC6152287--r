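# adipodiscrim

Simulation and discriminant screening of adipokine and metabolic markers in
insulin-treated type 2 diabetes.

## The problem

Paired clinical studies of obese type-2 diabetics under long-acting insulin
therapy measure a panel of anthropometric and biochemical parameters —
weight, BMI, circumferences, HbA1c, lipids, glucose/insulin and the HOMA
indices, and the adipokines leptin, soluble leptin receptor (sOB-R) and
adiponectin — at baseline and after six months, plus a healthy control
group.  The analytical question is which parameters best discriminate the
treated from the untreated state.  This package implements that analysis
end to end for biostatisticians who want to study or extend it:

* a **Gaussian-copula cohort generator** whose packaged scenario encodes
  the published per-group summary statistics (mean ± SD or median with
  quartiles for 21 parameters in 3 arms), the published pairwise Pearson
  correlations, gender effects, and the within-patient pairing of the two
  visits — so the whole pipeline is testable without access to patient
  data;
* the **difference transform** Δw(i) = w(i, month 6) − w(i, baseline), its
  21×21 absolute-correlation screen, and the Student's *t* comparisons
  (pooled-variance independent and paired);
* **five two-class Gaussian discriminants** implemented from their density
  and distance formulas — `linear` (pooled covariance), `diaglinear`
  (naive-Bayes pooled), `quadratic` (stratified covariances),
  `diagquadratic` (naive-Bayes stratified) and `mahalanobis` (pure distance
  rule, no priors or determinants) — with an escalating-ridge policy for
  the singular fits that small clinical samples produce;
* an **exhaustive subset search**: every feature subset up to a cardinality
  cap crossed with every classifier kind (5·(2²¹−1) = 10,485,755 tasks
  uncapped; 5,242,875 at the conventional 10-feature cap), scored by
  held-out accuracy (TN+TP)/(FN+FP+TN+TP) on a patient-level 2/3–1/3
  split (27 learning / 13 test patients at the study size of 40), ranked
  per kind.

## Worked example

```r
library(adipodiscrim)

coh <- generate_cohort(load_scenario(), seed = 1)
coh
#> <cohort> 107 records: 40 diabetic patients (paired), 27 healthy controls

res <- analyze_cohort(coh)
subset(res$summary, parameter %in% c("w19", "w21") & arm != "healthy")
#>    parameter                    name      arm  mean    sd
#> 56       w19 Soluble leptin receptor baseline 35.44 16.04
#> 57       w19 Soluble leptin receptor   month6 45.15 18.10
#> 62       w21      Plasma adiponectin baseline  7.04  3.80
#> 63       w21      Plasma adiponectin   month6  8.76  3.61
```

The summary reproduces the qualitative signature of the therapy: sOB-R and
adiponectin rise over the six months while leptin stays flat.  Both changes
are confirmed by the paired *t*-test at n = 40:

```r
subset(res$ttests, parameter %in% c("w19", "w21") & comparison == "baseline_vs_month6")
#>    parameter         comparison   test    t df       p skewed
#> 38       w19 baseline_vs_month6 paired 4.30 39 1.1e-04  FALSE
#> 42       w21 baseline_vs_month6 paired 4.47 39 6.5e-05  FALSE
```

The difference-correlation screen flags the structurally tied pairs
(`correlation_band(res$correlations[1, 2])` is `"almost-complete"`,
|r| = 0.96 for Δweight vs ΔBMI), and the subset search ranks feature
subsets per classifier kind:

```r
sr <- run_search(coh, search_config(max_cardinality = 2, seed = 1))
sr
#> <subset_search> 1155 tasks (5 kinds, max cardinality 2)
#>   linear        best ACC = 0.769 for {4+13}
#>   ...
#>   mahalanobis   best ACC = 0.808 for {7+19}
head(sr$top$mahalanobis, 1)   # ACC on the 13 held-out patients (26 rows)
```

An ACC of 0.808 means 21 of the 26 held-out observations (13 test patients
at two timepoints each) were assigned to the correct side of therapy.  On
a simulated cohort these rankings fluctuate with the seed; a cohort built
so that only one parameter carries treatment signal ranks that parameter
first deterministically (see `tests/testthat/test-acceptance.R`).

## Scenario files

The packaged scenario is `inst/extdata/detemir_2017.yaml`; any scenario
with the same shape (21 marginals × 3 arms, correlation targets, gender
multipliers, cohort sizes) can be passed to `load_scenario()` or built in
code with `as_cohort_scenario()`.  The methods vignette
(`vignettes/adipodiscrim-methods.Rmd`) documents the copula construction,
the gender-mixture calibration and its constraints, the ridge policy, and
the design decisions in detail.
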