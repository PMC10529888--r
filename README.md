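# erlf — volume-assisted estimation of remnant liver function

`erlf` implements a preoperative prediction pipeline for
post-hepatectomy liver dysfunction, built for radiologists, liver
surgeons and biostatisticians evaluating imaging-based function
scores. Liver function is quantified from gadoxetic-acid–enhanced MR
relaxometry: the percent reduction of the T1 relaxation time between
the plain and hepatobiliary-phase maps,

    RR = (T1_plain − T1_HBP) / T1_plain × 100%,

is combined with liver volumetry into a function estimate on the scale
of the indocyanine green plasma disappearance rate (ICG-PDR, %/min):

    eLF  = 0.84 · exp(0.038 · RR) · exp(0.045 · LV / 100 mL)
    erLF = 0.84 · exp(0.038 · RR) · exp(0.045 · rLV / 100 mL),   rLV = LV − resection volume

erLF — the estimate with the *remnant* volume — predicts the
postoperative PDR before the operation happens. Patients are classed
with the ICG cut-offs (dysfunction < 10, at risk 10–17, normal > 17
%/min; preoperatively LDF when PDR < 17 or R15 > 8). The volume
coefficient is applied per 100 mL; the package vignette explains why
that is the only unit reading consistent with the published per-group
score tables.

The package provides:

* **ICG kinetics** — monoexponential clearance fitting (`fit_monoexponential()`
  returns PDR, R15, back-extrapolated C0) and the pre-/postoperative
  classifications;
* **volumetry** — voxel-count volumes from segmentation label masks
  (NIfTI I/O), with lesions and vessels excluded from functional volume;
* **the function model** — `reduction_rate()`, `estimated_function()`,
  `classify_erlf()`, clinical outcome flags (acute dysfunction, the
  50/50 severe-failure criterion, peak bilirubin > 7 mg/dL) and
  bilirubin unit conversion;
* **diagnostics** — confusion matrices, sensitivity/specificity/PPV/NPV/
  accuracy, ROC-AUC with explicit orientation, exact Mann–Whitney
  tests, and `reconstruct_confusion()`, which inverts *published
  rounded metrics* back to the unique integer confusion matrix;
* **survival** — univariable Cox fit (Breslow ties, Wald CI) of
  overall survival on erLF and Kaplan–Meier curves per erLF class,
  with broom-style `tidy()`/`glance()` and `autoplot()` methods;
* **a synthetic cohort generator** whose defaults emulate the
  published 71-patient hepatectomy cohort (T1 751.9 ± 99.7 ms, LV
  1609 ± 443 mL, 22/71 dysfunctional, hazard ratio 0.87 per erLF
  unit), so the whole pipeline is testable without patient data.

## Worked example

```r
library(erlf)

report <- run_pipeline(run_config(params = generator_params(n = 71, seed = 42)))
report$metrics
#> # A tibble: 2 × 7
#>   model     sensitivity specificity   ppv   npv accuracy   auc
#>   <chr>           <dbl>       <dbl> <dbl> <dbl>    <dbl> <dbl>
#> 1 preop_icg       0.815       0.318 0.423 0.737    0.507 0.694
#> 2 erlf            0.741       0.864 0.769 0.844    0.817 0.859
```

Both rows evaluate a predictor of the postoperative reference
(ICG-PDR < 10 %/min): the preoperative ICG classification and the
erLF classification. On this simulated cohort the erLF model is the
stronger predictor (accuracy 0.82, AUC 0.86) — the generator embeds
erLF as the true driver of postoperative function, so this is the
expected behaviour at its default noise level, not an empirical claim
about patients.

```r
tidy(report$cox)
#> # A tibble: 1 × 8
#>   term  estimate std.error statistic  p.value    hr conf.low conf.high
#>   <chr>    <dbl>     <dbl>     <dbl>    <dbl> <dbl>    <dbl>     <dbl>
#> 1 erlf    -0.165    0.0436     -3.80 0.000145 0.847    0.778     0.923
```

Each additional unit of estimated remnant function multiplies the
death hazard by 0.85 (95% CI 0.78–0.92) here — the generator's true
value is 0.87. `autoplot(report$km)` draws the Kaplan–Meier curves
stratified by erLF class.

Fitting a dye-clearance curve directly:

```r
cur <- generate_icg_curve(pdr = 20.2, c0 = 5, times = 0:15, noise_sd = 0.05, seed = 3)
fit_monoexponential(cur)
#> ICG monoexponential fit (n = 16)
#>   PDR  20.448 %/min   R15  4.655 %   C0  5.023 mg/L
```

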