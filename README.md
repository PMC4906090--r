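# tiacdose

Internal dosimetry for Lu-177 peptide receptor radionuclide therapy
(PRRT) studies: from organ and blood time–activity curves to
time-integrated activity coefficients (TIACs), MIRD-schema absorbed-dose
coefficients, administered-activity dose predictions, cohort statistics
and organ toxicity checks.

The package is aimed at preclinical/clinical dosimetry analysts who have
per-region uptake tables (fraction of injected activity vs. time) and a
phantom S-value table, and want a tested, reproducible pipeline instead
of spreadsheet arithmetic.

## The method

For each subject and region, the decay-corrected time–activity curve is
fitted with a sum of exponentials

    f(t) = Σᵢ Aᵢ exp(−λᵢ t),   Aᵢ ≥ 0, λᵢ ≥ 0,

by weighted least squares (default weights 1/value², multistart
Levenberg–Marquardt); the number of terms is selected by corrected AIC,
AICc = N ln(SSRw/N) + 2K + 2K(K+1)/(N−K−1) with K = 2n+1. The TIAC
re-applies physical decay in closed form,

    ã = Σᵢ Aᵢ / (λᵢ + λ_phys),   λ_phys = ln2 / 159.528 h  (Lu-177),

with a standard error from Gaussian propagation through the fit
covariance plus a 10 % systematic quantification error in quadrature.
Bladder contents are integrated trapezoid-plus-tail (physical decay after
the last sample) instead of fitted.

Organ accounting sums the kidneys, derives the skeleton from the spine
VOI (spine = 19 % of skeleton mass), estimates red marrow from the fitted
blood curve via the extracellular-fluid surrogate
(ã_RM = ã_blood[h/L] · m_RM · RMECFF/(1−hct)), and closes the whole-body
balance with a remainder term. Doses follow the MIRD schema

    D(target) = Σ_source ã(source) · S(target ← source)   [mGy/MBq],

with a rest-of-body adjusted S-value for the remainder, cohort mean ±
sample SD over subjects, scaling to an administered activity (Gy), and a
check against organ toxicity limits (23 Gy for kidneys by default).

A synthetic-data module generates study-shaped cohorts (biexponential
blood clearance with a 2.0-min/36-min half-life pair and 80.1 % fast
fraction, organ uptake–washout curves calibrated to reference cohort
TIACs, 23.4 % urinary excretion by 4 h, multiplicative lognormal noise)
so the entire pipeline is testable without any external data. See the
methods vignette (`vignettes/tiacdose-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

Simulate a five-subject cohort on the study schedule, fit all TIACs, and
run the dose engine with the bundled toy phantom:

```r
library(tiacdose)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
<pipeline_result>
  subjects: sim01, sim02, sim03, sim04, sim05
  phantom targets: 7
  administered activity: 5000 MBq
  cohort dose coefficients (mGy/MBq) and predicted doses (Gy):
    liver                    0.229 +/- 0.068     ->    1.1 Gy
    kidneys                   2.63 +/- 0.112     ->   13.2 Gy
    heart_wall               0.358 +/- 0.0834    ->    1.8 Gy
    urinary_bladder_wall     0.462 +/- 0.16      ->    2.3 Gy
    red_marrow              0.0214 +/- 0.00414   ->   0.11 Gy
    osteogenic_cells         0.814 +/- 0.197     ->    4.1 Gy
    total_body              0.0643 +/- 0.00856   ->   0.32 Gy
```

Each line is a target region's cohort-mean absorbed-dose coefficient
(mGy per MBq injected) ± the between-subject sample SD, followed by the
predicted absorbed dose for a 5-GBq human administration at the package's
reporting precision. The per-subject TIACs behind it:

```r
subset(res$tiacs, subject_id == "sim01")
```

```
   subject_id            organ  tiac_h    se_h         method
1       sim01       whole_body 57.5056 7.44701       analytic
2       sim01            liver  5.1486 0.53216       analytic
3       sim01      kidney_left  4.7769 0.48469       analytic
4       sim01     kidney_right  4.6248 0.47576       analytic
5       sim01            heart  0.8502 0.08776       analytic
6       sim01 bladder_contents  0.8284 0.08284 trapezoid_tail
...
9       sim01          kidneys  9.4017 0.67917       analytic
10      sim01             bone 14.2061 1.65304       analytic
12      sim01        remainder 27.0578 7.67786       analytic
```

`tiac_h` is hours of cumulated activity per unit injected activity;
`se_h` includes the 10 % systematic quantification error. The toxicity
table reports `pass` for kidneys (13.2 Gy vs the 23 Gy limit, 9.8 Gy of
headroom) and `unchecked` for organs without a configured limit.

Real analyses replace the toy phantom with their own tables via
`read_s_matrix("S.csv", "masses.csv")` (CSV layouts are documented on
that function) and feed measured TACs with `read_tac_csv()` or
`run_pipeline(subjects = "tacs.csv")`. A thin command-line wrapper with
`simulate`, `fit-tiac`, `dose` and `run` subcommands is installed at
`inst/cli/tiacdose`.

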