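---
title: "Methods: TIAC estimation and MIRD-schema dosimetry in tiacdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIAC estimation and MIRD-schema dosimetry in tiacdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiacdose)
```

## The problem

Internal dosimetry for Lu-177 peptide receptor radionuclide therapy (PRRT)
asks: given measured time–activity curves (TACs) — the fraction of the
injected activity in each organ at a handful of imaging times, plus a
densely sampled blood concentration series — what absorbed dose will each
organ receive per unit administered activity, and is a therapeutic
administration (several GBq) safe against organ toxicity limits?

The pipeline implemented here follows the standard preclinical workflow:

1. **Kinetic fitting.** Each organ's decay-corrected TAC is fitted with a
   sum of exponentials; the number of terms is chosen by corrected AIC.
2. **TIAC integration.** The time-integrated activity coefficient (TIAC,
   hours; historically "residence time") is the integral of the fitted
   curve with physical decay re-applied, obtained in closed form with
   Gaussian error propagation, or by trapezoid-plus-tail integration for
   regions (bladder contents) where a fit is not meaningful.
3. **Organ accounting.** Left and right kidneys are summed; the skeletal
   TIAC is derived from the spine VOI assuming the spine holds 19 % of
   skeleton mass; red marrow is estimated from blood via the
   extracellular-fluid surrogate; the remainder of body closes the
   whole-body balance.
4. **MIRD dose engine.** Absorbed dose coefficients are
   \(D(t) = \sum_s \tilde a(s)\, S(t \leftarrow s)\) over source regions
   \(s\) with phantom S-values, a rest-of-body adjusted S-value for the
   remainder, cohort mean ± SD, administered-activity scaling, and a
   toxicity check (23 Gy for kidneys).

## Units and conventions

- Time is hours internally; readers convert minutes/days on ingest.
- Activity is fraction of injected activity (per litre for blood), so a
  TIAC is directly \(\int \text{fraction}\,dt\) in hours.
- Fitting is always done on decay-corrected data (biological kinetics
  only); the physical decay constant \(\lambda_{phys} = \ln 2 / 159.528\,
  \mathrm{h} \approx 4.345\times10^{-3}\,\mathrm{h^{-1}}\) is re-added at
  integration: \(\tilde a = \sum_i A_i/(\lambda_i + \lambda_{phys})\).
  This separates biology from physics and makes the physical-decay bound
  explicit: no region's TIAC can exceed (peak fraction)\(/\lambda_{phys}\),
  and the whole body is bounded by \(1/\lambda_{phys} = 230.16\) h.
- Two decay-correction conventions coexist in practice (corrected to
  injection time vs. left as measured); every curve carries an explicit
  flag and `convert_decay_convention()` is an exact inverse pair.

## The fitter

`fit_exp_sum()` minimises the weighted residual sum of squares of
\(f(t)=\sum_i A_i e^{-\lambda_i t}\) with non-negativity bounds on all
parameters, using Levenberg–Marquardt with an analytic Jacobian.

- **Weighting.** Default `1/value^2` (constant fractional error), matching
  gamma-counting and quantitative-SPECT error structure; `1/value` and
  uniform weights are selectable. Values below `max(value) * 1e-8` have
  their weights capped to avoid division blow-ups on near-zero late
  samples.
- **Initialisation.** Multistart (default 20 starts): rates are placed on
  a log-spaced grid spanning roughly \([\ln 2/(5 t_{max}),\,
  \ln 2/(0.2\,t_{min})]\), jittered up to 4-fold per start; amplitudes
  start from a weighted linear solve at those rates, floored at a small
  positive value. Starts are drawn under a caller-provided seed, so fits
  are reproducible. Non-converged starts are discarded; if no start
  converges the fit fails loudly rather than returning a best effort.
- **Canonical order.** Terms are sorted fastest-rate-first, so the "alpha"
  phase is always the first term and fits are invariant to term
  relabelling.
- **Covariance.** \(C = s^2 (J^\top W J)^{-1}\) with \(s^2 =
  SSR_w/(N-p)\) and the weighted Jacobian at the optimum; a
  pseudo-inverse is used if the normal matrix is singular (e.g. a rate
  pinned at the zero bound).

### Model selection

`select_model()` compares term counts (default 1–3) by
\[
AICc = N \ln(SSR_w/N) + 2K + \frac{2K(K+1)}{N-K-1},\qquad K = 2n + 1 .
\]
Two numerical choices matter on sparse schedules:

- Candidates with \(N - K - 1 \le 0\) carry no finite AICc. They are
  excluded whenever any candidate has one; if *no* candidate does (e.g. a
  3-point curve, where only the monoexponential is even fittable), the
  fittable candidate with fewest terms is returned. This keeps the
  degrees-of-freedom rule while still producing the obvious answer for
  minimal data.
- \(SSR_w\) is floored at \(10^{-20}\sum w y^2\) inside the AICc. Fits
  that have converged to machine precision (noiseless data) would
  otherwise be ranked by floating-point noise in \(\ln SSR_w\); with the
  floor they tie, and ties go to fewer terms (parsimony).

On the study's 6-point imaging schedule only the monoexponential carries a
finite AICc (\(N - K - 1 = 0\) for two terms), so organ TIACs come from
monoexponential fits — consistent with washout-dominated organ curves. The
16-point blood series supports and selects the biexponential.

### Uncertainty

The TIAC standard error is \(\sqrt{g^\top C g}\) with
\(g = (\ldots, 1/(\lambda_i+\lambda_{phys}), \ldots,
-A_i/(\lambda_i+\lambda_{phys})^2, \ldots)\). The test suite checks this
first-order propagation against a 2000-draw parametric bootstrap on the
study blood schedule (agreement within 15 %). A systematic
activity-quantification error of 10 % of the TIAC value is then folded in
in quadrature, once — `apply_systematic_error()` refuses double
application.

### Trapezoid-plus-tail

For bladder contents (filling/voiding, not a washout process) the TIAC is
computed on the *measured* (not decay-corrected) curve: trapezoids between
samples, a leading triangle from (0, 0) when the first sample is at
\(t > 0\), and a tail \(v_n/\lambda_{phys}\) assuming pure physical decay
after the last point. The per-organ method is overridable
(`trapezoid_organs` in the config).

## Organ accounting

- **Normalisation.** Image-derived uptakes are calibrated by setting the
  first scan's whole-body uptake to 100 % (`normalize_to_first_whole_body`,
  idempotent). The pipeline applies it only when asked
  (`normalize_first_scan = TRUE`): the synthetic generator emits absolute
  fractions of injected activity, for which the step is an identity in
  intent, whereas real image ingests need it.
- **Remainder.** Reconstructed as whole body minus liver, kidneys, heart,
  bladder contents, bone and red marrow. This composition was validated
  numerically against the bundled five-subject reference table (all
  remainders within ±0.04 h, i.e. within rounding of the inputs); it is a
  reconstruction, not an independently reported formula. Negative
  remainders (possible only through rounding/noise) are clipped to zero
  with a warning.
- **Bone from spine.** Spine TIAC divided by the spine's share of skeleton
  mass (default 0.19); linear in its input, SE scales identically. The
  spine TIAC is retained alongside the derived bone TIAC for reporting.
- **Red marrow.** Blood-based surrogate: marrow TIAC = blood concentration
  TIAC (h/L, from the fitted blood curve) × marrow mass (litre-equivalent
  at unit density) × \(RMECFF/(1-hct)\). Defaults \(RMECFF = 0.19\),
  \(hct = 0.41\) (multiplier 0.322) and a 0.9-kg marrow sized to a ~28-kg
  juvenile pig; all overridable, since published analyses rarely print the
  constants they used. Exact reproduction of any particular study's marrow
  TIACs therefore isn't attempted — the surrogate is validated for
  plausibility (results fall in the reference table's 0.01–0.25 h span)
  and linearity.
- **Heart.** The heart VOI is mapped to the phantom's heart source column;
  whether a published "heart" VOI means wall or contents is often
  ambiguous, so `dose_coefficients(source_map =)` lets the user remap
  (e.g. `c(heart = "heart_wall")`).

## Dose engine

S-values are an **input**, not a computed quantity: phantom dose-factor
tables are proprietary to the phantom software that tabulates them. The
package ships a small synthetic toy matrix (`toy_s_matrix()`, 7 × 7 with
masses) whose magnitudes are Lu-177-plausible (beta self-dose ≈ mean
energy per decay / organ mass; photon cross-doses ~10⁻⁴ mGy/MBq h) purely
for tests and examples. The remainder source uses the standard rest-of-body
adjustment
\[
S(t \leftarrow RoB) = \frac{S(t \leftarrow TB)\,m_{TB} -
\sum_k S(t \leftarrow k)\,m_k}{m_{TB} - \sum_k m_k},
\]
floored at zero with a warning. The engine itself is validated by
properties rather than by reproducing any phantom: it is exactly linear in
the TIACs, reduces to an elementwise product for a diagonal S-matrix, and
conserves the whole-body TIAC through the remainder closure.

**Reporting policy.** Human dose predictions are
coefficient × activity / 1000 (Gy), rounded to 3 significant figures at or
above 10 Gy and 2 below, with halves rounded up (a tiny relative guard
keeps decimal halves stored just below .5 in binary rounding up). Cohort
statistics are arithmetic mean and *sample* (n−1) SD; subject exclusions
are explicit flags recorded on the result, and the default is to exclude
no one — including a high-kidney-uptake subject keeps the assessment
conservative.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
any external data. It emulates the *structure* of a preclinical pig study:

- **Blood**: biexponential decay-corrected concentration, defaults
  \(f_\alpha = 0.801\), \(T_{1/2,\alpha} = 2.0\) min,
  \(T_{1/2,\beta} = 36\) min. The printed "% clearance in the α phase" is
  interpreted as an **amplitude** fraction (the standard reading for
  intercept-based fits), not an area fraction. The intercept
  \(c_0 = 20\) %IA/L is not a measured value; it is chosen so the
  noiseless model satisfies the reported "< 5 %IA/L at 10 min" bound, and
  is exposed as a parameter.
- **Organs**: uptake-washout curves
  \(u (1 - 2^{-t/T_u}) \sum_k f_k 2^{-t/\tau_k}\). The defaults are
  *calibration targets*, not measured rate constants: studies report
  TIACs, not organ rates, so uptake fractions and washout half-times were
  solved once, analytically, so the noiseless curves' TIACs land on the
  reference cohort means (kidneys 9.42 h, liver 4.24 h, spine 2.10 h,
  heart 1.25 h; whole-body retention 0.22 @ 1 h / 0.62 @ 61 h / 0.16 @
  2000 h giving 73.9 h against 74.02, with ≈23.4 % excreted by 4 h).
- **Urine**: cumulative excretion anchored exactly at 23.4 % at 4 h
  whatever the excretion half-time.
- **Noise**: multiplicative lognormal with unit mean (default fractional
  SD 0.05) — counting data are positive and heteroscedastic, and the
  dominant reported error is a 10 % systematic quantification error, so a
  5 % stochastic component is realistic. Between-subject variability is
  lognormal on uptake fractions (CV 25 %) and washout half-times (CV
  20 %), in line with the reference cohort's spread.
- **Schedule**: 12 early blood samples (0.5–300 min) plus days 2/4/6/10;
  three day-0 scans (1, 2, 3 h) plus days 2/4/10. All three day-0 scans
  are fitted as separate points; averaging them is a user choice upstream.
- **Pig-4 emulation**: `no_amino_acid =` doubles the kidney uptake
  fraction of listed subjects, mimicking the absence of nephroprotective
  amino-acid infusion. It is opt-in so the default cohort matches the
  protocol under which the calibration targets were reported.

What the generator does **not** emulate: receptor binding and saturation,
partial-volume and spill-over effects, reconstruction artefacts,
inter-organ correlation of noise, or physiologically based kinetics.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline arithmetic and fitting machinery* are correct under the study's
sampling structure — not that the kinetic model is biologically complete.

## Problem sizes used by the test suite

The suite runs entirely from code-generated data: 1000 noisy blood-curve
fits for the kinetics-recovery check, 20 replicate 5-subject cohorts for
the generator calibration check, 2000 bootstrap draws for the uncertainty
check, 1000-point grids for the integrator oracles. The whole suite
completes in well under a minute on a single CPU.

## Known limitations

- Exact reproduction of a published study's full cross-organ dose table
  requires that study's phantom S-value tables; with the toy matrix only
  engine *properties* are guaranteed.
- Monoexponential organ fits on 6-point schedules cannot represent early
  uptake; the resulting TIAC bias is small for fast-uptake organs
  (uptake half-times ≲ 0.5 h) but grows if uptake is slow.
- The fitter assumes independent multiplicative errors; correlated
  errors (e.g. a shared calibration factor) are represented only through
  the post-hoc 10 % systematic term.
- No inter-species mass scaling is applied anywhere; a conservative
  choice, consistent with reporting animal-derived TIACs as-is.
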