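Package: tiacdose
Title: Time-Integrated Activity Coefficients and MIRD-Schema Internal Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Internal dosimetry pipeline for Lu-177 peptide receptor
    radionuclide therapy studies: simulation of study-shaped time-activity
    data (biexponential blood clearance, organ uptake/washout, urinary
    excretion), weighted sum-of-exponentials curve fitting with corrected-AIC
    model selection, analytic and trapezoid-plus-tail computation of
    time-integrated activity coefficients (TIACs) with Gaussian error
    propagation, source-organ accounting (kidney summation, spine-to-bone
    scaling, remainder of body, blood-based red-marrow surrogate), and a
    MIRD-schema dose engine combining TIACs with a phantom S-value matrix to
    produce absorbed-dose coefficients, administered-activity dose
    predictions, cohort statistics and organ toxicity checks.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
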