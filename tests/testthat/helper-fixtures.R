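# Shared fixtures built in code.

study_blood_min <- c(0.5, 1, 2, 5, 10, 20, 30, 50, 75, 100, 200, 300)

# Noiseless blood curve on the early study schedule, in internal units.
noiseless_blood <- function(params = blood_model_params(),
                            times_min = study_blood_min) {
  tac_to_fraction(simulate_blood_tac(params, times_min, noise = NULL))
}

# An expsum_fit with known parameters, for testing the integrators
# independently of the fitter.
manual_fit <- function(amplitudes, rates_per_h, covariance = NULL,
                       organ = "liver", unit = "fraction_IA") {
  n <- length(amplitudes)
  if (is.null(covariance)) covariance <- matrix(0, 2 * n, 2 * n)
  structure(
    list(model = list(n_terms = n, amplitudes = amplitudes,
                      rates_per_h = rates_per_h),
         covariance = covariance, weighted_ssr = 0, aicc = NA_real_,
         n_points = 2 * n + 2, weighting = "relative", organ = organ,
         unit = unit, subject_id = "manual"),
    class = "expsum_fit")
}

# Tiny 2-source / 2-target S-matrix with hand-set values.
tiny_s <- function() {
  vals <- rbind(a = c(a = 0.5, b = 0.01, total_body = 0.06),
                b = c(a = 0.02, b = 0.4, total_body = 0.09))
  s_matrix("tiny", vals, c(a = 1, b = 2, total_body = 10))
}

lam_phys <- lu177()$decay_constant_per_h
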