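#' Biexponential blood clearance model parameters
#'
#' Decay-corrected blood concentration follows
#' \deqn{c(t) = c_0 [f_\alpha 2^{-t/T_{1/2,\alpha}} +
#'   (1-f_\alpha) 2^{-t/T_{1/2,\beta}}]}
#' with `t` in minutes. Defaults reproduce the study cohort's blood
#' kinetics: a fast distribution/clearance phase with a 2.0-min half-life
#' carrying 80.1 % of the amplitude, followed by a 36-min excretion phase.
#' The intercept `c0` (20 %IA/L) is chosen so that less than 5 % of the
#' injected activity per litre remains 10 min post-injection.
#'
#' @param c0 Intercept at t = 0, %IA per litre.
#' @param f_alpha Amplitude fraction of the fast phase, in (0, 1).
#' @param t_half_alpha_min Fast-phase half-life, minutes.
#' @param t_half_beta_min Slow-phase half-life, minutes (> alpha).
#' @return An object of class `blood_model_params`.
#' @export
blood_model_params <- function(c0 = 20, f_alpha = 0.801,
                               t_half_alpha_min = 2.0,
                               t_half_beta_min = 36) {
  stopifnot(c0 > 0, f_alpha > 0, f_alpha < 1,
            t_half_alpha_min > 0, t_half_beta_min > t_half_alpha_min)
  structure(list(c0 = c0, f_alpha = f_alpha,
                 t_half_alpha_min = t_half_alpha_min,
                 t_half_beta_min = t_half_beta_min),
            class = "blood_model_params")
}

#' Organ uptake/washout kinetic parameters
#'
#' Decay-corrected organ activity fraction follows an uptake-washout form
#' \deqn{a(t) = u (1 - 2^{-t/T_u}) \sum_k f_k 2^{-t/\tau_k}}
#' with `t` in hours, peak uptake fraction `u`, uptake half-time `T_u`
#' (`T_u = 0` means instantaneous uptake) and biological washout half-times
#' `tau_k` with fractions summing to 1. Defaults for each region are
#' calibrated so the analytic TIAC of the noiseless curve lands near the
#' study cohort means (see [organ_kinetic_defaults()]).
#'
#' @param organ Region label from [organ_vocabulary()].
#' @param uptake_fraction Peak fraction of injected activity, in `[0, 1]`.
#' @param uptake_half_time_h Uptake half-time, hours (>= 0; 0 = instant).
#' @param washout_fractions Washout-component fractions, summing to 1.
#' @param washout_half_times_h Biological washout half-times, hours (> 0).
#' @return An object of class `organ_kinetic_params`.
#' @export
organ_kinetic_params <- function(organ, uptake_fraction,
                                 uptake_half_time_h,
                                 washout_fractions,
                                 washout_half_times_h) {
  check_organ(organ)
  stopifnot(uptake_fraction >= 0, uptake_fraction <= 1,
            uptake_half_time_h >= 0,
            length(washout_fractions) == length(washout_half_times_h),
            all(washout_half_times_h > 0), all(washout_fractions >= 0))
  if (abs(sum(washout_fractions) - 1) > 1e-9) {
    stop("washout fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(list(organ = organ, uptake_fraction = uptake_fraction,
                 uptake_half_time_h = uptake_half_time_h,
                 washout_fractions = washout_fractions,
                 washout_half_times_h = washout_half_times_h),
            class = "organ_kinetic_params")
}

#' Default organ kinetics for the simulated cohort
#'
#' Uptake fractions and washout half-times are calibration targets: they are
#' set so the analytic TIAC (physical decay included) of each noiseless
#' default curve matches the study cohort mean TIACs (kidneys 9.42 h, liver
#' 4.24 h, spine 2.10 h, heart 1.25 h), and whole-body retention yields
#' ~23.4 % decay-corrected excretion within 4 h and a whole-body TIAC near
#' 74 h. They are surrogates, not measured rate constants.
#'
#' @return Named list of [organ_kinetic_params()] for `whole_body`, `liver`,
#'   `kidney_left`, `kidney_right`, `heart`, `bladder_contents`, `spine`.
#' @export
organ_kinetic_defaults <- function() {
  list(
    whole_body = organ_kinetic_params(
      "whole_body", uptake_fraction = 1.0, uptake_half_time_h = 0,
      washout_fractions = c(0.22, 0.62, 0.16),
      washout_half_times_h = c(1.0, 61, 2000)),
    liver = organ_kinetic_params(
      "liver", uptake_fraction = 0.0381, uptake_half_time_h = 0.25,
      washout_fractions = 1, washout_half_times_h = 150),
    kidney_left = organ_kinetic_params(
      "kidney_left", uptake_fraction = 0.0336, uptake_half_time_h = 0.25,
      washout_fractions = 1, washout_half_times_h = 250),
    kidney_right = organ_kinetic_params(
      "kidney_right", uptake_fraction = 0.0336, uptake_half_time_h = 0.25,
      washout_fractions = 1, washout_half_times_h = 250),
    heart = organ_kinetic_params(
      "heart", uptake_fraction = 0.0344, uptake_half_time_h = 0.05,
      washout_fractions = 1, washout_half_times_h = 30),
    bladder_contents = organ_kinetic_params(
      "bladder_contents", uptake_fraction = 0.04, uptake_half_time_h = 0.5,
      washout_fractions = 1, washout_half_times_h = 10),
    spine = organ_kinetic_params(
      "spine", uptake_fraction = 0.0150, uptake_half_time_h = 0.25,
      washout_fractions = 1, washout_half_times_h = 250))
}

#' Multiplicative measurement-noise model
#'
#' Each sample is multiplied by an independent lognormal factor with unit
#' median and the given fractional SD; counting data are positive and
#' heteroscedastic, which this preserves. `fractional_sd = 0` disables
#' noise.
#'
#' @param fractional_sd Fractional standard deviation (>= 0). Default 0.05.
#' @param seed Optional integer seed used when the noise is applied.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fractional_sd = 0.05, seed = NULL) {
  stopifnot(fractional_sd >= 0)
  structure(list(fractional_sd = fractional_sd, seed = seed),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (is.null(noise) || noise$fractional_sd == 0) return(values)
  sdlog <- sqrt(log(1 + noise$fractional_sd^2))
  with_seed(noise$seed,
            values * exp(stats::rnorm(length(values), 0, sdlog) - sdlog^2 / 2))
}

#' Cumulative urinary excretion model
#'
#' Decay-corrected cumulative excreted fraction
#' \deqn{E(t) = E_4 \frac{1 - 2^{-t/\tau}}{1 - 2^{-4/\tau}}}
#' anchored so that `E(4 h)` equals `cumulative_fraction_4h` exactly,
#' whatever the excretion half-time. The default 0.234 matches the
#' amino-acid-infused study animals.
#'
#' @param cumulative_fraction_4h Cumulative excreted fraction at 4 h, in
#'   `[0, 1]`. Default 0.234.
#' @param excretion_half_time_h Excretion half-time, hours. Default 1.
#' @return An object of class `urine_model`.
#' @export
urine_model <- function(cumulative_fraction_4h = 0.234,
                        excretion_half_time_h = 1) {
  stopifnot(cumulative_fraction_4h >= 0, cumulative_fraction_4h <= 1,
            excretion_half_time_h > 0)
  structure(list(cumulative_fraction_4h = cumulative_fraction_4h,
                 excretion_half_time_h = excretion_half_time_h),
            class = "urine_model")
}

#' Simulate a blood concentration time-activity curve
#'
#' Evaluates the biexponential blood model at the given times and applies
#' multiplicative lognormal noise. With zero noise the output is the exact
#' closed form.
#'
#' @param params A [blood_model_params()] object.
#' @param times_min Sampling times in minutes, non-empty, non-negative.
#' @param noise A [noise_model()] or `NULL` for noiseless output.
#' @param subject_id Subject label for the returned curve.
#' @return An [organ_tac()] for region `blood`, unit `percent_IA_per_L`,
#'   decay-corrected.
#' @export
#' @examples
#' simulate_blood_tac(blood_model_params(), times_min = c(0.5, 1, 2, 5, 10))
simulate_blood_tac <- function(params = blood_model_params(),
                               times_min, noise = NULL,
                               subject_id = "sim") {
  stopifnot(inherits(params, "blood_model_params"))
  if (length(times_min) == 0) stop("'times_min' must be non-empty", call. = FALSE)
  if (any(times_min < 0)) stop("'times_min' must be non-negative", call. = FALSE)
  c_t <- blood_model_value(params, times_min)
  organ_tac(subject_id, "blood", times_min / 60, apply_noise(c_t, noise),
            unit = "percent_IA_per_L", decay_corrected = TRUE)
}

#' Evaluate the noiseless blood model
#'
#' @param params A [blood_model_params()].
#' @param times_min Times in minutes.
#' @return Concentration in %IA/L at each time.
#' @export
blood_model_value <- function(params, times_min) {
  with(params,
       c0 * (f_alpha * 2^(-times_min / t_half_alpha_min) +
             (1 - f_alpha) * 2^(-times_min / t_half_beta_min)))
}

organ_model_value <- function(params, times_h) {
  uptake <- if (params$uptake_half_time_h == 0) 1
            else 1 - 2^(-times_h / params$uptake_half_time_h)
  washout <- rep(0, length(times_h))
  for (k in seq_along(params$washout_fractions)) {
    washout <- washout + params$washout_fractions[k] *
      2^(-times_h / params$washout_half_times_h[k])
  }
  params$uptake_fraction * uptake * washout
}

#' Simulate an organ time-activity curve
#'
#' Evaluates the uptake-washout model at the given times (decay-corrected
#' biological kinetics; physical decay is re-added at TIAC integration) and
#' applies multiplicative noise. Values never exceed the uptake fraction.
#'
#' @param params An [organ_kinetic_params()] object.
#' @param times_h Sampling times in hours, non-empty.
#' @param noise A [noise_model()] or `NULL`.
#' @param subject_id Subject label.
#' @return A decay-corrected [organ_tac()] in `fraction_IA`.
#' @export
simulate_organ_tac <- function(params, times_h, noise = NULL,
                               subject_id = "sim") {
  stopifnot(inherits(params, "organ_kinetic_params"))
  if (length(times_h) == 0) stop("'times_h' must be non-empty", call. = FALSE)
  a_t <- organ_model_value(params, times_h)
  organ_tac(subject_id, params$organ, times_h, apply_noise(a_t, noise),
            unit = "fraction_IA", decay_corrected = TRUE)
}

#' Analytic TIAC of a noiseless simulated organ curve
#'
#' Closed-form integral of the uptake-washout model times physical decay,
#' \eqn{\int_0^\infty a(t) e^{-\lambda_{phys} t} dt}, used to calibrate the
#' generator defaults and as an oracle in tests.
#'
#' @param params An [organ_kinetic_params()].
#' @param physics A [radionuclide()]; default [lu177()].
#' @return TIAC in hours.
#' @export
organ_model_tiac <- function(params, physics = lu177()) {
  lp <- physics$decay_constant_per_h
  lu <- if (params$uptake_half_time_h == 0) Inf
        else log(2) / params$uptake_half_time_h
  lk <- log(2) / params$washout_half_times_h
  terms <- params$washout_fractions *
    (1 / (lk + lp) - if (is.infinite(lu)) 0 else 1 / (lk + lp + lu))
  params$uptake_fraction * sum(terms)
}

#' Simulate cumulative urinary excretion
#'
#' Monotone non-decreasing decay-corrected cumulative excreted fraction on a
#' time grid up to `horizon_h`. Noise, if given, is applied to the
#' increments so monotonicity is preserved.
#'
#' @param model A [urine_model()].
#' @param horizon_h Horizon in hours (> 0).
#' @param times_h Optional explicit time grid (hours); default 0 to
#'   `horizon_h` in 0.5-h steps.
#' @param noise A [noise_model()] or `NULL`.
#' @return Data frame with columns `time_h` and `cumulative_fraction`.
#' @export
#' @examples
#' u <- simulate_urine(urine_model(), horizon_h = 4)
#' u$cumulative_fraction[u$time_h == 4]  # 0.234
simulate_urine <- function(model = urine_model(), horizon_h,
                           times_h = NULL, noise = NULL) {
  stopifnot(inherits(model, "urine_model"))
  if (horizon_h <= 0) stop("'horizon_h' must be positive", call. = FALSE)
  if (is.null(times_h)) times_h <- seq(0, horizon_h, by = 0.5)
  times_h <- sort(unique(c(0, times_h[times_h <= horizon_h])))
  tau <- model$excretion_half_time_h
  e <- model$cumulative_fraction_4h * (1 - 2^(-times_h / tau)) /
    (1 - 2^(-4 / tau))
  if (!is.null(noise) && noise$fractional_sd > 0) {
    inc <- apply_noise(diff(e), noise)
    e <- cumsum(c(e[1], inc))
  }
  data.frame(time_h = times_h, cumulative_fraction = e)
}

#' Study and dense sampling schedules
#'
#' The `"study"` preset reproduces the source study's sampling: 12 early
#' arterial blood samples (0.5-300 min) plus late samples at days 2, 4, 6
#' and 10; three scans in the first hours of day 0 plus scans at days 2, 4
#' and 10. The `"dense"` preset is a fine grid for oracle tests.
#'
#' @param preset `"study"` or `"dense"`.
#' @return List with `blood_min` (minutes) and `imaging_h` (hours).
#' @export
sampling_schedule <- function(preset = c("study", "dense")) {
  preset <- match.arg(preset)
  if (preset == "study") {
    list(blood_min = c(0.5, 1, 2, 5, 10, 20, 30, 50, 75, 100, 200, 300,
                       2 * 1440, 4 * 1440, 6 * 1440, 10 * 1440),
         imaging_h = c(1, 2, 3, 48, 96, 240))
  } else {
    list(blood_min = c(seq(0.5, 300, length.out = 40),
                       seq(720, 14400, by = 720)),
         imaging_h = c(seq(0.5, 6, by = 0.5), seq(12, 288, by = 12)))
  }
}

perturb_params <- function(p, cv_uptake, cv_halftime) {
  lsd_u <- sqrt(log(1 + cv_uptake^2))
  lsd_t <- sqrt(log(1 + cv_halftime^2))
  p$uptake_fraction <- min(1, p$uptake_fraction *
                             exp(stats::rnorm(1, 0, lsd_u) - lsd_u^2 / 2))
  p$washout_half_times_h <- p$washout_half_times_h *
    exp(stats::rnorm(length(p$washout_half_times_h), 0, lsd_t) - lsd_t^2 / 2)
  if (length(p$washout_fractions) > 1) {
    w <- p$washout_fractions * exp(stats::rnorm(length(p$washout_fractions),
                                                0, lsd_u) - lsd_u^2 / 2)
    p$washout_fractions <- w / sum(w)
  }
  p
}

#' Simulate a study-shaped cohort
#'
#' Generates `n_subjects` subjects with blood, organ and whole-body curves
#' on the given schedule. Between-subject variability is lognormal on
#' uptake fractions (default CV 25 %) and washout half-times (CV 20 %);
#' measurement noise is multiplicative lognormal per sample. Whole-body
#' retention is simulated with its own kinetics and floored at the sum of
#' the modelled organs so the accounting invariant (WB >= sum of sources)
#' holds at every sample. Subjects listed in `no_amino_acid` have their
#' kidney uptake fractions doubled, emulating a subject without the
#' nephroprotective amino-acid infusion.
#'
#' @param n_subjects Number of subjects (>= 1). Default 5.
#' @param seed Integer seed; same seed gives a bit-identical cohort.
#' @param schedule A [sampling_schedule()] list. Default study preset.
#' @param blood_params,organ_params,urine Generator parameter objects.
#' @param noise A [noise_model()]; default 5 % fractional SD.
#' @param subject_cv_uptake,subject_cv_halftime Between-subject lognormal
#'   CVs on uptake fractions and washout half-times.
#' @param no_amino_acid Integer indices of subjects without amino-acid
#'   infusion (kidney uptake doubled). Default none.
#' @return List of [subject()] objects, each with a `tacs` list containing
#'   blood, whole-body and organ curves plus a `urine` data frame.
#' @export
simulate_cohort <- function(n_subjects = 5, seed = 1,
                            schedule = sampling_schedule("study"),
                            blood_params = blood_model_params(),
                            organ_params = organ_kinetic_defaults(),
                            urine = urine_model(),
                            noise = noise_model(0.05),
                            subject_cv_uptake = 0.25,
                            subject_cv_halftime = 0.20,
                            no_amino_acid = integer()) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      id <- sprintf("sim%02d", i)
      pars <- lapply(organ_params, perturb_params,
                     cv_uptake = subject_cv_uptake,
                     cv_halftime = subject_cv_halftime)
      if (i %in% no_amino_acid) {
        for (k in c("kidney_left", "kidney_right")) {
          if (!is.null(pars[[k]]))
            pars[[k]]$uptake_fraction <- min(1, 2 * pars[[k]]$uptake_fraction)
        }
      }
      bp <- blood_params
      bp$c0 <- bp$c0 * exp(stats::rnorm(1, 0, 0.1))
      noise_i <- noise
      noise_i$seed <- NULL  # draws flow from the cohort RNG stream
      tacs <- list(blood = simulate_blood_tac(bp, schedule$blood_min,
                                              noise_i, subject_id = id))
      organ_names <- setdiff(names(pars), "whole_body")
      organ_vals <- matrix(0, nrow = length(schedule$imaging_h),
                           ncol = length(organ_names),
                           dimnames = list(NULL, organ_names))
      for (org in organ_names) {
        tac <- simulate_organ_tac(pars[[org]], schedule$imaging_h,
                                  noise_i, subject_id = id)
        organ_vals[, org] <- tac$value
        tacs[[org]] <- tac
      }
      wb_true <- organ_model_value(pars$whole_body, schedule$imaging_h)
      wb <- pmax(apply_noise(wb_true, noise_i), rowSums(organ_vals))
      tacs$whole_body <- organ_tac(id, "whole_body", schedule$imaging_h, wb,
                                   unit = "fraction_IA",
                                   decay_corrected = TRUE)
      tacs$urine <- simulate_urine(urine, horizon_h = 4,
                                   times_h = seq(0, 4, by = 0.5))
      subject(id,
              injected_activity_mbq = stats::runif(1, 97, 113),
              body_mass_kg = stats::runif(1, 25, 32),
              amino_acid_infusion = !(i %in% no_amino_acid),
              schedule = schedule, tacs = tacs)
    })
  })
}
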