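test_that("noiseless exponential data are recovered to high precision", {
  # monoexponential, A = 1, biological half-time 36 min
  lam <- log(2) / 0.6
  t <- c(0.1, 0.25, 0.5, 1, 2, 3, 4, 6)
  tac <- organ_tac("s", "blood", t, exp(-lam * t), unit = "fraction_IA_per_L")
  f <- fit_exp_sum(tac, 1)
  expect_equal(f$model$rates_per_h, lam, tolerance = 1e-6)
  expect_equal(f$model$amplitudes, 1, tolerance = 1e-6)
  expect_lt(f$weighted_ssr, 1e-12)

  # biexponential blood defaults on the 12-point study schedule
  f2 <- fit_exp_sum(noiseless_blood(), 2)
  hl_min <- sort(log(2) / f2$model$rates_per_h) * 60
  expect_equal(hl_min, c(2.0, 36), tolerance = 1e-4)
  # canonical ordering: fastest rate first
  expect_true(all(diff(f2$model$rates_per_h) <= 0))
})

test_that("fit preconditions are enforced with informative errors", {
  tac <- organ_tac("s", "liver", c(1, 2, 3), c(0.05, 0.04, 0.03))
  expect_error(fit_exp_sum(tac, 2), "at least 5 points")
  raw <- organ_tac("s", "liver", c(1, 2, 3), c(0.05, 0.04, 0.03),
                   decay_corrected = FALSE)
  expect_error(fit_exp_sum(raw, 1), "decay-corrected")
})

test_that("AICc selects parsimonious but sufficient models", {
  # one-term truth, dense noiseless sampling -> one term
  lam <- log(2) / 2
  t <- seq(0.2, 20, by = 0.4)
  tac <- organ_tac("s", "liver", t, 0.05 * exp(-lam * t))
  expect_equal(select_model(tac)$model$n_terms, 1L)

  # two well-separated terms (2 min / 36 min), study schedule -> two terms
  sel <- select_model(noiseless_blood())
  expect_equal(sel$model$n_terms, 2L)
  # brute-force AICc comparison across the fittable candidates
  aiccs <- sapply(1:3, function(n)
    fit_exp_sum(noiseless_blood(), n)$aicc)
  expect_equal(which.min(aiccs[1:2]), 2L)

  # three points: only the one-term candidate is fittable
  tac3 <- organ_tac("s", "liver", c(1, 24, 96), c(0.05, 0.045, 0.03))
  sel3 <- select_model(tac3)
  expect_equal(sel3$model$n_terms, 1L)
})

test_that("analytic TIAC matches closed forms and adaptive quadrature", {
  phys <- lu177()
  # no biological clearance: physical-decay bound 1/lambda = 230.16 h
  f <- manual_fit(1, 0)
  expect_equal(tiac_analytic(f, phys)$value_h, 230.16, tolerance = 1e-4)
  expect_equal(tiac_analytic(f, phys)$value_h, 1 / lam_phys,
               tolerance = 1e-12)
  # A = 0.5, lambda_bio = lambda_phys
  f2 <- manual_fit(0.5, lam_phys)
  expect_equal(tiac_analytic(f2, phys)$value_h, 0.25 / lam_phys,
               tolerance = 1e-12)
  # biexponential blood defaults as fraction in a 2-L pool vs quadrature
  A <- 0.20 / 2 * c(0.801, 0.199)
  lam <- log(2) / (c(2, 36) / 60)
  fb <- manual_fit(A, lam, unit = "fraction_IA_per_L")
  q <- integrate(function(t) (A[1] * exp(-lam[1] * t) +
                                A[2] * exp(-lam[2] * t)) *
                   exp(-lam_phys * t), 0, Inf, rel.tol = 1e-12)$value
  expect_equal(tiac_analytic(fb, phys)$value_h, q, tolerance = 1e-8)
})

test_that("systematic quantification error combines in quadrature, once", {
  t1 <- apply_systematic_error(tiac_result("liver", 10, 0))
  expect_equal(t1$se_h, 1.0)
  t2 <- apply_systematic_error(tiac_result("liver", 10, 1))
  expect_equal(t2$se_h, sqrt(2))
  t0 <- apply_systematic_error(tiac_result("liver", 0, 0.3))
  expect_equal(t0$se_h, 0.3)
  expect_error(apply_systematic_error(t1), "already applied")
})

test_that("trapezoid-plus-tail integration matches its oracles", {
  phys <- lu177()
  # dense sampling of pure physical decay from t = 0: limit 230.16 h
  t <- seq(0, 10 * phys$half_life_h, length.out = 1000)
  tac <- organ_tac("s", "whole_body", t, exp(-lam_phys * t),
                   decay_corrected = FALSE)
  ti <- tiac_trapezoid_tail(tac, phys)
  expect_equal(ti$value_h, 230.16, tolerance = 1e-3)
  expect_true(ti$includes_systematic)
  expect_equal(ti$se_h, 0.1 * ti$value_h)

  # two zero samples -> zero TIAC
  z <- organ_tac("s", "bladder_contents", c(1, 2), c(0, 0),
                 decay_corrected = FALSE)
  expect_equal(tiac_trapezoid_tail(z, phys)$value_h, 0)
  expect_error(tiac_trapezoid_tail(
    organ_tac("s", "bladder_contents", 1, 0.1), phys), "at least 2")

  # constant decay-corrected 0.01 at {1,2,4} h: hand-computed triangle +
  # trapezoids + physical-decay tail
  tac_c <- organ_tac("s", "bladder_contents", c(1, 2, 4), rep(0.01, 3))
  v <- 0.01 * exp(-lam_phys * c(1, 2, 4))
  expected <- v[1] / 2 +
    (v[1] + v[2]) / 2 + (v[2] + v[3]) / 2 * 2 +
    0.01 * exp(-lam_phys * 4) / lam_phys
  expect_equal(tiac_trapezoid_tail(tac_c, phys)$value_h, expected,
               tolerance = 1e-12)
})

test_that("analytic and trapezoid-tail integrators agree on dense data", {
  phys <- lu177()
  A <- c(0.03, 0.02)
  lam <- c(0.5, 0.01)
  t <- seq(0, 2000, length.out = 4000)
  corr <- A[1] * exp(-lam[1] * t[-1]) + A[2] * exp(-lam[2] * t[-1])
  tac <- organ_tac("s", "liver", t[-1], corr)
  trap <- tiac_trapezoid_tail(tac, phys)$value_h
  ana <- tiac_analytic(manual_fit(A, lam), phys)$value_h
  expect_equal(trap, ana, tolerance = 0.01)
})

test_that("propagated TIAC uncertainty matches a parametric bootstrap", {
  tac <- tac_to_fraction(simulate_blood_tac(
    blood_model_params(), study_blood_min, noise_model(0.05, seed = 21)))
  fit <- fit_exp_sum(tac, 2)
  ti <- tiac_analytic(fit)
  set.seed(33)
  draws <- MASS::mvrnorm(2000, c(fit$model$amplitudes, fit$model$rates_per_h),
                         fit$covariance)
  vals <- apply(draws, 1, function(p) {
    den <- p[3:4] + lam_phys
    if (any(den <= 0)) return(NA_real_)
    sum(p[1:2] / den)
  })
  boot_sd <- sd(vals, na.rm = TRUE)
  expect_equal(ti$se_h, boot_sd, tolerance = 0.15)
})

test_that("fitted TIACs respect the physical-decay upper bound", {
  set.seed(4)
  for (i in 1:10) {
    p <- organ_kinetic_params("kidney_left", runif(1, 0.01, 0.2),
                              runif(1, 0, 0.5), 1, runif(1, 20, 400))
    tac <- simulate_organ_tac(p, c(1, 2, 3, 48, 96, 240),
                              noise = noise_model(0.05))
    ti <- tiac_analytic(select_model(tac, n_starts = 5))
    expect_lte(ti$value_h, 1.2 * max(tac$value) / lam_phys)
    expect_lte(ti$value_h, 230.16)
  }
})
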