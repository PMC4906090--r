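#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

expsum_value <- function(amplitudes, rates, t) {
  drop(vapply(seq_along(amplitudes),
              function(i) amplitudes[i] * exp(-rates[i] * t),
              numeric(length(t))) %*% rep(1, length(amplitudes)))
}

# Weighted Jacobian of the residual sqrt(w) * (y - f) with respect to
# (A_1..A_n, lambda_1..lambda_n).
expsum_jacobian <- function(amplitudes, rates, t, sw) {
  n <- length(amplitudes)
  J <- matrix(0, length(t), 2 * n)
  for (i in seq_len(n)) {
    e <- exp(-rates[i] * t)
    J[, i]     <- -sw * e                       # d r / d A_i
    J[, n + i] <- sw * amplitudes[i] * t * e    # d r / d lambda_i
  }
  J
}

fit_weights <- function(y, weighting) {
  floor_y <- max(y) * 1e-8
  switch(weighting,
         relative = 1 / pmax(y, floor_y)^2,
         poisson  = 1 / pmax(y, floor_y),
         uniform  = rep(1, length(y)),
         stop("unknown weighting '", weighting, "'", call. = FALSE))
}

# Relative floor under the weighted SSR used in AICc: fits that have
# converged to machine precision are treated as exact ties so that
# parsimony, not floating-point noise, decides between them.
ssr_floor <- function(w, y) 1e-20 * sum(w * y^2)

#' Fit a sum of exponentials to a decay-corrected time-activity curve
#'
#' Weighted least-squares fit of
#' \eqn{f(t) = \sum_i A_i e^{-\lambda_i t}} with \eqn{A_i \ge 0},
#' \eqn{\lambda_i \ge 0} (rates are biological; physical decay is re-added
#' at integration). Initialisation is multistart: rates are drawn around a
#' log-spaced grid spanning the sampled time range and amplitudes are
#' obtained from a weighted linear solve, seeded for reproducibility. The
#' parameter covariance is computed from the weighted Jacobian at the
#' optimum. Terms are returned in canonical order (fastest rate first).
#'
#' @param tac A decay-corrected [organ_tac()].
#' @param n_terms Number of exponential terms (>= 1).
#' @param weighting `"relative"` (weights 1/value^2, constant fractional
#'   error, the gamma-counting default), `"poisson"` (1/value) or
#'   `"uniform"`.
#' @param n_starts Number of multistart initialisations. Default 20.
#' @param seed Integer seed for the start jitter. Default 1.
#' @return An object of class `expsum_fit` with elements `model`
#'   (`n_terms`, `amplitudes`, `rates_per_h`), `covariance` (order
#'   A_1..A_n, lambda_1..lambda_n), `weighted_ssr`, `aicc`, `n_points`,
#'   `weighting`, `organ`, `unit`, `subject_id`.
#' @export
fit_exp_sum <- function(tac, n_terms = 1,
                        weighting = c("relative", "poisson", "uniform"),
                        n_starts = 20, seed = 1) {
  stopifnot(inherits(tac, "organ_tac"), n_terms >= 1)
  weighting <- match.arg(weighting)
  if (!isTRUE(tac$decay_corrected)) {
    stop("fit_exp_sum() requires a decay-corrected curve; ",
         "use convert_decay_convention() first", call. = FALSE)
  }
  t <- tac$time_h
  y <- tac$value
  n_par <- 2L * n_terms
  if (length(t) < n_par + 1L) {
    stop(sprintf("need at least %d points to fit %d term(s), got %d",
                 n_par + 1L, n_terms, length(t)), call. = FALSE)
  }
  w <- fit_weights(y, weighting)
  sw <- sqrt(w)

  t_pos <- t[t > 0]
  lam_slow <- log(2) / (5 * max(t_pos))
  lam_fast <- log(2) / (0.2 * min(t_pos))
  grid <- if (n_terms == 1) sqrt(lam_slow * lam_fast)
          else exp(seq(log(lam_slow), log(lam_fast), length.out = n_terms))

  resid_fn <- function(p) {
    sw * (y - expsum_value(p[seq_len(n_terms)],
                           p[n_terms + seq_len(n_terms)], t))
  }
  jac_fn <- function(p) {
    expsum_jacobian(p[seq_len(n_terms)], p[n_terms + seq_len(n_terms)], t, sw)
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      jitter <- if (s == 1) rep(1, n_terms) else exp(stats::runif(n_terms, -log(4), log(4)))
      rates0 <- sort(grid * jitter, decreasing = TRUE)
      X <- vapply(rates0, function(l) exp(-l * t), numeric(length(t)))
      A0 <- tryCatch(qr.solve(sw * X, sw * y), error = function(e) NULL)
      if (is.null(A0)) A0 <- rep(max(y) / n_terms, n_terms)
      A0 <- pmax(A0, max(y) * 1e-4)
      # convergence is checked via `info`; non-converged starts are dropped
      ans <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = c(A0, rates0), lower = rep(0, n_par),
                             fn = resid_fn, jac = jac_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-14, ptol = 1e-14))),
        error = function(e) NULL)
      if (is.null(ans) || !ans$info %in% 1:4) next
      ssr <- ans$deviance
      if (is.null(best) || ssr < best$deviance - 1e-12 * best$deviance) {
        best <- ans
      }
    }
  })
  if (is.null(best)) {
    stop("exponential fit did not converge for subject ", tac$subject_id,
         ", region ", tac$organ, " after ", n_starts, " starts", call. = FALSE)
  }

  p <- best$par
  A <- p[seq_len(n_terms)]
  lam <- p[n_terms + seq_len(n_terms)]
  ord <- order(lam, decreasing = TRUE)  # canonical: fastest first
  A <- A[ord]; lam <- lam[ord]

  N <- length(t)
  ssr <- sum(w * (y - expsum_value(A, lam, t))^2)
  s2 <- if (N > n_par) ssr / (N - n_par) else 0
  J <- expsum_jacobian(A, lam, t, sw)
  JtJ <- crossprod(J)
  covm <- tryCatch(s2 * solve(JtJ), error = function(e) s2 * MASS::ginv(JtJ))
  covm <- (covm + t(covm)) / 2

  K <- n_par + 1L
  aicc <- if (N - K - 1L > 0L) {
    ssr_eff <- max(ssr, ssr_floor(w, y))
    N * log(ssr_eff / N) + 2 * K + 2 * K * (K + 1) / (N - K - 1)
  } else NA_real_

  structure(
    list(model = list(n_terms = n_terms, amplitudes = A, rates_per_h = lam),
         covariance = covm, weighted_ssr = ssr, aicc = aicc, n_points = N,
         weighting = weighting, organ = tac$organ, unit = tac$unit,
         subject_id = tac$subject_id),
    class = "expsum_fit")
}

#' @export
print.expsum_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("<expsum_fit> %s/%s: %d term(s), N = %d, wSSR = %.4g, AICc = %.4g\n",
              x$subject_id, x$organ, m$n_terms, x$n_points, x$weighted_ssr,
              x$aicc))
  hl <- log(2) / m$rates_per_h
  for (i in seq_len(m$n_terms)) {
    cat(sprintf("  A%d = %.4g, lambda%d = %.4g /h (T1/2 = %.4g h)\n",
                i, m$amplitudes[i], i, m$rates_per_h[i], hl[i]))
  }
  invisible(x)
}

#' Predicted values from a fitted exponential sum
#'
#' @param object An `expsum_fit`.
#' @param t_h Times in hours.
#' @param ... Unused.
#' @return Fitted decay-corrected values at `t_h`.
#' @export
predict.expsum_fit <- function(object, t_h, ...) {
  expsum_value(object$model$amplitudes, object$model$rates_per_h, t_h)
}

#' Select the number of exponential terms by corrected AIC
#'
#' Fits each candidate term count and returns the fit minimising
#' \deqn{AICc = N \ln(SSR_w/N) + 2K + \frac{2K(K+1)}{N-K-1}, \quad
#'   K = 2 n_{terms} + 1.}
#' Candidates with \eqn{N - K - 1 \le 0} carry no finite AICc and are only
#' used as a fallback (fewest terms) when no candidate has one; AICc ties
#' (including fits at the machine-precision SSR floor) go to the model with
#' fewer terms.
#'
#' @param tac A decay-corrected [organ_tac()].
#' @param candidates Candidate term counts. Default `1:3`.
#' @inheritParams fit_exp_sum
#' @return The selected `expsum_fit` (its `aicc` may be `NA` only when no
#'   candidate supported a finite AICc).
#' @export
select_model <- function(tac, candidates = 1:3,
                         weighting = c("relative", "poisson", "uniform"),
                         n_starts = 20, seed = 1) {
  weighting <- match.arg(weighting)
  fits <- list()
  errors <- character()
  for (n in sort(unique(candidates))) {
    f <- tryCatch(fit_exp_sum(tac, n_terms = n, weighting = weighting,
                              n_starts = n_starts, seed = seed),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "expsum_fit")) fits[[as.character(n)]] <- f
    else errors <- c(errors, f)
  }
  if (!length(fits)) {
    stop("no candidate model could be fitted: ",
         paste(unique(errors), collapse = "; "), call. = FALSE)
  }
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  if (all(is.na(aiccs))) {
    nt <- vapply(fits, function(f) f$model$n_terms, numeric(1))
    return(fits[[which.min(nt)]])
  }
  fits <- fits[!is.na(aiccs)]
  aiccs <- aiccs[!is.na(aiccs)]
  best <- min(aiccs)
  tied <- which(aiccs - best < 1e-6)
  nt <- vapply(fits[tied], function(f) f$model$n_terms, numeric(1))
  fits[tied][[which.min(nt)]]
}

#' Time-integrated activity coefficient result
#'
#' @param organ Region label.
#' @param value_h TIAC in hours (>= 0), per litre for blood concentration.
#' @param se_h Standard error in hours (>= 0).
#' @param method `"analytic"` or `"trapezoid_tail"`.
#' @param includes_systematic Whether the systematic quantification error
#'   has already been folded into `se_h`.
#' @param unit Unit of the underlying activity values.
#' @return An object of class `tiac_result`.
#' @export
tiac_result <- function(organ, value_h, se_h = 0, method = "analytic",
                        includes_systematic = FALSE, unit = "fraction_IA") {
  stopifnot(value_h >= 0, se_h >= 0,
            method %in% c("analytic", "trapezoid_tail"))
  structure(list(organ = organ, value_h = value_h, se_h = se_h,
                 method = method,
                 includes_systematic = isTRUE(includes_systematic),
                 unit = unit),
            class = "tiac_result")
}

#' @export
print.tiac_result <- function(x, ...) {
  cat(sprintf("<tiac> %s: %.4g +/- %.4g h (%s%s)\n", x$organ, x$value_h,
              x$se_h, x$method,
              if (x$includes_systematic) ", incl. systematic" else ""))
  invisible(x)
}

#' Analytic TIAC from a fitted exponential sum
#'
#' Integrates the fitted decay-corrected curve times physical decay in
#' closed form, \eqn{\sum_i A_i / (\lambda_i + \lambda_{phys})} (hours).
#' The standard error is Gaussian error propagation through the fit
#' covariance, \eqn{\sqrt{g^T C g}} with \eqn{g} the gradient of the TIAC
#' with respect to the fit parameters.
#'
#' @param fit An `expsum_fit` on decay-corrected data.
#' @param physics A [radionuclide()]; default [lu177()].
#' @return A [tiac_result()] with `method = "analytic"` and
#'   `includes_systematic = FALSE`.
#' @export
tiac_analytic <- function(fit, physics = lu177()) {
  stopifnot(inherits(fit, "expsum_fit"))
  A <- fit$model$amplitudes
  lam <- fit$model$rates_per_h
  lp <- physics$decay_constant_per_h
  denom <- lam + lp
  if (any(denom <= 0)) {
    stop("effective rate lambda_bio + lambda_phys must be positive; ",
         "curve is non-integrable", call. = FALSE)
  }
  value <- sum(A / denom)
  g <- c(1 / denom, -A / denom^2)
  se <- sqrt(max(0, drop(t(g) %*% fit$covariance %*% g)))
  tiac_result(fit$organ, value, se, method = "analytic", unit = fit$unit)
}

#' Fold in the systematic activity-quantification error
#'
#' Adds a systematic fractional error (default 10 % of the TIAC value) in
#' quadrature with the statistical standard error. Refuses double
#' application.
#'
#' @param tiac A [tiac_result()] with `includes_systematic = FALSE`.
#' @param fraction Systematic fractional error. Default 0.10.
#' @return The updated [tiac_result()] with the flag set.
#' @export
apply_systematic_error <- function(tiac, fraction = 0.10) {
  stopifnot(inherits(tiac, "tiac_result"), fraction >= 0)
  if (tiac$includes_systematic) {
    stop("systematic error already applied to this TIAC", call. = FALSE)
  }
  tiac$se_h <- sqrt(tiac$se_h^2 + (fraction * tiac$value_h)^2)
  tiac$includes_systematic <- TRUE
  tiac
}

#' Trapezoidal TIAC with a physical-decay tail
#'
#' Integrates a measured (not decay-corrected) curve by the trapezoidal
#' rule — with a leading triangle from (0, 0) to the first sample when that
#' sample is at t > 0 — and adds a tail assuming pure physical decay after
#' the last point, \eqn{v_n / \lambda_{phys}}. Decay-corrected input is
#' converted to the measured convention first. The standard error applies
#' the 10 % systematic quantification rule.
#'
#' @param tac An [organ_tac()] with at least two samples.
#' @param physics A [radionuclide()]; default [lu177()].
#' @param systematic_fraction Systematic fractional error. Default 0.10.
#' @return A [tiac_result()] with `method = "trapezoid_tail"` and
#'   `includes_systematic = TRUE`.
#' @export
tiac_trapezoid_tail <- function(tac, physics = lu177(),
                                systematic_fraction = 0.10) {
  stopifnot(inherits(tac, "organ_tac"))
  if (length(tac$time_h) < 2L) {
    stop("trapezoidal integration needs at least 2 samples", call. = FALSE)
  }
  tac <- convert_decay_convention(tac, physics, "uncorrected")
  t <- tac$time_h
  v <- tac$value
  trap <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  if (t[1] > 0) trap <- trap + t[1] * v[1] / 2
  tail_term <- v[length(v)] / physics$decay_constant_per_h
  value <- trap + tail_term
  tiac_result(tac$organ, value, se_h = systematic_fraction * value,
              method = "trapezoid_tail", includes_systematic = TRUE,
              unit = tac$unit)
}
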