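#' Radionuclide physical constants
#'
#' Container for the physical decay data needed by the dosimetry pipeline.
#' All internal times are hours; the decay constant is derived as
#' \eqn{\lambda = \ln 2 / T_{1/2}}.
#'
#' @param name Nuclide label, e.g. `"Lu-177"`.
#' @param half_life_h Physical half-life in hours (> 0).
#' @param photon_emissions Optional data frame with columns `energy_kev` and
#'   `probability` (per decay, in (0, 1]). Informational only; the dose
#'   engine works from S-values, not from emissions.
#'
#' @return An object of class `radionuclide` with fields `name`,
#'   `half_life_h`, `decay_constant_per_h` and `photon_emissions`.
#' @seealso [lu177()] for the built-in Lutetium-177 record.
#' @export
radionuclide <- function(name, half_life_h, photon_emissions = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("'half_life_h' must be a single positive number", call. = FALSE)
  }
  if (!is.null(photon_emissions)) {
    stopifnot(is.data.frame(photon_emissions),
              all(c("energy_kev", "probability") %in% names(photon_emissions)))
    p <- photon_emissions$probability
    if (any(p <= 0 | p > 1)) {
      stop("photon emission probabilities must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(
    list(name = name,
         half_life_h = half_life_h,
         decay_constant_per_h = log(2) / half_life_h,
         photon_emissions = photon_emissions),
    class = "radionuclide")
}

#' Built-in Lutetium-177 physical data
#'
#' Lu-177 decays with a 6.647-day half-life (159.528 h) by beta emission,
#' with principal gamma lines at 208.3 keV (10.38 %) and 112.9 keV (6.2 %).
#'
#' @return A `radionuclide` object for Lu-177.
#' @export
#' @examples
#' lu177()$decay_constant_per_h  # ~ 4.345e-3 per hour
lu177 <- function() {
  radionuclide(
    name = "Lu-177",
    half_life_h = 6.647 * 24,
    photon_emissions = data.frame(
      energy_kev  = c(208.3, 112.9),
      probability = c(0.1038, 0.062)))
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide> %s: T1/2 = %.4g h (%.4g d), lambda = %.4g /h\n",
              x$name, x$half_life_h, x$half_life_h / 24,
              x$decay_constant_per_h))
  invisible(x)
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `t_h` hours of physical decay,
#' \eqn{\exp(-\lambda t)}.
#'
#' @param physics A [radionuclide()] object.
#' @param t_h Time in hours, non-negative (vectorised).
#' @return Numeric vector in (0, 1].
#' @export
#' @examples
#' decay_factor(lu177(), 159.528)  # one half-life -> 0.5
decay_factor <- function(physics, t_h) {
  stopifnot(inherits(physics, "radionuclide"))
  if (!is.numeric(t_h) || any(!is.finite(t_h)) || any(t_h < 0)) {
    stop("'t_h' must be finite and non-negative", call. = FALSE)
  }
  exp(-physics$decay_constant_per_h * t_h)
}

#' Switch the decay-correction convention of a time-activity curve
#'
#' Measured activities are either left as measured ("uncorrected", physical
#' decay still present) or corrected back to the time of injection
#' ("corrected", biological kinetics only). Correction multiplies each value
#' by \eqn{\exp(+\lambda t)}; the two conventions are exact inverses.
#'
#' @param tac An [organ_tac()] object.
#' @param physics A [radionuclide()] object.
#' @param target One of `"corrected"` or `"uncorrected"`.
#' @return The converted `organ_tac`; the identity if already in the target
#'   convention.
#' @export
convert_decay_convention <- function(tac, physics,
                                     target = c("corrected", "uncorrected")) {
  stopifnot(inherits(tac, "organ_tac"))
  target <- match.arg(target)
  current <- if (isTRUE(tac$decay_corrected)) "corrected" else "uncorrected"
  if (current == target) return(tac)
  f <- decay_factor(physics, tac$time_h)
  tac$value <- if (target == "uncorrected") tac$value * f else tac$value / f
  tac$decay_corrected <- target == "corrected"
  tac
}
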