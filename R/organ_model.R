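#' Normalise a subject's scans to the first whole-body uptake
#'
#' Image-derived uptakes lack an absolute calibration; the convention is to
#' set the whole-body uptake of the first scan to 100 % of the injected
#' activity and scale every region at every time by the same factor. The
#' operation is idempotent.
#'
#' @param tacs Named list of [organ_tac()] objects for one subject,
#'   containing a `whole_body` curve.
#' @return The scaled list; the first whole-body sample becomes exactly 1.
#' @export
normalize_to_first_whole_body <- function(tacs) {
  wb <- tacs$whole_body
  if (is.null(wb)) {
    stop("no 'whole_body' curve present; cannot normalise", call. = FALSE)
  }
  v1 <- wb$value[which.min(wb$time_h)]
  if (!is.finite(v1) || v1 <= 0) {
    stop("first-scan whole-body value must be positive", call. = FALSE)
  }
  lapply(tacs, function(tac) {
    if (inherits(tac, "organ_tac")) tac$value <- tac$value / v1
    tac
  })
}

#' Sum left and right kidney TIACs
#'
#' @param left,right [tiac_result()] objects for the two kidneys.
#' @return A [tiac_result()] for region `kidneys`; the value is the sum and
#'   the standard errors combine in quadrature.
#' @export
#' @examples
#' sum_kidneys(tiac_result("kidney_left", 4.18), tiac_result("kidney_right", 3.29))
sum_kidneys <- function(left, right) {
  stopifnot(inherits(left, "tiac_result"), inherits(right, "tiac_result"))
  if (left$includes_systematic != right$includes_systematic) {
    stop("kidney TIACs disagree on whether systematic error is included",
         call. = FALSE)
  }
  tiac_result("kidneys", left$value_h + right$value_h,
              sqrt(left$se_h^2 + right$se_h^2),
              method = left$method,
              includes_systematic = left$includes_systematic)
}

#' Derive the skeletal (bone) TIAC from the spine TIAC
#'
#' The spine VOI is taken to contain a fixed fraction of the total skeleton
#' mass (default 19 %); the whole-skeleton TIAC is the spine TIAC divided
#' by that fraction, with the standard error scaled identically.
#'
#' @param spine A [tiac_result()] for region `spine`.
#' @param spine_mass_fraction Spine share of skeleton mass, in (0, 1].
#'   Default 0.19.
#' @return A [tiac_result()] for region `bone`.
#' @export
#' @examples
#' bone_from_spine(tiac_result("spine", 0.57))$value_h  # 3.0
bone_from_spine <- function(spine, spine_mass_fraction = 0.19) {
  stopifnot(inherits(spine, "tiac_result"))
  if (spine_mass_fraction <= 0 || spine_mass_fraction > 1) {
    stop("'spine_mass_fraction' must lie in (0, 1]", call. = FALSE)
  }
  tiac_result("bone", spine$value_h / spine_mass_fraction,
              spine$se_h / spine_mass_fraction, method = spine$method,
              includes_systematic = spine$includes_systematic)
}

#' Remainder-of-body TIAC
#'
#' Whole-body TIAC minus the explicit source organs (liver, kidneys, heart,
#' bladder contents, bone, red marrow). A negative difference — possible
#' only through rounding or noise — is clipped to zero with a warning.
#'
#' @param tiacs Named list of [tiac_result()] objects containing all six
#'   explicit sources.
#' @param whole_body A [tiac_result()] for `whole_body`.
#' @return A [tiac_result()] for region `remainder` (SE combined in
#'   quadrature).
#' @export
remainder_tiac <- function(tiacs, whole_body) {
  stopifnot(inherits(whole_body, "tiac_result"))
  needed <- c("liver", "kidneys", "heart", "bladder_contents", "bone",
              "red_marrow")
  missing <- setdiff(needed, names(tiacs))
  if (length(missing)) {
    stop("missing source region(s) for remainder: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(tiacs[needed], function(x) x$value_h, numeric(1))
  ses <- vapply(tiacs[needed], function(x) x$se_h, numeric(1))
  value <- whole_body$value_h - sum(vals)
  if (value < 0) {
    warning("remainder TIAC negative (", signif(value, 3),
            " h); clipped to 0", call. = FALSE)
    value <- 0
  }
  tiac_result("remainder", value, sqrt(whole_body$se_h^2 + sum(ses^2)),
              method = whole_body$method,
              includes_systematic = whole_body$includes_systematic)
}

#' Red-marrow blood-surrogate parameters
#'
#' Parameters of the blood-based marrow dose surrogate: the activity
#' concentration in marrow extracellular fluid is assumed equal to that in
#' plasma, so the marrow-to-blood concentration ratio is
#' \eqn{RMECFF / (1 - hematocrit)}.
#'
#' @param rmecff Red-marrow extracellular fluid fraction, in (0, 1).
#'   Default 0.19.
#' @param hematocrit Haematocrit, in (0, 1). Default 0.41.
#' @param red_marrow_mass_kg Red-marrow mass in kg (> 0); litre-equivalent
#'   at unit density. Default 0.9, sized to a juvenile ~28-kg pig.
#' @return An object of class `marrow_params`.
#' @export
marrow_params <- function(rmecff = 0.19, hematocrit = 0.41,
                          red_marrow_mass_kg = 0.9) {
  stopifnot(rmecff > 0, rmecff < 1, red_marrow_mass_kg > 0)
  if (hematocrit <= 0 || hematocrit >= 1) {
    stop("'hematocrit' must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(rmecff = rmecff, hematocrit = hematocrit,
                 red_marrow_mass_kg = red_marrow_mass_kg),
            class = "marrow_params")
}

#' Red-marrow TIAC from the blood-concentration TIAC
#'
#' Blood-based marrow surrogate: the marrow TIAC is the blood concentration
#' TIAC (h per litre, from the fitted blood curve) times the marrow volume
#' (litre-equivalent of its mass) times the marrow-to-blood concentration
#' ratio \eqn{RMECFF / (1 - hematocrit)}.
#'
#' @param blood_conc_tiac A [tiac_result()] from the blood curve with unit
#'   `fraction_IA_per_L` (h/L), or a bare numeric value in h/L.
#' @param params A [marrow_params()] object.
#' @return A [tiac_result()] for region `red_marrow` in hours.
#' @export
red_marrow_tiac_shen <- function(blood_conc_tiac, params = marrow_params()) {
  stopifnot(inherits(params, "marrow_params"))
  if (is.numeric(blood_conc_tiac)) {
    blood_conc_tiac <- tiac_result("blood", blood_conc_tiac,
                                   unit = "fraction_IA_per_L")
  }
  stopifnot(inherits(blood_conc_tiac, "tiac_result"))
  if (blood_conc_tiac$unit != "fraction_IA_per_L") {
    stop("blood TIAC must be on a per-litre fraction basis ",
         "(unit 'fraction_IA_per_L')", call. = FALSE)
  }
  mult <- params$red_marrow_mass_kg * params$rmecff / (1 - params$hematocrit)
  tiac_result("red_marrow", blood_conc_tiac$value_h * mult,
              blood_conc_tiac$se_h * mult,
              method = blood_conc_tiac$method,
              includes_systematic = blood_conc_tiac$includes_systematic)
}

#' Assemble the source-organ TIAC set for dosimetry
#'
#' Runs the accounting steps that turn raw per-region TIACs into the source
#' set used by the dose engine: left + right kidney summation, spine-to-bone
#' scaling, the blood-based red-marrow surrogate and the remainder-of-body
#' closure. The spine TIAC is retained alongside the derived bone TIAC for
#' reporting.
#'
#' @param subject_id Subject label.
#' @param tiacs Named list of [tiac_result()] objects with entries
#'   `whole_body`, `liver`, `kidney_left`, `kidney_right`, `heart`,
#'   `bladder_contents`, `spine` and `blood` (per-litre).
#' @param spine_mass_fraction Spine share of skeleton mass. Default 0.19.
#' @param marrow A [marrow_params()] object.
#' @return An object of class `source_organ_set`: list with `subject_id`
#'   and `tiacs` (named [tiac_result()] list including `kidneys`, `bone`,
#'   `red_marrow` and `remainder`).
#' @export
build_source_organ_set <- function(subject_id, tiacs,
                                   spine_mass_fraction = 0.19,
                                   marrow = marrow_params()) {
  needed <- c("whole_body", "liver", "kidney_left", "kidney_right", "heart",
              "bladder_contents", "spine", "blood")
  missing <- setdiff(needed, names(tiacs))
  if (length(missing)) {
    stop("missing TIAC(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tiacs
  out$kidneys <- sum_kidneys(tiacs$kidney_left, tiacs$kidney_right)
  out$bone <- bone_from_spine(tiacs$spine, spine_mass_fraction)
  out$red_marrow <- red_marrow_tiac_shen(tiacs$blood, marrow)
  out$remainder <- remainder_tiac(out, tiacs$whole_body)
  structure(list(subject_id = as.character(subject_id), tiacs = out),
            class = "source_organ_set")
}

#' @export
print.source_organ_set <- function(x, ...) {
  cat(sprintf("<source_organ_set> subject %s\n", x$subject_id))
  for (nm in names(x$tiacs)) {
    cat(sprintf("  %-16s %8.4g h\n", nm, x$tiacs[[nm]]$value_h))
  }
  invisible(x)
}

#' Source-organ set as a data frame
#'
#' @param x A `source_organ_set`.
#' @param ... Unused.
#' @return Data frame with columns `subject_id`, `organ`, `tiac_h`, `se_h`,
#'   `method`.
#' @export
as.data.frame.source_organ_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$tiacs), function(nm) {
    ti <- x$tiacs[[nm]]
    data.frame(subject_id = x$subject_id, organ = nm, tiac_h = ti$value_h,
               se_h = ti$se_h, method = ti$method, stringsAsFactors = FALSE)
  }))
}
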