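#' Controlled vocabulary of source regions
#'
#' Region labels accepted by the pipeline. Unknown labels are rejected on
#' construction and ingest so that accounting errors surface early.
#'
#' @return Character vector of accepted region names.
#' @export
organ_vocabulary <- function() {
  c("whole_body", "remainder", "liver", "kidney_left", "kidney_right",
    "kidneys", "heart", "bladder_contents", "spine", "bone", "red_marrow",
    "blood")
}

check_organ <- function(organ) {
  if (!is.character(organ) || length(organ) != 1L ||
      !(organ %in% organ_vocabulary())) {
    stop("unknown region '", organ, "'; accepted labels: ",
         paste(organ_vocabulary(), collapse = ", "), call. = FALSE)
  }
  organ
}

#' Time-activity curve for one region of one subject
#'
#' Ordered activity samples for a single source region. Times are hours
#' post-injection; values are fraction of injected activity (`fraction_IA`),
#' or fraction of injected activity per litre for blood concentration
#' (`fraction_IA_per_L`), or their percent forms. All samples of a curve
#' share one decay-correction convention.
#'
#' @param subject_id Subject identifier (character or integer).
#' @param organ Region label from [organ_vocabulary()].
#' @param time_h Sample times in hours, strictly increasing, >= 0.
#' @param value Activity values, non-negative, same length as `time_h`.
#' @param unit One of `"fraction_IA"`, `"percent_IA"`, `"fraction_IA_per_L"`,
#'   `"percent_IA_per_L"`.
#' @param decay_corrected Logical flag: `TRUE` if values are corrected to
#'   the time of injection (biological kinetics only).
#' @return An object of class `organ_tac`.
#' @export
organ_tac <- function(subject_id, organ, time_h, value,
                      unit = "fraction_IA", decay_corrected = TRUE) {
  check_organ(organ)
  unit <- match.arg(unit, c("fraction_IA", "percent_IA",
                            "fraction_IA_per_L", "percent_IA_per_L"))
  stopifnot(is.numeric(time_h), is.numeric(value),
            length(time_h) == length(value), length(time_h) >= 1L)
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    stop("sample times must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("activity values must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), organ = organ,
         time_h = as.numeric(time_h), value = as.numeric(value),
         unit = unit, decay_corrected = isTRUE(decay_corrected)),
    class = "organ_tac")
}

#' @export
print.organ_tac <- function(x, ...) {
  cat(sprintf("<organ_tac> subject %s, %s: %d samples over %.3g-%.3g h [%s, %s]\n",
              x$subject_id, x$organ, length(x$time_h),
              min(x$time_h), max(x$time_h), x$unit,
              if (x$decay_corrected) "decay-corrected" else "as measured"))
  invisible(x)
}

#' @export
as.data.frame.organ_tac <- function(x, ...) {
  data.frame(subject_id = x$subject_id, organ = x$organ,
             time_h = x$time_h, value = x$value,
             unit = x$unit, decay_corrected = x$decay_corrected,
             stringsAsFactors = FALSE)
}

#' Convert a TAC to internal units (fraction of IA, hours)
#'
#' Percent units are divided by 100; the per-litre distinction is kept.
#'
#' @param tac An [organ_tac()].
#' @return The same curve in `fraction_IA` or `fraction_IA_per_L`.
#' @export
tac_to_fraction <- function(tac) {
  stopifnot(inherits(tac, "organ_tac"))
  if (tac$unit == "percent_IA") {
    tac$value <- tac$value / 100; tac$unit <- "fraction_IA"
  } else if (tac$unit == "percent_IA_per_L") {
    tac$value <- tac$value / 100; tac$unit <- "fraction_IA_per_L"
  }
  tac
}

#' Study subject
#'
#' @param subject_id Identifier.
#' @param injected_activity_mbq Injected activity in MBq (> 0).
#' @param body_mass_kg Body mass in kg (> 0).
#' @param amino_acid_infusion Logical; whether a nephroprotective amino acid
#'   infusion was given.
#' @param schedule Optional list of sampling/imaging time vectors (hours).
#' @param tacs Optional named list of [organ_tac()] objects.
#' @return An object of class `dosimetry_subject`.
#' @export
subject <- function(subject_id, injected_activity_mbq = 105,
                    body_mass_kg = 28, amino_acid_infusion = TRUE,
                    schedule = NULL, tacs = list()) {
  stopifnot(injected_activity_mbq > 0, body_mass_kg > 0)
  structure(
    list(subject_id = as.character(subject_id),
         injected_activity_mbq = injected_activity_mbq,
         body_mass_kg = body_mass_kg,
         amino_acid_infusion = isTRUE(amino_acid_infusion),
         schedule = schedule, tacs = tacs),
    class = "dosimetry_subject")
}

#' @export
print.dosimetry_subject <- function(x, ...) {
  cat(sprintf("<subject> %s: %.3g MBq injected, %.3g kg, amino acids: %s, %d TACs\n",
              x$subject_id, x$injected_activity_mbq, x$body_mass_kg,
              if (x$amino_acid_infusion) "yes" else "no", length(x$tacs)))
  invisible(x)
}

time_to_hours <- function(time, unit) {
  mult <- c(s = 1 / 3600, min = 1 / 60, minute = 1 / 60, minutes = 1 / 60,
            h = 1, hour = 1, hours = 1, d = 24, day = 24, days = 24)
  m <- mult[tolower(unit)]
  if (any(is.na(m))) {
    stop("unknown time unit(s): ",
         paste(unique(unit[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  time * as.numeric(m)
}

#' Read time-activity curves from CSV
#'
#' Expected columns: `subject_id`, `organ`, `time`, `time_unit`, `value`,
#' `value_unit`, `decay_corrected` (true/false). One row per sample. Times
#' are converted to hours and percent values to fractions on ingest.
#'
#' @param path CSV file path.
#' @return Named list of [organ_tac()] objects, names `"<subject>.<organ>"`.
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "organ", "time", "time_unit", "value",
              "value_unit", "decay_corrected")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("TAC CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$time_h <- time_to_hours(df$time, df$time_unit)
  key <- paste(df$subject_id, df$organ, sep = ".")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_h), ]
    dc <- unique(as.logical(d$decay_corrected))
    if (length(dc) != 1L) {
      stop("mixed decay-correction conventions for ", d$subject_id[1], "/",
           d$organ[1], call. = FALSE)
    }
    unit <- unique(d$value_unit)
    if (length(unit) != 1L) {
      stop("mixed value units for ", d$subject_id[1], "/", d$organ[1],
           call. = FALSE)
    }
    tac_to_fraction(organ_tac(d$subject_id[1], d$organ[1], d$time_h, d$value,
                              unit = unit, decay_corrected = dc))
  })
  out[order(names(out))]
}

#' Write time-activity curves to CSV
#'
#' Inverse of [read_tac_csv()]: hours and internal units are written with
#' explicit unit columns.
#'
#' @param tacs A list of [organ_tac()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "organ_tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(tac) {
    data.frame(subject_id = tac$subject_id, organ = tac$organ,
               time = tac$time_h, time_unit = "h", value = tac$value,
               value_unit = tac$unit, decay_corrected = tac$decay_corrected,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
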