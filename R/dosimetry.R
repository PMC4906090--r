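#' Phantom S-value matrix
#'
#' Target-by-source table of absorbed dose per unit time-integrated
#' activity (mGy per MBq h) for a phantom geometry, plus the phantom's
#' region masses. S-values are an external input to the pipeline: they come
#' from phantom dose-factor tabulations (e.g. OLINDA-style tables) and are
#' not computed here.
#'
#' @param phantom Phantom name.
#' @param values Numeric matrix, rows = target regions, columns = source
#'   regions, all >= 0, with dimnames.
#' @param masses_kg Named numeric vector of region masses in kg, containing
#'   every source column plus `total_body`.
#' @return An object of class `s_matrix`.
#' @export
s_matrix <- function(phantom, values, masses_kg) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)), all(values >= 0),
            is.numeric(masses_kg), !is.null(names(masses_kg)))
  if (!"total_body" %in% names(masses_kg)) {
    stop("'masses_kg' must include 'total_body'", call. = FALSE)
  }
  missing_mass <- setdiff(colnames(values), names(masses_kg))
  if (length(missing_mass)) {
    stop("mass missing for source column(s): ",
         paste(missing_mass, collapse = ", "), call. = FALSE)
  }
  if (any(masses_kg <= 0)) stop("masses must be positive", call. = FALSE)
  shared <- intersect(rownames(values), colnames(values))
  for (r in shared) {
    if (any(values[r, r] < values[r, setdiff(colnames(values), r)])) {
      warning("self-dose S(", r, "<-", r, ") is below a cross-dose value; ",
              "check the table for a beta-dominated nuclide", call. = FALSE)
    }
  }
  structure(list(phantom = phantom, values = values, masses_kg = masses_kg),
            class = "s_matrix")
}

#' @export
print.s_matrix <- function(x, ...) {
  cat(sprintf("<s_matrix> phantom '%s': %d targets x %d sources [mGy/(MBq h)]\n",
              x$phantom, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an S-value matrix from CSV
#'
#' Layout: first column `target`, remaining columns one per source region,
#' values in mGy per MBq h; lines starting with `#` are comments. The
#' sidecar mass table has columns `region` and `mass_kg` and must include
#' `total_body`.
#'
#' @param path S-value CSV path.
#' @param masses_path Mass-table CSV path.
#' @param phantom Phantom name recorded on the object.
#' @return An [s_matrix()] object.
#' @export
read_s_matrix <- function(path, masses_path, phantom = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (names(df)[1] != "target") {
    stop("S-matrix CSV must have 'target' as its first column", call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$target
  md <- utils::read.csv(masses_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  masses <- stats::setNames(md$mass_kg, md$region)
  s_matrix(phantom, values, masses)
}

#' Bundled toy S-value matrix
#'
#' A small synthetic phantom table (7 targets x 7 sources, masses included)
#' for tests and examples. Its self-dose magnitudes are Lu-177-plausible
#' but it is not any published phantom; real analyses must supply their own
#' phantom tables.
#'
#' @return An [s_matrix()] object.
#' @export
toy_s_matrix <- function() {
  read_s_matrix(
    system.file("extdata", "toy_s_matrix.csv", package = "tiacdose"),
    system.file("extdata", "toy_s_masses.csv", package = "tiacdose"),
    phantom = "toy-synthetic")
}

#' Remainder-of-body S-value
#'
#' Standard MIRD-style rest-of-body adjustment: with total-body S-value
#' \eqn{S(t \leftarrow TB)}, explicit source organs k and masses m,
#' \deqn{S(t \leftarrow RoB) = \frac{S(t \leftarrow TB) m_{TB} -
#'   \sum_k S(t \leftarrow k) m_k}{m_{TB} - \sum_k m_k}.}
#' Negative results are floored at zero with a warning.
#'
#' @param S An [s_matrix()] containing a `total_body` column and masses for
#'   all explicit sources.
#' @param target Target region (row name).
#' @param explicit_sources Character vector of explicit source regions
#'   (may be empty, in which case the total-body S-value is returned).
#' @return S-value in mGy per MBq h.
#' @export
remainder_s_value <- function(S, target, explicit_sources = character()) {
  stopifnot(inherits(S, "s_matrix"))
  if (!target %in% rownames(S$values)) {
    stop("unknown target region '", target, "'", call. = FALSE)
  }
  if (!"total_body" %in% colnames(S$values)) {
    stop("S-matrix has no 'total_body' source column", call. = FALSE)
  }
  explicit_sources <- setdiff(explicit_sources, "total_body")
  missing <- setdiff(explicit_sources, colnames(S$values))
  if (length(missing)) {
    stop("source(s) absent from S-matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m_tb <- S$masses_kg[["total_body"]]
  m_k <- if (length(explicit_sources))
    S$masses_kg[explicit_sources] else numeric()
  m_rob <- m_tb - sum(m_k)
  if (m_rob <= 0) {
    stop("remainder mass is non-positive; explicit sources exceed the ",
         "total-body mass", call. = FALSE)
  }
  s_tb <- S$values[target, "total_body"]
  s_k <- if (length(explicit_sources))
    S$values[target, explicit_sources] else numeric()
  val <- (s_tb * m_tb - sum(s_k * m_k)) / m_rob
  if (val < 0) {
    warning("remainder S-value for target '", target,
            "' negative; floored at 0", call. = FALSE)
    val <- 0
  }
  val
}

#' Absorbed-dose coefficients from a source-organ TIAC set
#'
#' MIRD schema: for each target region,
#' \eqn{D(target) = \sum_{source} TIAC(source) \times S(target \leftarrow source)}
#' in mGy/MBq. The `remainder` source is mapped through
#' [remainder_s_value()] with all other used sources as the explicit set;
#' `whole_body`, `spine` (already represented by `bone`) and the per-litre
#' `blood` curve (represented by `red_marrow`) are excluded from the source
#' sum. Any other source region without an S-matrix column is an error.
#'
#' @param organ_set A [build_source_organ_set()] result, or a named list of
#'   [tiac_result()] objects.
#' @param S An [s_matrix()].
#' @param source_map Optional named character vector mapping TIAC region
#'   names to S-matrix column names (e.g. `c(heart = "heart_wall")`).
#' @return An object of class `dose_report`: list with `subject_id`,
#'   `coefficients_mgy_per_mbq` (named per-target vector), `phantom`,
#'   `sources_used`.
#' @export
dose_coefficients <- function(organ_set, S, source_map = NULL) {
  stopifnot(inherits(S, "s_matrix"))
  if (inherits(organ_set, "source_organ_set")) {
    subject_id <- organ_set$subject_id
    tiacs <- organ_set$tiacs
  } else {
    subject_id <- "unknown"
    tiacs <- organ_set
  }
  skip <- c("whole_body", "spine", "blood", "kidney_left", "kidney_right")
  use <- setdiff(names(tiacs), skip)
  explicit <- setdiff(use, "remainder")
  cols <- vapply(explicit, function(nm) {
    if (!is.null(source_map) && nm %in% names(source_map)) source_map[[nm]]
    else nm
  }, character(1))
  absent <- cols[!cols %in% colnames(S$values)]
  if (length(absent)) {
    stop("no S-matrix column for source region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  targets <- rownames(S$values)
  tiac_vals <- vapply(tiacs[explicit], function(x) x$value_h, numeric(1))
  doses <- vapply(targets, function(tg) {
    d <- sum(tiac_vals * S$values[tg, cols])
    if ("remainder" %in% use) {
      d <- d + tiacs$remainder$value_h * remainder_s_value(S, tg, cols)
    }
    d
  }, numeric(1))
  structure(list(subject_id = subject_id,
                 coefficients_mgy_per_mbq = doses,
                 phantom = S$phantom,
                 sources_used = stats::setNames(as.character(cols), explicit)),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> subject %s (phantom %s)\n", x$subject_id,
              x$phantom))
  d <- x$coefficients_mgy_per_mbq
  for (nm in names(d)) cat(sprintf("  %-20s %10.4g mGy/MBq\n", nm, d[nm]))
  invisible(x)
}

#' Scale dose coefficients to an administered activity
#'
#' \eqn{D[Gy] = c[mGy/MBq] \times A[MBq] / 1000}.
#'
#' @param report A `dose_report`, or a named numeric vector of coefficients
#'   in mGy/MBq.
#' @param activity_mbq Administered activity in MBq (> 0).
#' @return Named numeric vector of absorbed doses in Gy.
#' @export
#' @examples
#' scale_to_administered(c(kidneys = 2.73), 5000)  # 13.65 Gy
scale_to_administered <- function(report, activity_mbq) {
  if (!is.numeric(activity_mbq) || length(activity_mbq) != 1L ||
      activity_mbq <= 0) {
    stop("'activity_mbq' must be a single positive number", call. = FALSE)
  }
  coefs <- if (inherits(report, "dose_report"))
    report$coefficients_mgy_per_mbq else report
  stopifnot(is.numeric(coefs))
  coefs * activity_mbq / 1000
}

#' Format human dose predictions at reporting precision
#'
#' Reporting policy for administered-activity dose predictions: three
#' significant figures at or above 10 Gy, two below, rounding halves up.
#'
#' @param dose_gy Numeric vector of doses in Gy.
#' @return Numeric vector rounded per the policy.
#' @export
#' @examples
#' format_human_dose(c(13.65, 3.945))  # 13.7, 3.9
format_human_dose <- function(dose_gy) {
  out <- dose_gy
  hi <- is.finite(dose_gy) & abs(dose_gy) >= 10
  out[hi] <- signif_half_up(dose_gy[hi], 3)
  out[!hi] <- signif_half_up(dose_gy[!hi], 2)
  out
}

#' Cohort mean and sample standard deviation
#'
#' Arithmetic mean and n-1 standard deviation over subjects, with optional
#' exclusions recorded on the result.
#'
#' @param values Named numeric vector (one value per subject) or a matrix
#'   with subjects as columns (rows then summarised separately).
#' @param exclude Character vector of subject names to exclude.
#' @return For a vector: list with `mean`, `sd`, `n`, `included`,
#'   `excluded` (class `cohort_summary`). For a matrix: data frame with one
#'   row per matrix row and columns `mean`, `sd`, `n`.
#' @export
#' @examples
#' cohort_mean_sd(c(p1 = 9.34, p2 = 7.47, p3 = 8.80, p4 = 15.40, p5 = 6.07))
cohort_mean_sd <- function(values, exclude = character()) {
  if (is.matrix(values)) {
    keep <- setdiff(colnames(values), exclude)
    if (length(keep) < 2L) {
      stop("need at least 2 subjects after exclusions", call. = FALSE)
    }
    sub <- values[, keep, drop = FALSE]
    return(data.frame(mean = rowMeans(sub),
                      sd = apply(sub, 1, stats::sd),
                      n = length(keep), row.names = rownames(values)))
  }
  stopifnot(is.numeric(values))
  if (is.null(names(values))) {
    names(values) <- paste0("subject", seq_along(values))
  }
  keep <- setdiff(names(values), exclude)
  if (length(keep) < 2L) {
    stop("need at least 2 subjects after exclusions for a sample SD",
         call. = FALSE)
  }
  v <- values[keep]
  structure(list(mean = mean(v), sd = stats::sd(v), n = length(v),
                 included = keep,
                 excluded = intersect(names(values), exclude)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort> %.4g +/- %.4g (n = %d%s)\n", x$mean, x$sd, x$n,
              if (length(x$excluded))
                paste0(", excluded: ", paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Check absorbed doses against organ toxicity limits
#'
#' Flags organs whose cumulative dose reaches or exceeds the limit
#' (boundary inclusive) and reports the remaining headroom. Organs without
#' a limit are reported as unchecked.
#'
#' @param dose_gy Named numeric vector of cumulative absorbed doses in Gy.
#' @param limits_gy Named numeric vector of organ dose limits in Gy.
#'   Default `c(kidneys = 23)`, the critical kidney dose.
#' @return Data frame with columns `organ`, `dose_gy`, `limit_gy`,
#'   `status` (`"pass"`, `"fail"`, `"unchecked"`) and `margin_gy`.
#' @export
#' @examples
#' toxicity_check(c(kidneys = 13.7))
toxicity_check <- function(dose_gy, limits_gy = c(kidneys = 23)) {
  stopifnot(is.numeric(dose_gy), !is.null(names(dose_gy)))
  if (!length(limits_gy)) stop("'limits_gy' must be non-empty", call. = FALSE)
  if (any(dose_gy < 0)) stop("doses must be non-negative", call. = FALSE)
  lim <- limits_gy[names(dose_gy)]
  status <- ifelse(is.na(lim), "unchecked",
                   ifelse(dose_gy >= lim, "fail", "pass"))
  data.frame(organ = names(dose_gy), dose_gy = as.numeric(dose_gy),
             limit_gy = as.numeric(lim),
             status = status,
             margin_gy = as.numeric(lim - dose_gy),
             row.names = NULL, stringsAsFactors = FALSE)
}
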