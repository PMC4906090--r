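#' Bundled reference cohort TIACs
#'
#' Per-subject time-integrated activity coefficients (hours) for the
#' five-pig Lu-177 somatostatin-antagonist reference cohort, used for
#' regression tests of the organ-accounting arithmetic and cohort
#' statistics.
#'
#' @return Numeric matrix, rows = regions, columns = subjects
#'   (`pig1`..`pig5`).
#' @export
reference_tiacs <- function() {
  df <- utils::read.csv(
    system.file("extdata", "pig_tiacs.csv", package = "tiacdose"),
    comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$organ
  m
}

#' Bundled reference cohort dose coefficients
#'
#' Per-subject absorbed-dose coefficients (mGy/MBq, 70-kg adult male
#' phantom) for the reference cohort.
#'
#' @return Numeric matrix, rows = target regions, columns = subjects.
#' @export
reference_dose_coefficients <- function() {
  df <- utils::read.csv(
    system.file("extdata", "pig_dose_coefficients.csv", package = "tiacdose"),
    comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$target
  m
}
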