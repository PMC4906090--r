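test_that("first-scan whole-body normalisation scales and is idempotent", {
  tacs <- list(
    whole_body = organ_tac("s", "whole_body", c(1, 48), c(0.9, 0.5)),
    liver = organ_tac("s", "liver", c(1, 48), c(0.045, 0.02)))
  out <- normalize_to_first_whole_body(tacs)
  expect_equal(out$whole_body$value[1], 1.0)
  expect_equal(out$liver$value[1], 0.05)
  expect_equal(normalize_to_first_whole_body(out), out)
  # already normalised input is the identity
  expect_equal(normalize_to_first_whole_body(out)$liver$value,
               out$liver$value)
  expect_error(normalize_to_first_whole_body(list(liver = tacs$liver)),
               "whole_body")
  bad <- list(whole_body = organ_tac("s", "whole_body", c(1, 2), c(0, 0.5)))
  expect_error(normalize_to_first_whole_body(bad), "positive")
})

test_that("kidney summation reproduces the reference per-subject values", {
  # pig 2 and pig 3 of the reference cohort
  expect_equal(sum_kidneys(tiac_result("kidney_left", 4.18),
                           tiac_result("kidney_right", 3.29))$value_h, 7.47)
  expect_equal(sum_kidneys(tiac_result("kidney_left", 4.11),
                           tiac_result("kidney_right", 4.69))$value_h, 8.80)
  z <- sum_kidneys(tiac_result("kidney_left", 0), tiac_result("kidney_right", 0))
  expect_equal(z$value_h, 0)
  s <- sum_kidneys(tiac_result("kidney_left", 4, 0.3),
                   tiac_result("kidney_right", 3, 0.4))
  expect_equal(s$se_h, 0.5)
})

test_that("bone derivation from spine is the 19% skeleton-mass scaling", {
  expect_equal(bone_from_spine(tiac_result("spine", 0.57))$value_h, 3.00,
               tolerance = 1e-12)
  expect_equal(bone_from_spine(tiac_result("spine", 1.42))$value_h, 7.47,
               tolerance = 0.005)
  expect_equal(bone_from_spine(tiac_result("spine", 0))$value_h, 0)
  expect_error(bone_from_spine(tiac_result("spine", 1), 1.2), "\\(0, 1\\]")
  # linear: scaling the spine scales the bone
  b1 <- bone_from_spine(tiac_result("spine", 0.8, 0.08))
  b3 <- bone_from_spine(tiac_result("spine", 3 * 0.8, 3 * 0.08))
  expect_equal(b3$value_h, 3 * b1$value_h, tolerance = 1e-12)
  expect_equal(b3$se_h, 3 * b1$se_h, tolerance = 1e-12)
})

test_that("remainder closes the whole-body accounting", {
  mk <- function(v) lapply(v, function(x) tiac_result("liver", x))
  pig2 <- list(liver = tiac_result("liver", 3.48),
               kidneys = tiac_result("kidneys", 7.47),
               heart = tiac_result("heart", 3.89),
               bladder_contents = tiac_result("bladder_contents", 0.43),
               bone = tiac_result("bone", 3.00),
               red_marrow = tiac_result("red_marrow", 0.01))
  r2 <- remainder_tiac(pig2, tiac_result("whole_body", 72.23))
  expect_equal(r2$value_h, 53.95, tolerance = 1e-10)
  pig3 <- list(liver = tiac_result("liver", 2.66),
               kidneys = tiac_result("kidneys", 8.80),
               heart = tiac_result("heart", 0.41),
               bladder_contents = tiac_result("bladder_contents", 0.02),
               bone = tiac_result("bone", 7.47),
               red_marrow = tiac_result("red_marrow", 0.13))
  expect_equal(remainder_tiac(pig3, tiac_result("whole_body", 60.95))$value_h,
               41.46, tolerance = 1e-10)
  # all sources zero -> remainder is the whole body
  zeros <- lapply(pig2, function(x) tiac_result(x$organ, 0))
  expect_equal(remainder_tiac(zeros, tiac_result("whole_body", 5))$value_h, 5)
  expect_error(remainder_tiac(pig2[-2], tiac_result("whole_body", 72.23)),
               "kidneys")
  expect_warning(
    neg <- remainder_tiac(pig2, tiac_result("whole_body", 10)), "clipped")
  expect_equal(neg$value_h, 0)
})

test_that("remainder reconstruction matches all reference subjects", {
  ref <- reference_tiacs()
  for (pig in colnames(ref)) {
    sources <- list(
      liver = tiac_result("liver", ref["liver", pig]),
      kidneys = tiac_result("kidneys", ref["kidneys", pig]),
      heart = tiac_result("heart", ref["heart", pig]),
      bladder_contents = tiac_result("bladder_contents",
                                     ref["bladder_contents", pig]),
      bone = tiac_result("bone", ref["bone", pig]),
      red_marrow = tiac_result("red_marrow", ref["red_marrow", pig]))
    r <- remainder_tiac(sources, tiac_result("whole_body",
                                             ref["whole_body", pig]))
    expect_lt(abs(r$value_h - ref["remainder", pig]), 0.045)
  }
})

test_that("blood-based marrow surrogate applies the concentration ratio", {
  p <- marrow_params()
  expect_equal(p$rmecff / (1 - p$hematocrit), 0.3220, tolerance = 1e-3)
  expect_equal(red_marrow_tiac_shen(0, p)$value_h, 0)
  expect_error(marrow_params(hematocrit = 1), "hematocrit")
  # default synthetic blood model, 0.9-kg marrow: plausible reference range
  A <- 0.20 * c(0.801, 0.199)   # fraction IA per litre
  lam <- log(2) / (c(2, 36) / 60)
  blood_tiac <- sum(A / (lam + lam_phys))
  rm_ <- red_marrow_tiac_shen(blood_tiac, p)
  expect_gt(rm_$value_h, 0.01)
  expect_lt(rm_$value_h, 0.25)
  # wrong unit rejected
  expect_error(red_marrow_tiac_shen(tiac_result("blood", 1), p), "per-litre")
})

test_that("source-organ assembly conserves the whole-body TIAC", {
  tiacs <- list(
    whole_body = tiac_result("whole_body", 74),
    liver = tiac_result("liver", 4.2),
    kidney_left = tiac_result("kidney_left", 4.7),
    kidney_right = tiac_result("kidney_right", 4.7),
    heart = tiac_result("heart", 1.2),
    bladder_contents = tiac_result("bladder_contents", 0.5,
                                   method = "trapezoid_tail"),
    spine = tiac_result("spine", 2.1),
    blood = tiac_result("blood", 0.042, unit = "fraction_IA_per_L"))
  set <- build_source_organ_set("s1", tiacs)
  got <- set$tiacs
  expect_equal(got$kidneys$value_h, 9.4)
  expect_equal(got$bone$value_h, 2.1 / 0.19)
  total <- got$liver$value_h + got$kidneys$value_h + got$heart$value_h +
    got$bladder_contents$value_h + got$bone$value_h +
    got$red_marrow$value_h + got$remainder$value_h
  expect_equal(total, got$whole_body$value_h, tolerance = 1e-12)
  # spine retained alongside derived bone
  expect_equal(got$spine$value_h, 2.1)
  expect_error(build_source_organ_set("s1", tiacs[-3]), "kidney_left")
})
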