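test_that("S-matrix construction validates masses and layout", {
  vals <- rbind(a = c(a = 0.5, total_body = 0.02))
  expect_error(s_matrix("x", vals, c(a = 1)), "total_body")
  expect_error(s_matrix("x", vals, c(a = -1, total_body = 10)), "positive")
  S <- toy_s_matrix()
  expect_s3_class(S, "s_matrix")
  expect_true(all(S$values >= 0))
  expect_true("total_body" %in% colnames(S$values))
  expect_setequal(setdiff(colnames(S$values), "total_body"),
                  c("liver", "kidneys", "heart", "bladder_contents",
                    "bone", "red_marrow"))
})

test_that("remainder S-value follows the rest-of-body mass adjustment", {
  S <- tiny_s()
  # no explicit sources: total-body value verbatim
  expect_equal(remainder_s_value(S, "a"), 0.06)
  # algebraic identity: one source with half the total mass and the same
  # S-value as total body leaves the remainder value unchanged
  vals <- rbind(t1 = c(src = 0.07, total_body = 0.07))
  Sh <- s_matrix("h", vals, c(src = 5, total_body = 10))
  expect_equal(remainder_s_value(Sh, "t1", "src"), 0.07, tolerance = 1e-12)
  # hand-computed three-region case:
  # (S_tb*m_tb - S_a*m_a - S_b*m_b) / (m_tb - m_a - m_b)
  expect_equal(remainder_s_value(S, "a", c("a", "b")),
               (0.06 * 10 - 0.5 * 1 - 0.01 * 2) / 7, tolerance = 1e-12)
  expect_equal(remainder_s_value(S, "b", c("a", "b")),
               (0.09 * 10 - 0.02 * 1 - 0.4 * 2) / 7, tolerance = 1e-12)
  expect_error(remainder_s_value(S, "zz"), "unknown target")
  big <- s_matrix("b", rbind(t1 = c(src = 0.1, total_body = 0.1)),
                  c(src = 10, total_body = 10))
  expect_error(remainder_s_value(big, "t1", "src"), "non-positive")
})

test_that("dose engine implements the MIRD schema", {
  S <- tiny_s()
  tiacs <- list(a = tiac_result("liver", 3), b = tiac_result("kidneys", 2))
  # hand-computed: D = sum_source TIAC * S
  d <- dose_coefficients(tiacs, S)$coefficients_mgy_per_mbq
  expect_equal(unname(d["a"]), 3 * 0.5 + 2 * 0.01, tolerance = 1e-12)
  expect_equal(unname(d["b"]), 3 * 0.02 + 2 * 0.4, tolerance = 1e-12)
  # all-zero TIACs give all-zero doses
  z <- dose_coefficients(list(a = tiac_result("liver", 0),
                              b = tiac_result("kidneys", 0)), S)
  expect_true(all(z$coefficients_mgy_per_mbq == 0))
  # unmapped source region is a named error
  expect_error(dose_coefficients(list(nope = tiac_result("liver", 1)), S),
               "nope")
})

test_that("dose engine is linear and reduces to elementwise on diagonal S", {
  regions <- c("liver", "kidneys")
  vals <- diag(c(1, 1))
  dimnames(vals) <- list(regions, regions)
  vals <- cbind(vals, total_body = c(0, 0))
  Sd <- s_matrix("diag", vals,
                 c(liver = 1.8, kidneys = 0.3, total_body = 70))
  tiacs <- list(liver = tiac_result("liver", 4.24),
                kidneys = tiac_result("kidneys", 9.42))
  d <- dose_coefficients(tiacs, Sd)$coefficients_mgy_per_mbq
  expect_equal(unname(d[regions]), c(4.24, 9.42), tolerance = 1e-12)
  # doubling all TIACs doubles all doses exactly
  tiacs2 <- lapply(tiacs, function(x) tiac_result(x$organ, 2 * x$value_h))
  d2 <- dose_coefficients(tiacs2, Sd)$coefficients_mgy_per_mbq
  expect_equal(unname(d2), 2 * unname(d), tolerance = 1e-12)
})

test_that("administered-activity scaling and reporting precision", {
  expect_equal(unname(scale_to_administered(c(kidneys = 2.73), 5000)), 13.65)
  expect_equal(unname(format_human_dose(
    scale_to_administered(c(kidneys = 2.73), 5000))), 13.7)
  expect_equal(unname(format_human_dose(
    scale_to_administered(c(osteogenic_cells = 0.789), 5000))), 3.9)
  expect_equal(unname(scale_to_administered(c(a = 4), 1)), 0.004)
  expect_error(scale_to_administered(c(a = 1), 0), "positive")
})

test_that("cohort statistics use the sample SD and record exclusions", {
  k <- c(pig1 = 9.34, pig2 = 7.47, pig3 = 8.80, pig4 = 15.40, pig5 = 6.07)
  cs <- cohort_mean_sd(k)
  expect_equal(cs$mean, 9.42, tolerance = 5e-4)
  expect_equal(cs$sd, 3.58, tolerance = 2e-3)
  cs4 <- cohort_mean_sd(k, exclude = "pig4")
  expect_equal(cs4$mean, 7.92, tolerance = 5e-4)
  expect_equal(cs4$sd, 1.46, tolerance = 2e-3)
  expect_equal(cs4$n, 4L)
  expect_equal(cs4$excluded, "pig4")
  expect_equal(cohort_mean_sd(c(a = 2, b = 2, c = 2))$sd, 0)
  expect_error(cohort_mean_sd(c(a = 1)), "at least 2")
  expect_error(cohort_mean_sd(k, exclude = names(k)[-1]), "at least 2")
})

test_that("reference dose-coefficient cohort means match printed summaries", {
  ref <- reference_dose_coefficients()
  printed <- c(kidneys = 2.73, liver = 2.03e-1, osteogenic_cells = 7.89e-1,
               urinary_bladder_wall = 3.55e-1, total_body = 9.09e-2)
  for (tg in names(printed)) {
    expect_lt(abs(mean(ref[tg, ]) - printed[tg]), 0.01)
  }
  expect_equal(mean(ref["kidneys", ]), 2.73, tolerance = 1e-12)
  expect_equal(sd(ref["kidneys", ]), 1.03, tolerance = 5e-3)
})

test_that("toxicity check flags limits inclusively and reports headroom", {
  tox <- toxicity_check(c(kidneys = 13.7))
  expect_equal(tox$status, "pass")
  expect_equal(tox$margin_gy, 9.3)
  expect_equal(toxicity_check(c(kidneys = 23.0))$status, "fail")
  t2 <- toxicity_check(c(kidneys = 10, liver = 1))
  expect_equal(t2$status[t2$organ == "liver"], "unchecked")
  expect_error(toxicity_check(c(kidneys = -1)), "non-negative")
})
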