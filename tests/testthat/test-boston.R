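test_that("anion gap arithmetic matches hand-worked values and errors on missing analytes", {
  expect_equal(anion_gap(140, 104, 24), 12.0)
  expect_equal(anion_gap(140, 140, 0), 0.0)
  expect_equal(anion_gap(137, 110, 21.1), 5.9)
  expect_error(anion_gap(140, NA, 24), "cl")
})

test_that("albumin-corrected anion gap restores the gap hidden by hypoalbuminemia", {
  expect_equal(corrected_anion_gap(8.9, 1.3), 16.7)
  expect_equal(corrected_anion_gap(16.9, 2.0), 22.9)
  expect_equal(corrected_anion_gap(10.0, 4.4), 10.0)
  expect_error(corrected_anion_gap(10, -1), "positive")
  # identity at 4.4 g/dL and strict monotone decrease, slope -2.5 per g/dL
  ag <- seq(2, 20, by = 0.7)
  expect_equal(corrected_anion_gap(ag, 4.4, digits = NULL), ag)
  alb <- seq(0.5, 5.5, by = 0.25)
  cag <- corrected_anion_gap(5, alb, digits = NULL)
  expect_true(all(diff(cag) < 0))
  expect_equal(diff(cag) / diff(alb), rep(-2.5, length(alb) - 1))
})

test_that("pH 7.40 is classified on the alkalemia side", {
  expect_equal(ph_status(c(7.29, 7.40, 7.55)),
               c("acidemia", "alkalemia", "alkalemia"))
})

test_that("expected bicarbonate follows the acute and chronic compensation lines", {
  expect_equal(expected_hco3(40, "acute"), 25.0)
  expect_equal(expected_hco3(34.0, "acute"), 23.8)
  expect_equal(expected_hco3(25.7, "chronic"), 17.85)
  expect_error(expected_hco3(40, "subacute"), "phase")
  expect_error(expected_hco3(-3, "acute"), "positive")
})

test_that("Boston classification reproduces the worked single-patient verdicts", {
  r <- classify_boston(7.43, 34.0, 22.1)
  expect_equal(r$ph_status, "alkalemia")
  expect_equal(r$respiratory_verdict, "respiratory_alkalosis")
  expect_equal(r$metabolic_verdict, "none")  # 22.1 within 2 of 0.2*34+17 = 23.8

  r <- classify_boston(7.43, 43.2, 28.2)
  expect_equal(r$respiratory_verdict, "none")
  expect_equal(r$metabolic_verdict, "metabolic_alkalosis")

  r <- classify_boston(7.29, 31.5, 14.9)
  expect_equal(r$ph_status, "acidemia")
  expect_equal(r$metabolic_verdict, "metabolic_acidosis")

  # both compensation lines always populated
  expect_equal(r$expected_hco3_acute, 0.2 * 31.5 + 17)
  expect_equal(r$expected_hco3_chronic, 0.5 * 31.5 + 5)
})

test_that("every complete gas gets one pH status and a non-trivial verdict set", {
  r <- classify_boston(ref_cohort$ph, ref_cohort$paco2, ref_cohort$hco3)
  expect_true(all(r$ph_status %in% c("acidemia", "alkalemia")))
  # fixture has no perfectly normal gas: everyone gets at least one verdict
  expect_true(all(r$respiratory_verdict != "none" | r$metabolic_verdict != "none"))
})

test_that("reference cohort yields 4 acidemic and 18 respiratory-alkalosis patients", {
  r <- classify_boston(ref_cohort$ph, ref_cohort$paco2, ref_cohort$hco3)
  expect_equal(sum(r$ph_status == "acidemia"), 4)
  expect_equal(sum(r$respiratory_verdict == "respiratory_alkalosis"), 18)
})
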