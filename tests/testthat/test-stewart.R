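test_that("A_TOT dialects match hand-worked values and rise with albumin, phosphate and pH", {
  expect_equal(a_tot(0, 0, 7.40), 0.0)
  expect_equal(a_tot(1.3, 3.8, 7.43), 3.5044 + 2.2417, tolerance = 1e-4)
  expect_equal(a_tot(1.3, 3.8, 7.43, "rastegar"), 3.6776 + 2.0502,
               tolerance = 1e-4)
  expect_error(a_tot(1, 1, 7.4, "kishen"), "dialect")
  for (d in c("agrafiotis", "rastegar")) {
    expect_true(all(diff(a_tot(seq(0.5, 5, 0.5), 3.8, 7.4, d)) > 0))
    expect_true(all(diff(a_tot(2, seq(1, 8, 0.5), 7.4, d)) > 0))
    expect_true(all(diff(a_tot(2, 3.8, seq(7.2, 7.6, 0.05), d)) > 0))
  }
})

test_that("calculated bicarbonate dialects agree within 3% over the physiological range", {
  expect_equal(hco3_calc(7.40, 0), 0.0)
  expect_equal(hco3_calc(7.40, 40), 24.02, tolerance = 1e-3)
  expect_equal(hco3_calc(7.40, 40, "kellum"), 24.72, tolerance = 1e-3)
  expect_error(hco3_calc(7.4, 40, "copenhagen"), "dialect")
  grid <- expand.grid(ph = seq(7.2, 7.6, 0.05), paco2 = seq(20, 50, 5))
  a <- hco3_calc(grid$ph, grid$paco2)
  k <- hco3_calc(grid$ph, grid$paco2, "kellum")
  expect_true(all(abs(k / a - 1) < 0.03))
})

test_that("strong ion difference and gap arithmetic holds exactly by construction", {
  expect_equal(sida(140, 4, 104), 40.0)
  expect_equal(sida(142, 4.7, 105), 41.7)
  expect_equal(sida(0, 0, 0), 0.0)
  expect_equal(side(24.0, 0), 24.0)
  expect_equal(sig(34.8, 28.1), 6.7)
  expect_equal(sig(34.4, 31.9), 2.5)
  expect_equal(sig(17.3, 17.3), 0.0)
  # construction identity at arbitrary inputs
  set.seed(42)
  for (i in 1:25) {
    s <- runif(1, 25, 45); h <- runif(1, 10, 30); a <- runif(1, 2, 15)
    expect_equal(sig(s, side(h, a)), s - h - a)
  }
})

test_that("deltas measure departure from the control means", {
  expect_equal(delta_a_tot(6.16), 7.93)
  expect_equal(delta_a_tot(3.89), 10.20)
  expect_equal(delta_a_tot(14.09), 0.0)
  expect_equal(delta_sida(34.8), 7.9)
  expect_equal(delta_sida(31.7), 11.0)
  expect_equal(delta_sida(42.7), 0.0)
  expect_equal(delta_a_tot_from_alb(4.4), 0.154, tolerance = 1e-9)
  expect_equal(delta_a_tot_from_alb(1.5), 7.81)
  expect_equal(delta_a_tot_from_alb(11.77 / 2.64), 0.0)
})

test_that("normal-AG verdict takes the larger delta and is antisymmetric", {
  expect_equal(classify_normal_ag(6.96, 6.2), "Alkalosis")
  expect_equal(classify_normal_ag(6.40, 8.6), "Acidosis")
  expect_equal(classify_normal_ag(7.93, 7.9), "Neutral")
  # antisymmetry under swapping the two deltas
  set.seed(7)
  a <- runif(40, 0, 12); b <- runif(40, 0, 12)
  v1 <- classify_normal_ag(a, b); v2 <- classify_normal_ag(b, a)
  flip <- c(Alkalosis = "Acidosis", Acidosis = "Alkalosis", Neutral = "Neutral")
  expect_equal(v2, unname(flip[v1]))
})

test_that("increased-AG flag is strict at the threshold", {
  expect_equal(classify_high_ag(c(7.7, 6.7, 7.0)), c(TRUE, FALSE, FALSE))
  expect_equal(sig_minus_lactate(6.7, 1.3), 5.4)
  expect_equal(sig_minus_lactate(13.6, 1.9), 11.7)
  expect_equal(sig_minus_lactate(2.2, 2.2), 0.0)
})

test_that("published shortcut formulas evaluate as reported", {
  expect_equal(round_half_up(estimate_a_tot_from_alb(4.4), 1), 14.0)
  expect_equal(round_half_up(estimate_a_tot_from_alb(1.5), 2), 6.30)
  expect_equal(estimate_a_tot_from_alb(0), 2.3323)
  expect_equal(round_half_up(estimate_sig_from_cag(12), 2), 3.16)
  expect_equal(round_half_up(estimate_sig_from_cag(16.7), 2), 7.61)
  # raw and delta forms differ only by intercept rounding
  cag <- seq(5, 30, by = 0.1)
  expect_lt(max(abs(estimate_sig_from_cag(cag, "raw") -
                      estimate_sig_from_cag(cag, "delta"))), 0.001)
  expect_error(estimate_sig_from_cag(12, "log"), "form")
})

test_that("Stewart pipeline reproduces the reference cohort's reported panel", {
  p <- stewart_profile(ref_cohort$ph, ref_cohort$paco2,
                       ref_cohort$a_tot_printed, ref_cohort$sida_printed,
                       ref_cohort$lactate)
  # two-decimal pH propagates up to ln(10)*0.005 = 1.16% of HCO3 (~0.35)
  expect_lt(max(abs(p$side - ref_cohort$side_printed)), 0.35)
  expect_lt(max(abs(p$sig - ref_cohort$sig_printed)), 0.35)
  expect_equal(p$delta_a_tot, ref_cohort$delta_a_tot_printed, tolerance = 0.0101)
  expect_equal(p$delta_sida, ref_cohort$delta_sida_printed, tolerance = 0.0101)
  expect_equal(p$normal_ag_verdict, ref_cohort$verdict_printed)
  expect_equal(p$high_ag_flag, ref_cohort$agplus_printed == 1)
  expect_equal(sum(p$high_ag_flag), 12)
})

test_that("lactate partition labels split flagged gaps by lactate contribution", {
  expect_equal(lactate_partition(11.4, 0.9, TRUE), "non_lactate_dominant")
  expect_equal(lactate_partition(12.0, 4.2, TRUE), "mixed")
  expect_equal(lactate_partition(5.5, 1.8, FALSE), "lactate_dominant")
  expect_equal(lactate_partition(3.0, 0.8, FALSE), "none")
})
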