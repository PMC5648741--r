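test_that("cohort generation is deterministic under a fixed spec and seed", {
  spec <- cohort_spec("nephrotic", n = 20, seed = 123)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  other <- generate_cohort(cohort_spec("nephrotic", n = 20, seed = 124))
  expect_false(identical(generate_cohort(spec)$na, other$na))
})

test_that("n = 0 gives an empty but fully typed table", {
  empty <- generate_cohort(cohort_spec("nephrotic", n = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("patient_id", "group", "na", "k", "cl", "albumin",
                    "phosphate", "ph", "paco2", "hco3", "lactate")
                  %in% names(empty)))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec("nephrotic", n = -1), "n must be")
  expect_error(cohort_spec("nephrotic", ranges = list(albumin = c(3, 1))),
               "lower > upper")
  expect_error(cohort_spec("nephrotic", ranges = list(unobtainium = c(0, 1))),
               "unknown analyte")
  expect_error(generate_cohort(list()), "cohort_spec")
})

test_that("default nephrotic draws land in the cohort's reported territory", {
  syn <- generate_cohort(cohort_spec("nephrotic", n = 500, seed = 20170313))
  alb_med <- median(syn$albumin)
  expect_gte(alb_med, 1.4); expect_lte(alb_med, 2.1)
  expect_lt(median(sida(syn$na, syn$k, syn$cl)), 42.7)
  # measured HCO3 tracks the Henderson-Hasselbalch value to analyzer noise
  expect_lt(max(abs(syn$hco3 - hco3_calc(syn$ph, syn$paco2))), 5 * 0.3)
})

test_that("injection preserves electroneutrality: SIG rises one-for-one with added anion load", {
  base <- generate_cohort(cohort_spec("control", n = 25, seed = 99))
  sig_of <- function(df) {
    sida(df$na, df$k, df$cl) - hco3_calc(df$ph, df$paco2) -
      a_tot(df$albumin, df$phosphate, df$ph)
  }
  for (m in c(2, 6, 11)) {
    pert <- inject_disorder(base, "high_ag_acidosis", m)
    expect_lt(max(abs((sig_of(pert) - sig_of(base)) - m)), 1e-9)
    # re-derived gas stays internally consistent
    expect_lt(max(abs(pert$hco3 - hco3_calc(pert$ph, pert$paco2))), 1e-9)
  }
  expect_identical(inject_disorder(base, "resp_alkalosis", 0), base)
  expect_error(inject_disorder(base, "panic", 3), "disorder")
})

test_that("injected disorders are recovered by the classifiers at default magnitudes", {
  n <- 200
  base <- generate_cohort(cohort_spec("control", n = n, seed = 314159))
  rate <- function(x) mean(x)

  resp <- inject_disorder(base, "resp_alkalosis", 8)
  b <- classify_boston(resp$ph, resp$paco2, resp$hco3)
  expect_gte(rate(b$respiratory_verdict == "respiratory_alkalosis"), 0.95)

  high <- inject_disorder(base, "high_ag_acidosis", 6)
  rep <- acid_base(high)
  expect_gte(rate(rep$high_ag_flag), 0.95)

  nag <- inject_disorder(base, "normal_ag_acidosis", 8)
  rep <- acid_base(nag)
  expect_gte(rate(rep$normal_ag_verdict == "Acidosis"), 0.95)

  malk <- inject_disorder(base, "metabolic_alkalosis", 2)
  rep <- acid_base(malk)
  expect_gte(rate(rep$normal_ag_verdict == "Alkalosis"), 0.95)
})
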