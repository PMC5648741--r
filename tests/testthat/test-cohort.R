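test_that("nearest-rank quartiles reproduce the reported gap summary", {
  expect_equal(median_iqr(ref_cohort$ag_printed),
               c(median = 8.6, q25 = 7.0, q75 = 10.8))
  expect_equal(median_iqr(5), c(median = 5, q25 = 5, q75 = 5))
  expect_equal(median_iqr(1:9), c(median = 5, q25 = 3, q75 = 7))
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("median_iqr is permutation-invariant and affine-equivariant", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1))
    expect_equal(median_iqr(sample(x)), median_iqr(x))
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(median_iqr(a * x + b), a * median_iqr(x) + b)
  }
})

test_that("count_where applies explicit strictness and reports the denominator", {
  expect_equal(count_where(ref_cohort, "ph", "<", 7.40)$count, 4)
  expect_equal(count_where(ref_cohort, "lactate", ">", 1.0)$count, 20)
  expect_equal(count_where(ref_cohort, "paco2", "<", 40)$count, 21)
  empty <- ref_cohort[0, ]
  expect_equal(count_where(empty, "ph", "<", 7.40)$count, 0)
  expect_error(count_where(ref_cohort, "no_such", ">", 1), "unknown field")
  with_na <- data.frame(x = c(1, NA, 3))
  expect_equal(count_where(with_na, "x", ">", 0)$denominator, 2)
})

test_that("ols_fit agrees with the closed-form normal equations", {
  f <- ols_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1); expect_equal(f$r2, 1)

  f <- ols_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, -1 / 6)

  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(29); y <- 1.7 * x + rnorm(29)
    f <- ols_fit(x, y); o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2, o$r2, tolerance = 1e-10)
    # r2 equals squared sample correlation for a simple regression
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-12)
  }
  expect_error(ols_fit(rep(1, 5), 1:5), "constant")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("albumin predicts reported A_TOT about as strongly as published", {
  f <- ols_fit(ref_cohort$albumin, ref_cohort$a_tot_printed)
  expect_gt(f$slope, 2.2); expect_lt(f$slope, 3.1)
  expect_gt(f$r2, 0.80)
})

test_that("poly_fit matches a QR design-matrix oracle and nests ols_fit", {
  x <- c(-2, -1, 0, 1, 2, 3); y <- 3 - 2 * x + 0.5 * x^2
  f <- poly_fit(x, y, 2)
  expect_equal(f$coefficients, c(3, -2, 0.5), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_equal(predict(f, x), y, tolerance = 1e-9)

  set.seed(9)
  x <- runif(29, 5, 130); y <- 12 - 0.1 * x + rnorm(29)
  for (d in c(1, 3, 6)) {
    expect_equal(poly_fit(x, y, d)$coefficients, poly_oracle(x, y, d),
                 tolerance = 1e-8)
  }
  f1 <- poly_fit(x, y, 1); f0 <- ols_fit(x, y)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-12)
  expect_error(poly_fit(1:3, 1:3, 3), "under-determined")
})

test_that("cohort_summary lays out median and IQR per analyte", {
  s <- cohort_summary(ref_cohort, c("ph", "ag_printed"))
  expect_equal(s$analyte, c("ph", "ag_printed"))
  expect_equal(s$median, c(7.43, 8.6))
  expect_equal(s$n, c(29L, 29L))
  expect_error(cohort_summary(ref_cohort, "nope"), "unknown field")
})

test_that("reproduction report recomputes the published cohort values", {
  rep <- reproduce_report(ref_cohort)
  expect_s3_class(rep, "reproduction_report")
  expect_true(all(rep$pass))
  # spot the headline rows
  expect_equal(rep$computed[rep$check == "patients with SIG > 7.0"], 12)
  expect_equal(rep$computed[rep$check == "median cag"], 15.8)
})
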