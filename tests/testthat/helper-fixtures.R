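# Shared fixtures: the packaged reference cohort, loaded once per run.
ref_cohort <- nephrotic_cohort()
ref_report <- acid_base(ref_cohort)

# Closed-form normal-equations OLS, independent of the lm()-backed fit path.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Explicit design-matrix polynomial LS via QR, independent of lm().
poly_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  qr.solve(X, y)
}
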