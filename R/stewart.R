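#' Total non-volatile weak acid concentration (A_TOT)
#'
#' A_TOT sums the buffer charge carried by albumin and inorganic phosphate
#' at the measured pH. Two published coefficient sets ("dialects") are
#' supported:
#' \describe{
#'   \item{agrafiotis (default)}{`Alb*10*(0.1204*pH - 0.625) +
#'     P*0.3229*(0.309*pH - 0.469)`}
#'   \item{rastegar}{`Alb*10*(0.123*pH - 0.631) +
#'     P*0.3229*(0.309*pH - 0.625)`}
#' }
#' Over the physiological range the two differ by well under 0.1 mEq/L at
#' nephrotic albumin levels.
#'
#' @param albumin serum albumin, g/dL (>= 0).
#' @param phosphate serum inorganic phosphate, mg/dL (>= 0).
#' @param ph arterial pH.
#' @param dialect `"agrafiotis"` or `"rastegar"`.
#' @return A_TOT, mEq/L (unrounded).
#' @examples
#' a_tot(1.3, 3.8, 7.43)               # 5.75 (severe hypoalbuminemia)
#' a_tot(1.3, 3.8, 7.43, "rastegar")   # 5.73
#' @export
a_tot <- function(albumin, phosphate, ph,
                  dialect = c("agrafiotis", "rastegar")) {
  require_analytes(albumin = albumin, phosphate = phosphate, ph = ph)
  if (any(albumin < 0) || any(phosphate < 0)) {
    stop("albumin and phosphate must be non-negative", call. = FALSE)
  }
  dialect <- match_label(dialect[1], c("agrafiotis", "rastegar"), "A_TOT dialect")
  if (dialect == "agrafiotis") {
    albumin * 10 * (0.1204 * ph - 0.625) +
      phosphate * 0.3229 * (0.309 * ph - 0.469)
  } else {
    albumin * 10 * (0.123 * ph - 0.631) +
      phosphate * 0.3229 * (0.309 * ph - 0.625)
  }
}

#' Calculated bicarbonate from pH and PaCO2
#'
#' Henderson-Hasselbalch solved for HCO3. Dialects:
#' \describe{
#'   \item{agrafiotis (default)}{`0.0301 * PaCO2 * 10^(pH - 6.1)`}
#'   \item{kellum}{`2.46e-8 * PaCO2 * 10^pH`}
#' }
#' The two differ only through the rounding of the solubility/pK constants
#' (a constant ~2.9% ratio); the Agrafiotis form is used throughout the
#' Stewart pipeline so that SIDe decomposes exactly into calculated HCO3
#' plus A_TOT.
#'
#' @param ph arterial pH.
#' @param paco2 arterial CO2 tension, Torr (>= 0).
#' @param dialect `"agrafiotis"` or `"kellum"`.
#' @return calculated HCO3, mEq/L (unrounded).
#' @examples
#' hco3_calc(7.40, 40)            # 24.02
#' hco3_calc(7.40, 40, "kellum")  # 24.72
#' @export
hco3_calc <- function(ph, paco2, dialect = c("agrafiotis", "kellum")) {
  require_analytes(ph = ph, paco2 = paco2)
  if (any(paco2 < 0)) stop("paco2 must be non-negative", call. = FALSE)
  dialect <- match_label(dialect[1], c("agrafiotis", "kellum"), "HCO3 dialect")
  if (dialect == "agrafiotis") {
    0.0301 * paco2 * 10^(ph - 6.1)
  } else {
    2.46e-8 * paco2 * 10^ph
  }
}

#' Apparent strong ion difference (SIDa)
#'
#' SIDa = Na + K - Cl. Calcium, magnesium and lactate contribute negligibly
#' and are excluded.
#'
#' @param na,k,cl serum sodium, potassium, chloride, mEq/L.
#' @return SIDa, mEq/L.
#' @examples
#' sida(142, 4.7, 105)  # 41.7, a control-like value
#' @export
sida <- function(na, k, cl) {
  require_analytes(na = na, k = k, cl = cl)
  na + k - cl
}

#' Effective strong ion difference (SIDe)
#'
#' SIDe = calculated HCO3 + A_TOT: the buffer-base side of the
#' physicochemical balance.
#'
#' @param hco3_calc calculated bicarbonate, mEq/L (see [hco3_calc()]).
#' @param a_tot total non-volatile weak acids, mEq/L (see [a_tot()]).
#' @return SIDe, mEq/L.
#' @export
side <- function(hco3_calc, a_tot) {
  require_analytes(hco3_calc = hco3_calc, a_tot = a_tot)
  if (any(hco3_calc < 0) || any(a_tot < 0)) {
    stop("hco3_calc and a_tot must be non-negative", call. = FALSE)
  }
  hco3_calc + a_tot
}

#' Strong ion gap (SIG)
#'
#' SIG = SIDa - SIDe. Positive values beyond the reference range indicate
#' unmeasured non-volatile anions (lactate, uremic anions, ketoacids).
#'
#' @param sida apparent strong ion difference, mEq/L.
#' @param side effective strong ion difference, mEq/L.
#' @return SIG, mEq/L; may be negative.
#' @examples
#' sig(34.8, 28.1)  # 6.7
#' @export
sig <- function(sida, side) {
  require_analytes(sida = sida, side = side)
  sida - side
}

#' Departure of A_TOT from the control mean
#'
#' delta A_TOT = reference - A_TOT. A positive delta (hypoalbuminemia) is a
#' power toward metabolic alkalosis.
#'
#' @param a_tot measured A_TOT, mEq/L.
#' @param reference control mean, mEq/L (default 14.09).
#' @return delta A_TOT, mEq/L.
#' @export
delta_a_tot <- function(a_tot, reference = reference_ranges()$reference_a_tot) {
  require_analytes(a_tot = a_tot)
  reference - a_tot
}

#' Shortcut delta A_TOT from albumin alone
#'
#' The published bedside line delta A_TOT = 11.77 - 2.64 x albumin (g/dL),
#' equivalent to subtracting the albumin-only regression of A_TOT from the
#' control mean.
#'
#' @param albumin serum albumin, g/dL (>= 0).
#' @return estimated delta A_TOT, mEq/L.
#' @examples
#' delta_a_tot_from_alb(1.5)  # 7.81
#' @export
delta_a_tot_from_alb <- function(albumin) {
  require_analytes(albumin = albumin)
  if (any(albumin < 0)) stop("albumin must be non-negative", call. = FALSE)
  fit <- published_fits()$delta_a_tot_from_alb
  unname(fit["intercept"] + fit["slope"] * albumin)
}

#' Departure of SIDa from the control mean
#'
#' delta SIDa = reference - SIDa. A positive delta (relative hyperchloremia)
#' is a power toward metabolic acidosis.
#'
#' @param sida measured SIDa, mEq/L.
#' @param reference control mean, mEq/L (default 42.7).
#' @return delta SIDa, mEq/L.
#' @export
delta_sida <- function(sida, reference = reference_ranges()$reference_sida) {
  require_analytes(sida = sida)
  reference - sida
}

#' Normal-anion-gap metabolic verdict from the two deltas
#'
#' Compares the alkalinizing power of lost weak acid (delta A_TOT) against
#' the acidifying power of lost strong-ion difference (delta SIDa). The
#' larger delta wins; when they balance to within `neutral_band` the verdict
#' is `"Neutral"`.
#'
#' @param delta_a_tot,delta_sida the two departures, mEq/L.
#' @param neutral_band half-width of the tie region, mEq/L (default 0.1;
#'   calibrated so the packaged cohort's reported verdicts are reproduced,
#'   see the methods vignette).
#' @return character vector: `"Alkalosis"`, `"Acidosis"` or `"Neutral"`.
#' @examples
#' classify_normal_ag(7.93, 7.9)  # Neutral
#' classify_normal_ag(6.40, 8.6)  # Acidosis
#' @export
classify_normal_ag <- function(delta_a_tot, delta_sida,
                               neutral_band = reference_ranges()$neutral_band) {
  require_analytes(delta_a_tot = delta_a_tot, delta_sida = delta_sida)
  if (neutral_band < 0) stop("neutral_band must be >= 0", call. = FALSE)
  diff <- delta_a_tot - delta_sida
  ifelse(abs(diff) <= neutral_band, "Neutral",
         ifelse(diff > 0, "Alkalosis", "Acidosis"))
}

#' Increased-anion-gap flag from SIG
#'
#' `TRUE` when SIG strictly exceeds the threshold (default 7.0 mEq/L, the
#' upper normal bound), marking metabolic acidosis with an increased anion
#' gap.
#'
#' @param sig strong ion gap, mEq/L.
#' @param threshold flag threshold, mEq/L.
#' @return logical vector.
#' @examples
#' classify_high_ag(c(6.7, 7.0, 7.7))  # FALSE FALSE TRUE
#' @export
classify_high_ag <- function(sig, threshold = reference_ranges()$sig_threshold) {
  require_analytes(sig = sig)
  sig > threshold
}

#' Non-lactate unmeasured anion load
#'
#' SIG - lactate (lactate in mmol/L equals mEq/L for a monovalent anion):
#' the part of the strong ion gap not explained by lactate, i.e. uremic and
#' other non-volatile acids.
#'
#' @param sig strong ion gap, mEq/L.
#' @param lactate serum lactate, mmol/L (>= 0).
#' @return SIG - lactate, mEq/L.
#' @export
sig_minus_lactate <- function(sig, lactate) {
  require_analytes(sig = sig, lactate = lactate)
  if (any(lactate < 0)) stop("lactate must be non-negative", call. = FALSE)
  sig - lactate
}

#' Estimate A_TOT from albumin alone
#'
#' The published cohort regression A_TOT = 2.6425 x albumin + 2.3323
#' (R^2 = 0.919), a bedside shortcut when phosphate or pH is unavailable.
#'
#' @param albumin serum albumin, g/dL (>= 0).
#' @return estimated A_TOT, mEq/L.
#' @examples
#' estimate_a_tot_from_alb(4.4)  # ~14.0, the normal value
#' estimate_a_tot_from_alb(1.5)  # 6.30
#' @export
estimate_a_tot_from_alb <- function(albumin) {
  require_analytes(albumin = albumin)
  if (any(albumin < 0)) stop("albumin must be non-negative", call. = FALSE)
  fit <- published_fits()$a_tot_vs_alb
  unname(fit["slope"] * albumin + fit["intercept"])
}

#' Estimate SIG from the corrected anion gap
#'
#' Published forms: raw, SIG = 0.9463 x cAG - 8.1956; delta, SIG = 0.9463 x
#' (cAG - 12) + 3.1605. The two differ only by rounding of the intercept
#' (< 0.001 mEq/L everywhere).
#'
#' @param cag corrected anion gap, mEq/L.
#' @param form `"raw"` or `"delta"`.
#' @return estimated SIG, mEq/L.
#' @examples
#' estimate_sig_from_cag(16.7)  # ~7.6, above the 7.0 flag threshold
#' @export
estimate_sig_from_cag <- function(cag, form = c("raw", "delta")) {
  require_analytes(cag = cag)
  form <- match_label(form[1], c("raw", "delta"), "regression form")
  f <- published_fits()
  if (form == "raw") {
    unname(f$sig_vs_cag["slope"] * cag + f$sig_vs_cag["intercept"])
  } else {
    unname(f$sig_vs_delta_cag["slope"] * (cag - 12) +
             f$sig_vs_delta_cag["intercept"])
  }
}

#' Full Stewart profile for one or more patients
#'
#' Derives the physicochemical panel from pH, PaCO2, A_TOT and SIDa:
#' calculated HCO3, SIDe, SIG, both deltas, SIG - lactate, the normal-AG
#' verdict and the increased-AG flag. `a_tot` may be supplied directly (the
#' reference cohort reports it) or computed from albumin/phosphate with
#' [a_tot()] upstream.
#'
#' @param ph,paco2 arterial pH and CO2 tension.
#' @param a_tot total non-volatile weak acids, mEq/L.
#' @param sida apparent strong ion difference, mEq/L.
#' @param lactate serum lactate, mmol/L; optional (NA gives NA for
#'   `sig_minus_lactate`).
#' @param refs a [reference_ranges()] object.
#' @param hco3_dialect dialect for the calculated HCO3 inside SIDe.
#' @return data.frame: `hco3_calc`, `a_tot`, `delta_a_tot`, `sida`,
#'   `delta_sida`, `side`, `sig`, `sig_minus_lactate`, `normal_ag_verdict`,
#'   `high_ag_flag`.
#' @examples
#' stewart_profile(7.43, 34.0, a_tot = 6.16, sida = 34.8, lactate = 1.3)
#' @export
stewart_profile <- function(ph, paco2, a_tot, sida, lactate = NA_real_,
                            refs = reference_ranges(),
                            hco3_dialect = c("agrafiotis", "kellum")) {
  hco3_dialect <- hco3_dialect[1]
  h <- hco3_calc(ph, paco2, hco3_dialect)
  se <- side(h, a_tot)
  sg <- sig(sida, se)
  da <- delta_a_tot(a_tot, refs$reference_a_tot)
  ds <- delta_sida(sida, refs$reference_sida)
  data.frame(
    hco3_calc = h,
    a_tot = a_tot,
    delta_a_tot = da,
    sida = sida,
    delta_sida = ds,
    side = se,
    sig = sg,
    sig_minus_lactate = ifelse(is.na(lactate), NA_real_, sg - lactate),
    normal_ag_verdict = classify_normal_ag(da, ds, refs$neutral_band),
    high_ag_flag = classify_high_ag(sg, refs$sig_threshold),
    stringsAsFactors = FALSE
  )
}

#' Partition an increased-anion-gap acidosis by lactate contribution
#'
#' Heuristic labels for what fills the strong ion gap, applied to patients
#' flagged by [classify_high_ag()]: `"lactate_dominant"` (elevated lactate
#' and little residual gap), `"mixed"` (elevated lactate plus a substantial
#' non-lactate residual), `"non_lactate_dominant"` (flagged gap without
#' elevated lactate), otherwise `"none"`. The cut-offs are package defaults
#' exposed for sensitivity analysis; they are not validated against any
#' published partition (see the methods vignette).
#'
#' @param sig strong ion gap, mEq/L.
#' @param lactate serum lactate, mmol/L.
#' @param high_ag_flag logical, from [classify_high_ag()].
#' @param lactate_cut lactate threshold, mmol/L (default 1.0).
#' @param residual_cut SIG - lactate threshold, mEq/L (default 5).
#' @return character vector of partition labels.
#' @export
lactate_partition <- function(sig, lactate, high_ag_flag,
                              lactate_cut = 1.0, residual_cut = 5) {
  require_analytes(sig = sig, lactate = lactate)
  sml <- sig - lactate
  ifelse(lactate > lactate_cut & sml <= residual_cut, "lactate_dominant",
  ifelse(lactate > lactate_cut & sml > residual_cut, "mixed",
  ifelse(lactate <= lactate_cut & high_ag_flag, "non_lactate_dominant",
         "none")))
}
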