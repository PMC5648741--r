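#' Serum anion gap
#'
#' AG = Na - (Cl + HCO3), the classic unmeasured-anion screen. In severe
#' hypoalbuminemia the uncorrected AG is misleadingly low because albumin
#' carries most of the normal unmeasured negative charge; see
#' [corrected_anion_gap()].
#'
#' @param na,cl serum sodium and chloride, mEq/L.
#' @param hco3 bicarbonate, mEq/L (typically the blood-gas value).
#' @param digits decimals for half-up rounding of the result (default 1);
#'   `NULL` to skip rounding.
#' @return anion gap, mEq/L.
#' @examples
#' anion_gap(140, 104, 24)   # 12, midpoint of the normal 12 +/- 2 range
#' @export
anion_gap <- function(na, cl, hco3, digits = 1) {
  require_analytes(na = na, cl = cl, hco3 = hco3)
  out <- na - (cl + hco3)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Albumin-corrected anion gap
#'
#' cAG = AG + 2.5 x (4.4 - albumin), restoring the gap that hypoalbuminemia
#' hides (2.5 mEq/L of anionic charge per g/dL of albumin below 4.4 g/dL).
#'
#' @param ag anion gap, mEq/L.
#' @param albumin serum albumin, g/dL; must be positive.
#' @inheritParams anion_gap
#' @return corrected anion gap, mEq/L. Equal to `ag` at albumin 4.4 g/dL and
#'   strictly larger below it.
#' @examples
#' corrected_anion_gap(8.9, 1.3)   # 16.7
#' @export
corrected_anion_gap <- function(ag, albumin, digits = 1) {
  require_analytes(ag = ag, albumin = albumin)
  if (any(albumin <= 0)) stop("albumin must be positive (g/dL)", call. = FALSE)
  out <- ag + 2.5 * (4.4 - albumin)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Acidemia or alkalemia from pH
#'
#' The cut is pH 7.40; the boundary value itself is labelled alkalemia,
#' matching the reference cohort's counting of a pH-7.40 patient among the
#' alkalemic majority.
#'
#' @param ph arterial pH.
#' @return character vector, `"acidemia"` or `"alkalemia"`.
#' @examples
#' ph_status(c(7.29, 7.40, 7.55))
#' @export
ph_status <- function(ph) {
  require_analytes(ph = ph)
  ifelse(ph >= 7.40, "alkalemia", "acidemia")
}

#' Expected bicarbonate in respiratory alkalosis
#'
#' Compensation lines for respiratory alkalosis: acute, HCO3 = 0.2 PaCO2 +
#' 17; chronic, HCO3 = 0.5 PaCO2 + 5. A measured HCO3 far from both lines
#' flags a coexisting metabolic disturbance.
#'
#' @param paco2 arterial CO2 tension, Torr; positive.
#' @param phase `"acute"` or `"chronic"`.
#' @param refs a [reference_ranges()] object carrying the coefficients.
#' @return expected HCO3, mEq/L (unrounded).
#' @examples
#' expected_hco3(34, "acute")     # 23.8
#' expected_hco3(25.7, "chronic") # 17.85
#' @export
expected_hco3 <- function(paco2, phase = c("acute", "chronic"),
                          refs = reference_ranges()) {
  require_analytes(paco2 = paco2)
  if (any(paco2 <= 0)) stop("paco2 must be positive (Torr)", call. = FALSE)
  phase <- match_label(phase[1], c("acute", "chronic"), "compensation phase")
  k <- if (phase == "acute") refs$kellum_acute else refs$kellum_chronic
  unname(k["slope"] * paco2 + k["intercept"])
}

#' Boston (CO2/HCO3) classification of a blood gas
#'
#' The traditional workflow: label acidemia/alkalemia at pH 7.40, call
#' respiratory alkalosis when an alkalemic patient has PaCO2 strictly below
#' 40 Torr, then compare measured HCO3 against the acute compensation line
#' (the chronic line is reported alongside) to detect an additional
#' metabolic disturbance. An alkalemic patient with PaCO2 at or above 40
#' Torr is called metabolic alkalosis outright; an acidemic patient with
#' PaCO2 above 40 Torr respiratory acidosis; an acidemic patient with HCO3
#' below the normal floor or below the expected compensation band metabolic
#' acidosis.
#'
#' @param ph arterial pH.
#' @param paco2 arterial CO2 tension, Torr.
#' @param hco3 measured bicarbonate, mEq/L.
#' @param refs a [reference_ranges()] object; `compensation_band` (default
#'   +/- 2 mEq/L) is the tolerance around the expected HCO3 treated as
#'   adequate compensation.
#' @param phase compensation phase compared against, `"acute"` by default
#'   (duration of the respiratory disturbance is usually unknown on a single
#'   gas).
#' @return a data.frame with one row per input: `ph_status`,
#'   `respiratory_verdict`, `metabolic_verdict`, `expected_hco3_acute`,
#'   `expected_hco3_chronic`, `compensation_note`.
#' @examples
#' classify_boston(7.43, 34.0, 22.1)  # respiratory alkalosis
#' classify_boston(7.29, 31.5, 14.9)  # metabolic acidosis
#' @export
classify_boston <- function(ph, paco2, hco3, refs = reference_ranges(),
                            phase = c("acute", "chronic")) {
  require_analytes(ph = ph, paco2 = paco2, hco3 = hco3)
  phase <- match.arg(phase)
  n <- max(length(ph), length(paco2), length(hco3))
  ph <- rep_len(ph, n); paco2 <- rep_len(paco2, n); hco3 <- rep_len(hco3, n)

  status <- ph_status(ph)
  exp_acute <- expected_hco3(paco2, "acute", refs)
  exp_chronic <- expected_hco3(paco2, "chronic", refs)
  expected <- if (phase == "acute") exp_acute else exp_chronic
  band <- refs$compensation_band

  resp <- ifelse(status == "alkalemia" & paco2 < 40, "respiratory_alkalosis",
          ifelse(status == "acidemia" & paco2 > 40, "respiratory_acidosis",
                 "none"))
  metab <- character(n)
  note <- character(n)
  for (i in seq_len(n)) {
    if (status[i] == "alkalemia") {
      if (resp[i] == "respiratory_alkalosis") {
        dev <- hco3[i] - expected[i]
        if (dev > band) {
          metab[i] <- "metabolic_alkalosis"
          note[i] <- sprintf(
            "HCO3 %.1f exceeds expected %s-compensation %.1f by %.1f mEq/L",
            hco3[i], phase, expected[i], dev)
        } else if (dev < -band) {
          metab[i] <- "metabolic_acidosis"
          note[i] <- sprintf(
            "HCO3 %.1f below expected %s-compensation %.1f by %.1f mEq/L",
            hco3[i], phase, expected[i], -dev)
        } else {
          metab[i] <- "none"
          note[i] <- sprintf(
            "HCO3 %.1f within %.1f mEq/L of expected %s-compensation %.1f",
            hco3[i], band, phase, expected[i])
        }
      } else {
        metab[i] <- "metabolic_alkalosis"
        note[i] <- "alkalemia without hypocapnia"
      }
    } else {
      if (hco3[i] < 22 || hco3[i] < expected[i] - band) {
        metab[i] <- "metabolic_acidosis"
        note[i] <- sprintf("acidemia with HCO3 %.1f mEq/L", hco3[i])
      } else {
        metab[i] <- "none"
        note[i] <- "acidemia without reduced HCO3"
      }
    }
  }
  data.frame(
    ph_status = status,
    respiratory_verdict = resp,
    metabolic_verdict = metab,
    expected_hco3_acute = exp_acute,
    expected_hco3_chronic = exp_chronic,
    compensation_note = note,
    stringsAsFactors = FALSE
  )
}
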