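#' Urinary anion gap
#'
#' U-Na + U-K - U-Cl, a bedside proxy for urinary ammonium excretion: a
#' negative gap implies brisk NH4+ excretion (appropriate renal response to
#' acidosis), a positive gap impaired acid excretion.
#'
#' @param u_na,u_k,u_cl urinary sodium, potassium, chloride, mEq/L (>= 0).
#' @param digits decimals for half-up rounding (default 1); `NULL` to skip.
#' @return urinary anion gap, mEq/L.
#' @examples
#' urinary_anion_gap(80, 52, 96)  # 36
#' @export
urinary_anion_gap <- function(u_na, u_k, u_cl, digits = 1) {
  require_analytes(u_na = u_na, u_k = u_k, u_cl = u_cl)
  if (any(c(u_na, u_k, u_cl) < 0)) {
    stop("urinary electrolytes must be non-negative", call. = FALSE)
  }
  out <- u_na + u_k - u_cl
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Categorize renin and aldosterone against their reference ranges
#'
#' Labels plasma renin activity (PRA) and plasma aldosterone concentration
#' (PAC) as below / within / above their reference ranges (inclusive on both
#' ends) and derives the combined state: both above is hyperreninemic
#' hyperaldosteronism; PAC below normal is hypoaldosteronism
#' (hyperreninemic or hyporeninemic/normoreninemic by the PRA label).
#'
#' @param pra plasma renin activity, ng/mL/h (>= 0).
#' @param pac plasma aldosterone concentration, pg/mL (>= 0).
#' @param refs a [reference_ranges()] object (`pra_normal`, `pac_normal`).
#' @return data.frame: `pra`, `pac`, `pra_category`, `pac_category`,
#'   `combined` (text label).
#' @examples
#' categorize_endocrine(13.0, 191.0)  # hyperreninemic hyperaldosteronism
#' categorize_endocrine(0.6, 10.0)    # hypoaldosteronism
#' @export
categorize_endocrine <- function(pra, pac, refs = reference_ranges()) {
  require_analytes(pra = pra, pac = pac)
  if (any(pra < 0) || any(pac < 0)) {
    stop("pra and pac must be non-negative", call. = FALSE)
  }
  cut3 <- function(x, rng) {
    ifelse(x < rng[1], "below", ifelse(x > rng[2], "above", "within"))
  }
  pra_cat <- cut3(pra, refs$pra_normal)
  pac_cat <- cut3(pac, refs$pac_normal)
  combined <- ifelse(
    pra_cat == "above" & pac_cat == "above", "hyperreninemic hyperaldosteronism",
    ifelse(pac_cat == "below" & pra_cat == "above", "hyperreninemic hypoaldosteronism",
    ifelse(pac_cat == "below", "hypoaldosteronism",
    ifelse(pac_cat == "above", "hyperaldosteronism", "normoaldosteronism"))))
  data.frame(pra = pra, pac = pac,
             pra_category = pra_cat, pac_category = pac_cat,
             combined = combined, stringsAsFactors = FALSE)
}

#' Alveolar-arterial oxygen gradient (standard alveolar gas equation)
#'
#' A-aDO2 = FiO2 (Patm - PH2O) - PaCO2 / RQ - PaO2, with room-air defaults
#' (FiO2 0.21, Patm 760 Torr, water vapour 47 Torr, respiratory quotient
#' 0.8). Provided as a utility; the packaged cohort's A-aDO2 column is
#' carried as recorded analyzer output and never recomputed, because no
#' stated constant set reproduces it.
#'
#' @param pao2,paco2 arterial O2 and CO2 tensions, Torr.
#' @param fio2 inspired O2 fraction in (0, 1].
#' @param patm barometric pressure, Torr.
#' @param ph2o water vapour pressure, Torr.
#' @param rq respiratory quotient.
#' @param digits decimals for half-up rounding (default 1); `NULL` to skip.
#' @return A-aDO2, Torr.
#' @examples
#' aado2_standard(90, 40)  # 9.7
#' @export
aado2_standard <- function(pao2, paco2, fio2 = 0.21, patm = 760, ph2o = 47,
                           rq = 0.8, digits = 1) {
  require_analytes(pao2 = pao2, paco2 = paco2)
  if (fio2 <= 0 || fio2 > 1) stop("fio2 must be in (0, 1]", call. = FALSE)
  out <- fio2 * (patm - ph2o) - paco2 / rq - pao2
  if (is.null(digits)) out else round_half_up(out, digits)
}
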