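#' Reference ranges and model constants
#'
#' All published constants used by the Boston and Stewart workflows, bundled
#' in one overridable object: control-group means and normal ranges for the
#' Stewart quantities, the normal anion-gap and corrected-anion-gap ranges,
#' the SIG threshold for increased-anion-gap acidosis, renin/aldosterone
#' reference ranges, and the respiratory-alkalosis compensation coefficients.
#'
#' Defaults are the control-derived values of the packaged nephrotic cohort
#' study: A_TOT 14.09 (12.29--15.90), SIDa 42.7 (39.9--45.5), SIDe 38.5
#' (36.1--41.0), SIG 4.2 (1.4--7.0) mEq/L; AG 12 +/- 2 and cAG 11.0--15.1
#' mEq/L; PRA 0.3--2.9 ng/mL/h; PAC 30--160 pg/mL. Compensation (acute,
#' chronic) lines are HCO3 = 0.2 PaCO2 + 17 and 0.5 PaCO2 + 5.
#'
#' @param ... named overrides of any listed field.
#' @return an object of class `acidbase_refs` (a named list).
#' @examples
#' reference_ranges()
#' reference_ranges(sig_threshold = 6.5)
#' @export
reference_ranges <- function(...) {
  refs <- list(
    reference_a_tot = 14.09, a_tot_range = c(12.29, 15.90),
    reference_sida  = 42.7,  sida_range  = c(39.9, 45.5),
    reference_side  = 38.5,  side_range  = c(36.1, 41.0),
    reference_sig   = 4.2,   sig_range   = c(1.4, 7.0),
    sig_threshold   = 7.0,
    ag_normal       = c(10, 14),       # 12 +/- 2 mEq/L
    cag_normal      = c(11.0, 15.1),
    pra_normal      = c(0.3, 2.9),     # ng/mL/h
    pac_normal      = c(30, 160),      # pg/mL
    kellum_acute    = c(slope = 0.2, intercept = 17),
    kellum_chronic  = c(slope = 0.5, intercept = 5),
    neutral_band    = 0.1,             # mEq/L, see classify_normal_ag()
    compensation_band = 2.0,           # mEq/L, see classify_boston()
    reference_lactate = 0.9            # mmol/L, control mean
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(refs))
  if (length(unknown)) {
    stop("unknown reference field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  refs[names(dots)] <- dots
  ranges <- refs[grepl("_range$|_normal$", names(refs))]
  ok <- vapply(ranges, function(r) length(r) == 2L && r[1] <= r[2], logical(1))
  if (!all(ok)) {
    stop("reference range(s) with lower > upper: ",
         paste(names(ranges)[!ok], collapse = ", "), call. = FALSE)
  }
  structure(refs, class = "acidbase_refs")
}

#' @export
print.acidbase_refs <- function(x, ...) {
  cat("Acid-base reference constants\n")
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = " - ")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, fmt(x[[nm]])))
  invisible(x)
}

#' Published regression constants
#'
#' The study-reported fits relating the Stewart quantities to routine
#' chemistry, stored verbatim (they are published constants, never refitted
#' in place): A_TOT from albumin, SIG from the corrected anion gap (raw and
#' delta-cAG forms), and the delta-A_TOT shortcut line in albumin.
#'
#' @return named list of coefficient sets.
#' @examples
#' published_fits()$a_tot_vs_alb
#' @export
published_fits <- function() {
  list(
    a_tot_vs_alb = c(slope = 2.6425, intercept = 2.3323, r2 = 0.91851),
    sig_vs_cag = c(slope = 0.9463, intercept = -8.1956, r2 = 0.91057),
    sig_vs_delta_cag = c(slope = 0.9463, intercept = 3.1605),
    delta_a_tot_from_alb = c(intercept = 11.77, slope = -2.64)
  )
}
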