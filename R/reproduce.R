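#' Published summary values for the packaged nephrotic cohort
#'
#' The headline cohort-level numbers reported for the 29-patient reference
#' cohort, used by [reproduce_report()] as comparison targets: threshold
#' counts and the median/IQR rows of the summary table.
#'
#' @return named list of constants.
#' @export
published_cohort_values <- function() {
  list(
    n = 29L,
    n_acidemia = 4L,              # pH < 7.40
    n_alkalemia = 25L,            # pH >= 7.40
    n_resp_alkalosis = 18L,       # alkalemia & PaCO2 < 40
    n_paco2_lt40 = 21L,
    n_lactate_gt1 = 20L,
    n_cag_gt_normal = 16L,        # cAG > 15.1
    n_high_ag = 12L,              # SIG > 7.0
    medians = data.frame(
      analyte = c("ph", "paco2", "hco3", "ag", "cag", "lactate",
                  "a_tot", "sida", "side", "sig", "urinary_ag"),
      median = c(7.43, 34.9, 23.7, 8.6, 15.8, 1.3,
                 7.13, 36.4, 29.9, 6.6, 38.9),
      q25 = c(7.42, 30.8, 21.1, 7.0, 13.6, 1.0,
              6.00, 35.0, 27.1, 4.4, 29.0),
      q75 = c(7.45, 40.0, 26.0, 10.8, 17.4, 1.9,
              7.83, 38.0, 32.9, 8.2, 55.0),
      stringsAsFactors = FALSE)
  )
}

report_row <- function(check, computed, expected, tol) {
  data.frame(check = check, computed = computed, expected = expected,
             tol = tol, pass = is.finite(computed) &
               abs(computed - expected) <= tol + 1e-12,
             stringsAsFactors = FALSE)
}

#' Reproduction report against the packaged reference cohort
#'
#' Recomputes every reproducible reported quantity from the packaged
#' per-patient fixtures -- the full Stewart chain (SIDe, SIG, deltas,
#' verdicts, flags) from pH, PaCO2, reported A_TOT and SIDa; the Boston
#' counts; the gap arithmetic; the urinary anion gap; and the cohort
#' medians/IQRs -- and compares each against its reported value at a stated
#' tolerance. Recomputed SIDe/SIG carry +/- 0.35 mEq/L per patient: the
#' source tables print pH to two decimals, and +/- 0.005 pH moves the
#' calculated HCO3 by ln(10) x 0.005 = 1.16%, up to ~0.34 mEq/L at the
#' cohort's highest bicarbonates. Chain medians carry +/- 0.25 (rounding
#' errors largely cancel across patients); directly transcribable cells
#' +/- 0.05; deltas 0.01; counts 0. No randomness is involved.
#'
#' @param cohort the merged cohort table; defaults to [nephrotic_cohort()].
#' @param refs a [reference_ranges()] object.
#' @return object of class `reproduction_report`: data.frame with columns
#'   `check`, `computed`, `expected`, `tol`, `pass`; attribute `report` (the
#'   per-patient [acid_base()] report). Overall pass iff `all(x$pass)`.
#' @examples
#' rep <- reproduce_report()
#' all(rep$pass)
#' @export
reproduce_report <- function(cohort = nephrotic_cohort(),
                             refs = reference_ranges()) {
  pub <- published_cohort_values()
  rep <- acid_base(cohort, refs)

  rows <- list(
    report_row("records loaded", nrow(cohort), pub$n, 0),
    report_row("max |SIDe - reported|", max(abs(rep$side - cohort$side_printed)),
               0, 0.35),
    report_row("max |SIG - reported|", max(abs(rep$sig - cohort$sig_printed)),
               0, 0.35),
    report_row("max |delta A_TOT - reported|",
               max(abs(rep$delta_a_tot - cohort$delta_a_tot_printed)), 0, 0.01),
    report_row("max |delta SIDa - reported|",
               max(abs(rep$delta_sida - cohort$delta_sida_printed)), 0, 0.01),
    report_row("normal-AG verdicts reproduced",
               sum(rep$normal_ag_verdict == cohort$verdict_printed), pub$n, 0),
    report_row("increased-AG flags reproduced",
               sum(rep$high_ag_flag == (cohort$agplus_printed == 1)), pub$n, 0),
    report_row("patients with SIG > 7.0", sum(rep$high_ag_flag),
               pub$n_high_ag, 0),
    report_row("acidemic patients (pH < 7.40)",
               count_where(cohort, "ph", "<", 7.40)$count, pub$n_acidemia, 0),
    report_row("respiratory alkalosis verdicts",
               sum(rep$respiratory_verdict == "respiratory_alkalosis"),
               pub$n_resp_alkalosis, 0),
    report_row("patients with PaCO2 < 40",
               count_where(cohort, "paco2", "<", 40)$count, pub$n_paco2_lt40, 0),
    report_row("patients with lactate > 1.0",
               count_where(cohort, "lactate", ">", 1.0)$count,
               pub$n_lactate_gt1, 0),
    report_row("patients with cAG > 15.1",
               count_where(cohort, "cag_printed", ">", 15.1)$count,
               pub$n_cag_gt_normal, 0),
    report_row("max |cAG - reported| (recomputed from AG, albumin)",
               max(abs(corrected_anion_gap(cohort$ag_printed, cohort$albumin) -
                         cohort$cag_printed)), 0, 0.05),
    report_row("max |urinary AG - reported|",
               max(abs(urinary_anion_gap(cohort$u_na, cohort$u_k, cohort$u_cl) -
                         cohort$urinary_ag_printed)), 0, 0.05)
  )

  med <- pub$medians
  src <- list(
    ph = cohort$ph, paco2 = cohort$paco2, hco3 = cohort$hco3,
    ag = cohort$ag_printed, cag = cohort$cag_printed,
    lactate = cohort$lactate, a_tot = cohort$a_tot_printed,
    sida = cohort$sida_printed, side = rep$side, sig = rep$sig,
    urinary_ag = urinary_anion_gap(cohort$u_na, cohort$u_k, cohort$u_cl))
  for (i in seq_len(nrow(med))) {
    a <- med$analyte[i]
    tol <- if (a %in% c("side", "sig")) 0.25 else 0.05
    m <- median_iqr(src[[a]])
    rows <- c(rows, list(
      report_row(paste0("median ", a), m[["median"]], med$median[i], tol),
      report_row(paste0("q25 ", a), m[["q25"]], med$q25[i], tol),
      report_row(paste0("q75 ", a), m[["q75"]], med$q75[i], tol)))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("reproduction_report", "data.frame"), report = rep)
}

#' @export
print.reproduction_report <- function(x, ...) {
  n_pass <- sum(x$pass)
  cat(sprintf("Reproduction report: %d/%d checks pass\n", n_pass, nrow(x)))
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  df$status <- ifelse(df$pass, "ok", "FAIL")
  print(df[, c("check", "computed", "expected", "tol", "status")],
        right = FALSE, row.names = FALSE)
  invisible(x)
}
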