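resolve_column <- function(records, name) {
  for (cand in c(name, paste0(name, "_printed"))) {
    if (cand %in% names(records)) return(records[[cand]])
  }
  NULL
}

#' Dual-model acid-base assessment of a cohort
#'
#' Runs the Boston (CO2/HCO3) and Stewart (physicochemical) workflows over a
#' table of patient records and returns one report row per patient.
#'
#' Input resolution, per quantity: a plain column is used if present, then a
#' `*_printed` column (the packaged reference cohort reports A_TOT, SIDa and
#' AG directly), then a computed fallback -- A_TOT from albumin, phosphate
#' and pH; SIDa from Na, K, Cl; AG from Na, Cl and measured HCO3. The
#' Stewart chain always uses the calculated (Henderson-Hasselbalch) HCO3
#' inside SIDe, not the analyzer's reported HCO3.
#'
#' @param records data.frame; must contain `ph` and `paco2`, plus enough
#'   columns to resolve the quantities above. `hco3` (measured) is required
#'   for the Boston arm, `lactate` is optional.
#' @param refs a [reference_ranges()] object.
#' @param a_tot_dialect,hco3_dialect Stewart formula dialects.
#' @return an object of class `acid_base_report`: a data.frame with
#'   `patient_id`, the Boston columns of [classify_boston()], `ag`, `cag`,
#'   and the Stewart columns of [stewart_profile()] plus `partition_label`.
#' @examples
#' acid_base(nephrotic_cohort())
#' @export
acid_base <- function(records, refs = reference_ranges(),
                      a_tot_dialect = "agrafiotis",
                      hco3_dialect = "agrafiotis") {
  if (!is.data.frame(records)) stop("records must be a data.frame", call. = FALSE)
  for (col in c("ph", "paco2")) {
    if (!col %in% names(records)) {
      stop("schema error: missing column: ", col, call. = FALSE)
    }
  }
  n <- nrow(records)
  ph <- records$ph
  paco2 <- records$paco2
  hco3_meas <- resolve_column(records, "hco3")
  lactate <- resolve_column(records, "lactate")
  if (is.null(lactate)) lactate <- rep(NA_real_, n)

  atot <- resolve_column(records, "a_tot")
  if (is.null(atot)) {
    alb <- resolve_column(records, "albumin")
    phos <- resolve_column(records, "phosphate")
    if (is.null(alb) || is.null(phos)) {
      stop("cannot resolve a_tot: need a_tot or albumin + phosphate",
           call. = FALSE)
    }
    atot <- a_tot(alb, phos, ph, a_tot_dialect)
  }
  sda <- resolve_column(records, "sida")
  if (is.null(sda)) {
    na <- resolve_column(records, "na"); k <- resolve_column(records, "k")
    cl <- resolve_column(records, "cl")
    if (is.null(na) || is.null(k) || is.null(cl)) {
      stop("cannot resolve sida: need sida or na + k + cl", call. = FALSE)
    }
    sda <- sida(na, k, cl)
  }
  ag <- resolve_column(records, "ag")
  if (is.null(ag)) {
    na <- resolve_column(records, "na"); cl <- resolve_column(records, "cl")
    if (!is.null(na) && !is.null(cl) && !is.null(hco3_meas)) {
      ag <- anion_gap(na, cl, hco3_meas)
    } else {
      ag <- rep(NA_real_, n)
    }
  }
  alb <- resolve_column(records, "albumin")
  cag <- if (!is.null(alb) && !all(is.na(ag))) {
    corrected_anion_gap(ag, alb)
  } else rep(NA_real_, n)

  boston <- if (!is.null(hco3_meas)) {
    classify_boston(ph, paco2, hco3_meas, refs)
  } else {
    data.frame(ph_status = ph_status(ph),
               respiratory_verdict = NA_character_,
               metabolic_verdict = NA_character_,
               expected_hco3_acute = expected_hco3(paco2, "acute", refs),
               expected_hco3_chronic = expected_hco3(paco2, "chronic", refs),
               compensation_note = "measured HCO3 unavailable",
               stringsAsFactors = FALSE)
  }
  stew <- stewart_profile(ph, paco2, atot, sda, lactate, refs, hco3_dialect)
  stew$partition_label <- lactate_partition(
    stew$sig, ifelse(is.na(lactate), 0, lactate), stew$high_ag_flag)

  out <- cbind(
    data.frame(patient_id = if ("patient_id" %in% names(records)) {
      records$patient_id
    } else seq_len(n)),
    data.frame(ph = ph, paco2 = paco2, ag = ag, cag = cag),
    boston, stew)
  rownames(out) <- NULL
  structure(out, class = c("acid_base_report", "data.frame"), refs = refs)
}

#' @export
print.acid_base_report <- function(x, ...) {
  cat(sprintf("Acid-base report: %d patient(s)\n", nrow(x)))
  cat(sprintf("  alkalemia %d / acidemia %d; respiratory alkalosis %d\n",
              sum(x$ph_status == "alkalemia"),
              sum(x$ph_status == "acidemia"),
              sum(x$respiratory_verdict == "respiratory_alkalosis",
                  na.rm = TRUE)))
  cat(sprintf("  normal-AG verdicts: %s\n",
              paste(sprintf("%s %d", names(table(x$normal_ag_verdict)),
                            table(x$normal_ag_verdict)), collapse = ", ")))
  cat(sprintf("  increased-AG flags (SIG > %.1f): %d\n",
              attr(x, "refs")$sig_threshold, sum(x$high_ag_flag)))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more row(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.acid_base_report <- function(object, ...) {
  x <- object
  out <- list(
    n = nrow(x),
    ph_status = table(x$ph_status),
    respiratory_verdict = table(x$respiratory_verdict),
    metabolic_verdict = table(x$metabolic_verdict),
    normal_ag_verdict = table(x$normal_ag_verdict),
    high_ag_flag = sum(x$high_ag_flag),
    stewart = cohort_summary(as.data.frame(x),
                             c("a_tot", "delta_a_tot", "sida", "delta_sida",
                               "side", "sig")))
  class(out) <- "summary.acid_base_report"
  out
}

#' @export
print.summary.acid_base_report <- function(x, ...) {
  cat(sprintf("Acid-base report summary (n = %d)\n\n", x$n))
  for (nm in c("ph_status", "respiratory_verdict", "metabolic_verdict",
               "normal_ag_verdict")) {
    cat(nm, ":\n", sep = "")
    print(x[[nm]])
    cat("\n")
  }
  cat("increased-AG flags:", x$high_ag_flag, "\n\n")
  cat("Stewart quantities (median, nearest-rank IQR):\n")
  print(x$stewart, digits = 4, row.names = FALSE)
  invisible(x)
}
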