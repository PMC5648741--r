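#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, "." decimal, `#` comment lines, empty cell =
#' missing. Missing numeric cells become `NA`, never zero. Column presence
#' and (numeric) type are checked against `required`.
#'
#' @param path file path.
#' @param required character vector of column names that must be present;
#'   names with a `"numeric"` entry in `types` are coerced and checked.
#' @param types optional named character vector, `"numeric"` or
#'   `"character"`, for required columns (default: numeric for all except
#'   obvious text fields).
#' @return data.frame of typed records.
#' @export
read_cohort <- function(path, required = c("patient_id"), types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  text_default <- c("sex", "biopsy", "association", "group", "diagnosis",
                    "verdict")
  for (col in required) {
    want <- if (!is.null(types) && col %in% names(types)) types[[col]]
            else if (col %in% text_default) "character" else "numeric"
    if (want == "numeric" && !is.numeric(df[[col]])) {
      conv <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.na(df[[col]]) & is.na(conv))
      if (length(bad)) {
        stop("unparsable cell in column '", col, "', row ", bad[1], ": ",
             df[[col]][bad[1]], call. = FALSE)
      }
      df[[col]] <- conv
    }
  }
  if ("patient_id" %in% names(df) && anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }
  df
}

#' Write a cohort CSV
#'
#' Companion writer to [read_cohort()] (same dialect; round-trips values).
#'
#' @param records data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "acidbase")
  if (p == "") stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' Load the packaged nephrotic reference cohort
#'
#' Reads the four transcribed per-patient tables (characteristics, arterial
#' blood gas, urine/endocrine panel, Stewart panel), merges them on
#' `patient_id`, and -- unless `validate = FALSE` -- runs transcription
#' guards so that a transcription error fails fast:
#' reported SIG equals reported SIDa - SIDe within 0.1; reported urinary AG
#' equals U-Na + U-K - U-Cl within 0.05; reported deltas equal reference
#' minus reported A_TOT/SIDa within 0.01; reported cAG equals
#' AG + 2.5 (4.4 - albumin) at half-up rounding.
#'
#' Reported derived columns are suffixed `_printed`; measured inputs keep
#' plain names. The Stewart table's own pH/PaCO2 columns are checked to
#' match the blood-gas table and then dropped.
#'
#' @param validate logical; run the cross-field transcription guards.
#' @return data.frame with one row per patient (n = 29), `group =
#'   "nephrotic"`.
#' @examples
#' coh <- nephrotic_cohort()
#' nrow(coh)  # 29
#' @export
nephrotic_cohort <- function(validate = TRUE) {
  pat <- read_cohort(
    fixture_path("nephrotic_patients.csv"),
    required = c("patient_id", "age", "sex", "u_protein", "tp", "albumin",
                 "bun", "creatinine", "egfr", "igg", "iga", "igm"))
  gas <- read_cohort(
    fixture_path("nephrotic_bloodgas.csv"),
    required = c("patient_id", "ph", "paco2", "pao2", "hco3", "aado2",
                 "ag", "cag", "lactate"))
  ue <- read_cohort(
    fixture_path("nephrotic_urine_endocrine.csv"),
    required = c("patient_id", "posm", "uosm", "u_na", "u_k", "u_cl",
                 "urinary_ag", "pra", "pac"))
  st <- read_cohort(
    fixture_path("nephrotic_stewart.csv"),
    required = c("patient_id", "ph", "paco2", "a_tot", "delta_a_tot",
                 "sida", "delta_sida", "verdict", "side", "sig", "agplus",
                 "lactate", "sig_minus_lactate"))

  names(gas)[names(gas) %in% c("ag", "cag")] <-
    c("ag_printed", "cag_printed")
  names(ue)[names(ue) == "urinary_ag"] <- "urinary_ag_printed"
  derived <- c("a_tot", "delta_a_tot", "sida", "delta_sida", "verdict",
               "side", "sig", "agplus", "sig_minus_lactate")
  names(st)[match(derived, names(st))] <- paste0(derived, "_printed")

  if (validate) {
    stopifnot(
      isTRUE(all.equal(st$ph, gas$ph)),
      max(abs(st$paco2 - gas$paco2)) < 1e-9,
      max(abs(st$lactate - gas$lactate)) < 1e-9
    )
    guard <- function(ok, what) {
      if (!all(ok)) {
        stop("fixture transcription guard failed: ", what, " (patient ",
             paste(st$patient_id[!ok], collapse = ", "), ")", call. = FALSE)
      }
    }
    refs <- reference_ranges()
    guard(abs(st$sig_printed - (st$sida_printed - st$side_printed)) <= 0.1 + 1e-9,
          "SIG = SIDa - SIDe")
    guard(abs(st$delta_a_tot_printed -
                (refs$reference_a_tot - st$a_tot_printed)) <= 0.01 + 1e-9,
          "delta A_TOT vs reference 14.09")
    guard(abs(st$delta_sida_printed -
                (refs$reference_sida - st$sida_printed)) <= 0.01 + 1e-9,
          "delta SIDa vs reference 42.7")
    guard(abs(ue$urinary_ag_printed -
                (ue$u_na + ue$u_k - ue$u_cl)) <= 0.05 + 1e-9,
          "urinary AG = U-Na + U-K - U-Cl")
    guard(abs(gas$cag_printed -
                round_half_up(gas$ag_printed +
                                2.5 * (4.4 - pat$albumin), 1)) <= 0.05 + 1e-9,
          "cAG = AG + 2.5 (4.4 - albumin)")
  }

  st$ph <- NULL; st$paco2 <- NULL; st$lactate <- NULL
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", sort = FALSE),
                list(pat, gas, ue, st))
  out <- out[order(out$patient_id), ]
  rownames(out) <- NULL
  out$group <- "nephrotic"
  out
}
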