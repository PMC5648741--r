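#' Sampling specification for a synthetic cohort
#'
#' Describes how to draw an internally consistent synthetic cohort:
#' group-specific physiologic ranges per analyte (scaled Beta(2, 2) draws,
#' so hard bounds are respected and values pile up mid-range), a seed, and
#' the analyzer noise added to the measured HCO3.
#'
#' Default nephrotic ranges span the packaged reference cohort's observed
#' values (severe hypoalbuminemia, mild hyperchloremia, low PaCO2, elevated
#' lactate); control ranges centre on the control group's reported summary
#' values. Any range can be overridden.
#'
#' @param group `"nephrotic"` or `"control"`.
#' @param n number of patients (>= 0).
#' @param seed integer RNG seed (default 20170313).
#' @param hco3_noise_sd analyzer noise on measured HCO3, mEq/L (default 0.3).
#' @param ranges named list of `c(lower, upper)` overrides.
#' @return object of class `cohort_spec`.
#' @examples
#' cohort_spec("control", n = 6)
#' @export
cohort_spec <- function(group = c("nephrotic", "control"), n = 29,
                        seed = 20170313, hco3_noise_sd = 0.3,
                        ranges = list()) {
  group <- match.arg(group)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  base <- if (group == "nephrotic") {
    list(albumin = c(0.8, 2.9), phosphate = c(3.0, 4.5),
         na = c(135, 144), k = c(3.5, 4.8), cl = c(103, 112),
         ph = c(7.29, 7.56), paco2 = c(21.5, 44.7), pao2 = c(47, 128),
         lactate = c(0.6, 4.2), pra = c(0.1, 19.0), pac = c(10, 310),
         u_na = c(18, 155), u_k = c(14, 100), u_cl = c(12, 160),
         posm = c(267, 332), uosm = c(196, 818))
  } else {
    list(albumin = c(4.4, 5.0), phosphate = c(3.0, 3.8),
         na = c(140, 145), k = c(4.5, 4.8), cl = c(103, 105),
         ph = c(7.39, 7.41), paco2 = c(39.4, 41.1), pao2 = c(87, 91),
         lactate = c(0.8, 1.0), pra = c(0.3, 2.9), pac = c(30, 160),
         u_na = c(40, 120), u_k = c(20, 60), u_cl = c(40, 120),
         posm = c(280, 295), uosm = c(300, 700))
  }
  unknown <- setdiff(names(ranges), names(base))
  if (length(unknown)) {
    stop("unknown analyte range(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(ranges)] <- ranges
  bad <- names(base)[vapply(base, function(r) {
    length(r) != 2L || r[1] > r[2]
  }, logical(1))]
  if (length(bad)) {
    stop("invalid range (lower > upper) for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(group = group, n = as.integer(n), seed = as.integer(seed),
                 hco3_noise_sd = hco3_noise_sd, ranges = base),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d %s patient(s), seed %d\n",
              x$n, x$group, x$seed))
  for (nm in names(x$ranges)) {
    cat(sprintf("  %-10s [%g, %g]\n", nm, x$ranges[[nm]][1], x$ranges[[nm]][2]))
  }
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws each analyte independently from its scaled-Beta range (correlation
#' with pathology enters through the group's ranges, not through copulas --
#' a documented simplification), then sets the measured HCO3 to the
#' Henderson-Hasselbalch value for the drawn pH/PaCO2 plus analyzer noise,
#' so the Boston and Stewart arms see mutually consistent gases.
#' Reproducible: the same spec and seed give the identical table.
#'
#' @param spec a [cohort_spec()] object.
#' @return data.frame with one row per patient, the same column schema the
#'   readers and [acid_base()] consume (empty but fully typed for `n = 0`).
#' @examples
#' generate_cohort(cohort_spec("nephrotic", n = 5, seed = 1))
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("spec must be a cohort_spec object", call. = FALSE)
  }
  n <- spec$n
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  draw <- function(rng) rng[1] + (rng[2] - rng[1]) * stats::rbeta(n, 2, 2)
  cols <- lapply(spec$ranges, draw)
  hco3 <- if (n > 0L) {
    hco3_calc(cols$ph, cols$paco2) + stats::rnorm(n, 0, spec$hco3_noise_sd)
  } else numeric(0)
  out <- data.frame(
    patient_id = seq_len(n),
    group = rep(spec$group, n),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cols), data.frame(hco3 = hco3))
}

# Electroneutrality-consistent pH: given strong ions, weak acids and the
# unmeasured-anion load xa, find the pH at which calculated HCO3 + A_TOT
# equals SIDa - xa. Monotone in pH, solved by uniroot to 1e-12.
solve_gas_ph <- function(na, k, cl, albumin, phosphate, paco2, xa) {
  target <- sida(na, k, cl) - xa
  f <- function(ph) hco3_calc(ph, paco2) + a_tot(albumin, phosphate, ph) - target
  stats::uniroot(f, c(6.5, 8.0), tol = 1e-12)$root
}

#' Inject a canonical acid-base disorder into a record
#'
#' Perturbs the minimal analyte set for the requested disorder and
#' re-derives pH and HCO3 so the record stays electroneutrality-consistent:
#' the implied unmeasured-anion load `xa = SIDa - calculated HCO3 - A_TOT`
#' is held (or incremented, for the increased-AG route) and pH is re-solved
#' from `HCO3(pH, PaCO2) + A_TOT(pH) = SIDa - xa`.
#'
#' \describe{
#'   \item{resp_alkalosis}{PaCO2 down by `magnitude` Torr}
#'   \item{high_ag_acidosis}{lactate (and the unmeasured-anion load) up by
#'     `magnitude` mmol/L; SIG rises one-for-one}
#'   \item{normal_ag_acidosis}{Cl up by `magnitude` mEq/L at fixed Na + K}
#'   \item{metabolic_alkalosis}{albumin down by `magnitude` g/dL (floored at
#'     0.1), lowering A_TOT}
#' }
#'
#' @param record one-or-more-row data.frame with `na`, `k`, `cl`, `albumin`,
#'   `phosphate`, `paco2`, `ph`, `lactate`.
#' @param disorder one of the labels above.
#' @param magnitude perturbation size, >= 0; `0` returns the record
#'   unchanged.
#' @return the perturbed record(s), with `ph`, `hco3` re-derived (noise-free).
#' @examples
#' ctrl <- generate_cohort(cohort_spec("control", n = 1, seed = 7))
#' inject_disorder(ctrl, "high_ag_acidosis", 6)
#' @export
inject_disorder <- function(record,
                            disorder = c("resp_alkalosis", "high_ag_acidosis",
                                         "normal_ag_acidosis",
                                         "metabolic_alkalosis"),
                            magnitude) {
  disorder <- match_label(disorder[1],
                          c("resp_alkalosis", "high_ag_acidosis",
                            "normal_ag_acidosis", "metabolic_alkalosis"),
                          "disorder")
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  if (magnitude == 0) return(record)
  need <- c("na", "k", "cl", "albumin", "phosphate", "paco2", "ph", "lactate")
  miss <- setdiff(need, names(record))
  if (length(miss)) {
    stop("record lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- record
  for (i in seq_len(nrow(record))) {
    r <- record[i, ]
    xa <- sida(r$na, r$k, r$cl) - hco3_calc(r$ph, r$paco2) -
      a_tot(r$albumin, r$phosphate, r$ph)
    if (disorder == "resp_alkalosis") {
      r$paco2 <- r$paco2 - magnitude
      if (r$paco2 <= 0) stop("magnitude drives PaCO2 non-positive", call. = FALSE)
    } else if (disorder == "high_ag_acidosis") {
      r$lactate <- r$lactate + magnitude
      xa <- xa + magnitude
    } else if (disorder == "normal_ag_acidosis") {
      r$cl <- r$cl + magnitude
    } else {
      r$albumin <- max(r$albumin - magnitude, 0.1)
    }
    r$ph <- solve_gas_ph(r$na, r$k, r$cl, r$albumin, r$phosphate, r$paco2, xa)
    r$hco3 <- hco3_calc(r$ph, r$paco2)
    out[i, names(r)] <- r
  }
  out
}
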