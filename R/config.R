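#' Load an analysis configuration from YAML
#'
#' A configuration file may set the Stewart formula dialects and override
#' any [reference_ranges()] field, e.g.:
#' ```yaml
#' a_tot_dialect: agrafiotis
#' hco3_dialect: agrafiotis
#' refs:
#'   sig_threshold: 7.0
#'   neutral_band: 0.1
#' ```
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return list with `refs` (an `acidbase_refs` object), `a_tot_dialect`,
#'   `hco3_dialect`.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(a_tot_dialect = "agrafiotis", hco3_dialect = "agrafiotis",
              refs = list())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  match_label(cfg$a_tot_dialect, c("agrafiotis", "rastegar"), "A_TOT dialect")
  match_label(cfg$hco3_dialect, c("agrafiotis", "kellum"), "HCO3 dialect")
  cfg$refs <- do.call(reference_ranges, cfg$refs)
  cfg
}
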