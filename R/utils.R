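#' Round half away from zero
#'
#' Reported clinical chemistry values use commercial ("half-up") rounding,
#' not the IEEE round-half-even used by [base::round()]. Ties are rounded
#' away from zero.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 1, the precision of
#'   the reported tables).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(16.65)   # 16.7
#' round(16.65, 1)        # 16.6 under banker's rounding
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Error out naming every analyte that is missing (NULL, NA or non-finite).
# `...` are named values, e.g. require_analytes(na = na, cl = cl).
require_analytes <- function(...) {
  vals <- list(...)
  bad <- names(vals)[vapply(vals, function(v) {
    is.null(v) || length(v) == 0L || anyNA(v) || !all(is.finite(v))
  }, logical(1))]
  if (length(bad)) {
    stop("missing or non-finite analyte(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

match_label <- function(x, choices, what) {
  if (length(x) != 1L || !is.character(x) || !x %in% choices) {
    stop("unknown ", what, " ", deparse(x), "; must be one of: ",
         paste(choices, collapse = ", "), call. = FALSE)
  }
  x
}
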