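#' Median and interquartile range, nearest-rank quartiles
#'
#' The median is the usual midpoint convention; the quartiles are
#' nearest-rank (type-1: the `ceiling(p * n)`-th sorted value), the
#' convention that reproduces every reported interquartile pair of the
#' packaged cohort at n = 29. Changing the quantile type invalidates the
#' reproduction report, so it is fixed here rather than exposed.
#'
#' @param values numeric vector, non-empty; NAs are dropped.
#' @return named numeric vector `c(median, q25, q75)`.
#' @examples
#' median_iqr(1:9)  # 5, 3, 7
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty value list", call. = FALSE)
  c(median = stats::median(values),
    q25 = unname(stats::quantile(values, 0.25, type = 1)),
    q75 = unname(stats::quantile(values, 0.75, type = 1)))
}

#' Count records satisfying a threshold predicate
#'
#' @param records data.frame of patient records.
#' @param field column name the predicate tests.
#' @param op comparison operator: one of `"<"`, `"<="`, `">"`, `">="`,
#'   `"=="` (strictness is always explicit).
#' @param value threshold.
#' @return list with `count` and `denominator` (non-missing records).
#' @examples
#' count_where(data.frame(ph = c(7.35, 7.42, NA)), "ph", "<", 7.40)
#' @export
count_where <- function(records, field, op = c("<", "<=", ">", ">=", "=="),
                        value) {
  if (!field %in% names(records)) {
    stop("unknown field: ", field, call. = FALSE)
  }
  op <- match.arg(op)
  x <- records[[field]]
  keep <- !is.na(x)
  hits <- get(op)(x[keep], value)
  list(count = sum(hits), denominator = sum(keep))
}

# R^2 without summary.lm()'s perfect-fit warning.
rsq <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Simple least-squares line
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], returned as a
#' light `regression_fit` record (slope, intercept, R^2).
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must vary.
#' @return object of class `regression_fit`: list with `coefficients`
#'   (intercept-first), `slope`, `intercept`, `r2`, `degree = 1`, `n`.
#' @examples
#' ols_fit(0:2, c(0, 1, 3))  # slope 1.5, intercept -1/6
#' @export
ols_fit <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2) stop("degenerate fit: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(
    list(coefficients = unname(stats::coef(fit)),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = rsq(fit, y),
         degree = 1L, n = length(x)),
    class = "regression_fit")
}

#' Polynomial least-squares fit
#'
#' Least-squares polynomial of the given degree (raw basis, via
#' [stats::lm()] on `poly(x, degree, raw = TRUE)`). Degree 1 reduces to
#' [ols_fit()].
#'
#' @param x,y numeric vectors; more points than `degree` required.
#' @param degree polynomial degree, 1 to 6.
#' @return object of class `regression_fit` with `coefficients` ordered
#'   intercept first.
#' @export
poly_fit <- function(x, y, degree) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  degree <- as.integer(degree)
  if (degree < 1L || degree > 6L) stop("degree must be 1..6", call. = FALSE)
  if (length(x) <= degree) {
    stop("under-determined fit: need more than ", degree, " points",
         call. = FALSE)
  }
  if (length(unique(x)) <= degree) {
    stop("degenerate fit: too few distinct x values", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  structure(
    list(coefficients = co,
         slope = if (degree == 1L) co[2] else NA_real_,
         intercept = co[1],
         r2 = rsq(fit, y),
         degree = degree, n = length(x)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  if (x$degree == 1L) {
    cat(sprintf("Least-squares line (n = %d): y = %.6g x + %.6g, R^2 = %.5f\n",
                x$n, x$slope, x$intercept, x$r2))
  } else {
    cat(sprintf("Degree-%d least-squares polynomial (n = %d), R^2 = %.5f\n",
                x$degree, x$n, x$r2))
    cat("  coefficients (intercept first):",
        paste(format(x$coefficients, digits = 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.regression_fit <- function(object, ...) object$coefficients

#' @export
predict.regression_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

#' Cohort summary table
#'
#' Median and nearest-rank IQR per analyte, in the row layout of the
#' reference cohort's summary table.
#'
#' @param records data.frame of patient records.
#' @param analytes column names to summarize; defaults to every numeric
#'   column except `patient_id`.
#' @return data.frame: `analyte`, `median`, `q25`, `q75`, `n`.
#' @export
cohort_summary <- function(records, analytes = NULL) {
  if (is.null(analytes)) {
    num <- vapply(records, is.numeric, logical(1))
    analytes <- setdiff(names(records)[num], "patient_id")
  }
  rows <- lapply(analytes, function(a) {
    x <- records[[a]]
    if (is.null(x)) stop("unknown field: ", a, call. = FALSE)
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(data.frame(analyte = a, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, n = 0L))
    }
    m <- median_iqr(x)
    data.frame(analyte = a, median = m[["median"]], q25 = m[["q25"]],
               q75 = m[["q75"]], n = length(x))
  })
  do.call(rbind, rows)
}
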