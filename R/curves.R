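#' Age-trajectory curve helpers
#'
#' The synthetic-data generator is parameterised by curves mapping child age
#' (in days) to a HAZ-scale quantity: the true population mean HAZ, the true
#' biological SD, or the SD of age-specific measurement error. These helpers
#' build such curves as plain R functions with light validation, so any
#' vectorised function of age can be supplied directly as well.
#'
#' @param value constant value returned at every age.
#' @param ages increasing vector of knot ages in days.
#' @param values curve values at the knot ages; linearly interpolated between
#'   knots and held constant beyond the outermost knots.
#' @return A function mapping a numeric vector of ages (days) to curve values.
#' @examples
#' f <- haz_curve_piecewise(c(0, 730), c(-0.4, -1.9))
#' f(c(0, 365, 730, 1000))
#' @name haz_curve
NULL

#' @rdname haz_curve
#' @export
haz_curve_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  force(value)
  f <- function(age_days) rep_len(value, length(age_days))
  attr(f, "curve_spec") <- list(type = "constant", value = value)
  f
}

#' @rdname haz_curve
#' @export
haz_curve_piecewise <- function(ages, values) {
  stopifnot(is.numeric(ages), is.numeric(values), length(ages) == length(values),
            length(ages) >= 1L, !is.unsorted(ages, strictly = TRUE))
  if (length(ages) == 1L) return(haz_curve_constant(values))
  f <- function(age_days) {
    stats::approx(ages, values, xout = age_days, rule = 2)$y
  }
  attr(f, "curve_spec") <- list(type = "piecewise", ages = ages, values = values)
  f
}

## Validate and normalise a user-supplied curve: must be a function of age
## returning finite numerics of matching length; optionally non-negative.
as_haz_curve <- function(curve, name = "curve", nonnegative = FALSE) {
  if (is.numeric(curve) && length(curve) == 1L) curve <- haz_curve_constant(curve)
  if (!is.function(curve)) {
    stop(sprintf("'%s' must be a function of age in days (or a single number)", name),
         call. = FALSE)
  }
  probe <- c(0, 500, 1095)
  out <- tryCatch(curve(probe), error = function(e) {
    stop(sprintf("'%s' failed when evaluated on ages %s: %s", name,
                 paste(probe, collapse = ", "), conditionMessage(e)), call. = FALSE)
  })
  if (!is.numeric(out) || length(out) != length(probe) || anyNA(out) ||
      any(!is.finite(out))) {
    stop(sprintf("'%s' must return finite numeric values, one per age", name),
         call. = FALSE)
  }
  if (nonnegative && any(out < 0)) {
    stop(sprintf("'%s' must be non-negative at every age", name), call. = FALSE)
  }
  curve
}
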