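#' Blank-correct a raw measurement series
#'
#' Subtracts the pointwise mean of the blank traces from a raw trace. With an
#' empty blank list the trace is returned unchanged.
#'
#' @param trace Numeric vector of raw measurements.
#' @param blanks List of numeric vectors (blank traces), each the same length
#'   as `trace`. May be empty.
#'
#' @return Numeric vector of corrected measurements, same length as `trace`.
#' @export
#' @examples
#' blank_correct(rep(0.5, 4), list(rep(0.1, 4), rep(0.1, 4)))
blank_correct <- function(trace, blanks = list()) {
  stopifnot(is.numeric(trace))
  if (is.numeric(blanks)) blanks <- list(blanks)
  if (length(blanks) == 0L) {
    return(trace)
  }
  lens <- vapply(blanks, length, integer(1))
  if (any(lens != length(trace))) {
    stop("All blank traces must have the same length as `trace`.",
         call. = FALSE)
  }
  trace - Reduce(`+`, blanks) / length(blanks)
}

#' Rolling-average smoothing
#'
#' Centered moving average with half-width `floor(window / 2)`. At the edges
#' the window is truncated symmetrically (equally many points on both sides),
#' so the output has the same length as the input and a constant series is
#' left unchanged. `window = 1` is the identity.
#'
#' @param series Numeric vector.
#' @param window Window size in data points (>= 1). Default 10, the
#'   application default.
#'
#' @return Smoothed numeric vector, same length as `series`.
#' @export
#' @examples
#' rolling_smooth(c(0, 3, 6), window = 3)
rolling_smooth <- function(series, window = 10L) {
  stopifnot(is.numeric(series))
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1) {
    stop("`window` must be an integer >= 1.", call. = FALSE)
  }
  window <- as.integer(window)
  n <- length(series)
  if (window == 1L || n <= 1L) {
    return(series)
  }
  h <- window %/% 2L
  cs <- cumsum(c(0, series))
  idx <- seq_len(n)
  hi <- pmin(h, idx - 1L, n - idx)
  (cs[idx + hi + 1L] - cs[idx - hi]) / (2 * hi + 1)
}

#' Log-transformed growth trace
#'
#' Transforms a blank-corrected series into the \eqn{y = \ln(N/N_0)} space
#' in which all fitting occurs. The reference \eqn{N_0} is the smallest
#' strictly positive value of the series, so `y >= 0` at every usable point.
#' Nonpositive values (possible after blank subtraction of noisy data) are
#' masked rather than clipped; fitters use valid points only.
#'
#' @param series Numeric vector of blank-corrected measurements in population
#'   units.
#' @param times Numeric vector of timestamps in hours, same length.
#'
#' @return An object of class `log_trace`: a list with elements `times`, `y`
#'   (log population, `NA` where masked), `n0` (reference population size)
#'   and `valid` (logical mask of usable points).
#' @export
#' @examples
#' tr <- log_transform(0.05 * exp(0.5 * (0:10)), times = 0:10)
#' tr$y  # 0.5 * t
log_transform <- function(series, times) {
  stopifnot(is.numeric(series), is.numeric(times))
  if (length(series) != length(times)) {
    stop("`series` and `times` must have the same length.", call. = FALSE)
  }
  valid <- !is.na(series) & series > 0
  if (!any(valid)) {
    stop("Cannot log-transform: trace entirely at or below blank.",
         call. = FALSE)
  }
  n0 <- min(series[valid])
  y <- rep(NA_real_, length(series))
  y[valid] <- log(series[valid] / n0)
  structure(
    list(times = as.numeric(times), y = y, n0 = n0, valid = valid),
    class = "log_trace"
  )
}

#' @export
print.log_trace <- function(x, ...) {
  cat(sprintf("<log_trace> %d points (%d valid), N0 = %s, t in [%s, %s] h\n",
              length(x$times), sum(x$valid), format(x$n0),
              format(min(x$times)), format(max(x$times))))
  invisible(x)
}

#' @export
as_tibble.log_trace <- function(x, ...) {
  tibble::tibble(time = x$times, y = x$y, valid = x$valid)
}
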