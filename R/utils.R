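# Internal numeric helpers shared across modules.

#' Trapezoidal integral of sampled data
#'
#' @param x sorted abscissa
#' @param y ordinates, same length
#' @return the trapezoidal quadrature of y over x
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Integral of the piecewise-linear interpolant of (x, y) over [lo, hi].
# Splits partial segments exactly so that adjacent intervals tile:
# trapz_between(x, y, a, b) + trapz_between(x, y, b, c) == trapz_between(x, y, a, c).
trapz_between <- function(x, y, lo, hi) {
  n <- length(x)
  lo <- max(lo, x[1L])
  hi <- min(hi, x[n])
  if (hi <= lo) return(0)
  interp <- function(at) {
    i <- findInterval(at, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    y[i] + (y[i + 1L] - y[i]) * (at - x[i]) / (x[i + 1L] - x[i])
  }
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(interp(lo), y[inside], interp(hi))
  trapz(xs, ys)
}

# Geometric mean of a positive vector.
geometric_mean <- function(x) exp(mean(log(x)))

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
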