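#' Falling factorial
#'
#' Computes \eqn{(x)_k = x (x-1) \cdots (x-k+1)}, the convention used
#' throughout for factorial moments and combinatorial binding propensities.
#' \code{ff(x, 0) = 1}.
#'
#' @param x numeric vector.
#' @param k non-negative integer order.
#' @return numeric vector of the same length as \code{x}.
#' @export
ff <- function(x, k) {
  stopifnot(length(k) == 1L, k >= 0)
  if (k == 0) return(rep(1, length(x)))
  out <- x
  if (k > 1) for (j in 1:(k - 1)) out <- out * (x - j)
  out
}

#' Mean burst size from the geometric burst parameter
#'
#' For geometric bursts with \eqn{P(k = n) = p^n (1 - p)} the mean burst
#' size is \eqn{B = p/(1-p)}. The degenerate case \code{p = 0} denotes
#' non-bursty synthesis (exactly one molecule per event, \eqn{B = 1}).
#'
#' @param p burst parameter in \eqn{[0, 1)}.
#' @return mean number of molecules produced per synthesis event.
#' @export
burst_size <- function(p) {
  check_prob(p, "p")
  ifelse(p == 0, 1, p / (1 - p))
}

#' Geometric burst parameter from the mean burst size
#'
#' Inverse of \code{\link{burst_size}} for genuinely bursty synthesis:
#' \eqn{p = B/(1+B)}.
#'
#' @param B mean burst size, \eqn{B > 0}.
#' @return burst parameter \eqn{p \in (0, 1)}.
#' @export
burst_param <- function(B) {
  if (any(B <= 0)) stop("B must be positive")
  B / (1 + B)
}

# Factorial moments E[(k)_j], j = 0..jmax, of the burst size distribution.
# p = 0 encodes the non-bursty fixed jump k = 1.
burst_factorial_moments <- function(p, jmax) {
  j <- 0:jmax
  if (p == 0) {
    as.numeric(j <= 1)
  } else {
    B <- p / (1 - p)
    factorial(j) * B^j
  }
}

#' Protein decay rate from half-life and cell-cycle duration
#'
#' Combines active degradation (protein half-life) and dilution due to cell
#' division into a single first-order decay rate
#' \eqn{d = \ln 2 / t_{1/2} + \ln 2 / t_{cc}}.
#'
#' @param half_life protein half-life, in hours.
#' @param cell_cycle mean cell-cycle duration, in hours.
#' @param unit output time unit, \code{"per_min"} or \code{"per_hour"}.
#' @return decay rate in the requested unit.
#' @examples
#' decay_rate(46, 27.5)            # ~6.7e-4 per minute
#' @export
decay_rate <- function(half_life, cell_cycle, unit = c("per_min", "per_hour")) {
  unit <- match.arg(unit)
  if (half_life <= 0 || cell_cycle <= 0) stop("durations must be positive")
  d <- log(2) / half_life + log(2) / cell_cycle
  if (unit == "per_min") d / 60 else d
}

# --- validation helpers -----------------------------------------------------

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative rate", name), call. = FALSE)
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x >= 1))
    stop(sprintf("'%s' must lie in [0, 1)", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# structured warning record used for matching fallbacks / clamped parameters
holimap_condition <- function(msg, class, ...) {
  structure(
    class = c(class, "holimap_condition", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}
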