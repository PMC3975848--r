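# IIR filtering primitives. Coefficients come from signal::butter; the
# recursion itself runs in compiled code (direct-form II transposed),
# which keeps per-call overhead low enough for the 10,000-draw
# permutation loop and for filtering hours of multichannel EEG.

#' Steady-state filter state for a unit-amplitude input
#'
#' Solves the direct-form II transposed state equations at equilibrium,
#' so filtering a constant series reproduces it exactly when the state is
#' scaled by the first sample.
#' @noRd
iir_steady_state <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n < 2) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n]
  if (n > 2) A[2:(n - 1), 1:(n - 2)] <- diag(n - 2)
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Direct-form IIR filter with steady-state initial conditions
#' @noRd
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]
  a <- a / a[1]
  if (is.null(zi)) zi <- iir_steady_state(b, a)
  iir_filter_cpp(b, a, x, zi * x[1])
}

#' Zero-phase (forward-backward) IIR filtering
#' @noRd
filtfilt_fast <- function(bf, x) {
  b <- bf$b / bf$a[1]
  a <- bf$a / bf$a[1]
  zi <- iir_steady_state(b, a)
  y <- iir_filter_cpp(b, a, x, zi * x[1])
  y <- rev(y)
  rev(iir_filter_cpp(b, a, y, zi * y[1]))
}

#' Zero-phase filtering with reflection edge padding
#'
#' Extends the series at both ends over `padlen` samples before
#' forward-backward filtering, which suppresses edge transients.
#' `type = "odd"` reflects point-symmetrically about the end values
#' (preserves trends but pins the filtered output to the raw end values,
#' so end samples escape smoothing); `type = "even"` mirrors the series
#' (end values get genuinely smoothed at the cost of flattening the
#' local slope).
#' @noRd
filtfilt_padded <- function(bf, x, padlen, type = c("odd", "even")) {
  type <- match.arg(type)
  n <- length(x)
  padlen <- min(n - 1, padlen)
  front <- x[(padlen + 1):2]
  back <- x[(n - 1):(n - padlen)]
  if (type == "odd") {
    front <- 2 * x[1] - front
    back <- 2 * x[n] - back
  }
  y <- filtfilt_fast(bf, c(front, x, back))
  y[(padlen + 1):(padlen + n)]
}
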