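#' Analytic signal via the FFT
#'
#' Computes the analytic (complex-valued) signal of a real vector by zeroing
#' the negative-frequency half of its discrete Fourier transform. The modulus
#' of the result is the instantaneous amplitude (Hilbert envelope); the
#' argument is the instantaneous phase.
#'
#' @param x numeric vector, finite.
#' @return complex vector of the same length as \code{x}.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("analytic_signal: input must be finite numeric")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Sample indices covering the closed-open time window [a, b) seconds.
# Sample i (1-based) sits at time (i - 1) / fs.
time_window_idx <- function(a, b, fs, n) {
  i1 <- floor(a * fs + 1e-9) + 1L
  i2 <- ceiling(b * fs - 1e-9)
  if (i1 < 1L || i2 > n || i2 < i1) return(integer(0))
  seq.int(i1, i2)
}

# Seed derived deterministically from a base seed; kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase filtering with odd-reflection padding at both ends, so edge
# transients from the filter's settling time do not leak into the output.
filtfilt_pad <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  if (pad < 1L) return(signal::filtfilt(bf, x))
  head_ref <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(head_ref, x, tail_ref))
  y[(pad + 1L):(pad + n)]
}
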