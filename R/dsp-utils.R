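# Small shared DSP primitives used across the feature families.

#' Teager-Kaiser energy operator
#'
#' `psi[n] = x[n]^2 - x[n-1] * x[n+1]`, a nonlinear instantaneous-energy
#' estimate. Returns a vector of length `length(x) - 2`.
#'
#' @param x Numeric vector.
#' @return TKEO sequence.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

# Frame a signal into a matrix (one column per frame); hop and length in samples.
frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  if (n < frame_len) return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len))
}

# Shannon entropy (nats) of a probability vector; zero bins contribute 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) + 0   # + 0 normalizes the signed zero of a point mass
}

# Normalized squared-coefficient entropy of a signal (its "spectral" entropy
# when applied to transform coefficients).
coef_entropy <- function(x) {
  e <- x^2
  s <- sum(e)
  if (s <= 0) return(0)
  shannon_entropy(e / s)
}

# Analytic-signal envelope via FFT (Hilbert). Returns |analytic(x)|.
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Linear-prediction coefficients by the autocorrelation (Levinson via solve)
# method. Returns a = c(1, -a1, ..., -ap) such that filtering x with `a`
# yields the LP residual.
lpc_coeffs <- function(x, order) {
  n <- length(x)
  if (n <= order + 1) stop("signal too short for LPC order ", order)
  r <- stats::acf(x, lag.max = order, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  R <- stats::toeplitz(r[1:order])
  if (abs(det(R)) < 1e-300 || r[1] <= 0) stop("degenerate signal for LPC")
  a <- solve(R, r[2:(order + 1)])
  c(1, -a)
}

# Zero-phase Butterworth band filter; `type` as in signal::butter.
# Uses filtfilt so the pass does not shift cycle marks.
butter_zerophase <- function(x, fs, cutoff, type, order = 3) {
  w <- cutoff / (fs / 2)
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  bf <- signal::butter(order, w, type = type)
  signal::filtfilt(bf, x)
}

# Band energy of a signal between lo and hi Hz via the periodogram.
band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  half <- f <= fs / 2
  sum(Mod(X[half & f >= lo & f < hi])^2)
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))
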