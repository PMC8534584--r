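# Fundamental-frequency contour on a 10 ms grid using a sawtooth-inspired
# spectral-matching estimator, and cycle-level period/amplitude extraction.

erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)

is_prime <- function(n) {
  vapply(n, function(k) {
    if (k < 2) return(FALSE)
    if (k < 4) return(TRUE)
    if (k %% 2 == 0) return(FALSE)
    lim <- floor(sqrt(k))
    if (lim < 3) return(TRUE)
    all(k %% seq(3, lim, by = 2) != 0)
  }, logical(1))
}

# Kernel matrix: one column per pitch candidate, rows on the ERB-spaced
# frequency grid. A positive cosine lobe at each prime harmonic (plus the
# fundamental) with the adjacent negative cosine regions retained, so
# energy falling between a candidate's harmonics (e.g. the odd harmonics
# of the true pitch for an octave-up candidate) is penalized. Weights
# 1/sqrt(h) match the square-root magnitude spectrum of a sawtooth
# source. Columns are unit-normalized.
swipe_kernel <- function(freqs, candidates, nyquist) {
  K <- matrix(0, length(freqs), length(candidates))
  for (j in seq_along(candidates)) {
    fc <- candidates[j]
    eta <- freqs / fc
    h <- round(eta)
    ok <- h >= 1 & h * fc < nyquist
    hp <- h[ok]
    keep <- hp == 1 | is_prime(hp)
    idx <- which(ok)[keep]
    hv <- hp[keep]
    K[idx, j] <- cos(2 * pi * (eta[idx] - hv)) / sqrt(hv)
  }
  nrm <- sqrt(colSums(K^2))
  nrm[nrm == 0] <- 1
  sweep(K, 2, nrm, "/")
}

# Voicing strength of one frame: harmonic contrast at the localized pitch.
# A second analysis pass with a window of 8 periods of the frame's
# estimate and only the first 3 harmonics: the spectral energy under the
# positive cosine lobes at the harmonics minus the energy in the
# inter-harmonic valleys, over their sum. Near 1 for periodic voice,
# ~0 for broadband noise; restricting to low harmonics keeps the score
# stable for heavily jittered (yet voiced) phonations, whose upper
# harmonics smear first.
harmonic_contrast <- function(x, fs, t, f_hat, n_periods = 8, h_max = 3) {
  n <- length(x)
  wl <- min(round(n_periods / f_hat * fs), n)
  s0 <- min(max(round(t * fs) + 1 - round(wl / 2), 1), n - wl + 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))
  nfft <- 2^ceiling(log2(wl) + 2)
  mag <- sqrt(Mod(stats::fft(c(x[s0:(s0 + wl - 1)] * w,
                               numeric(nfft - wl)))[1:(nfft / 2 + 1)]))
  f <- (0:(nfft / 2)) * fs / nfft
  keep <- f >= 0.5 * f_hat & f <= min((h_max + 0.5) * f_hat, fs / 2)
  eta <- f[keep] / f_hat
  h <- round(eta)
  val <- cos(2 * pi * (eta - h)) / sqrt(pmax(h, 1))
  a <- sum(pmax(val, 0) * mag[keep])
  b <- sum(pmax(-val, 0) * mag[keep])
  if (a + b < 1e-12) return(0)
  (a - b) / (a + b)
}

#' Estimate the F0 contour of a phonation every 10 ms
#'
#' A sawtooth-inspired spectral-matching estimator: per 10 ms frame, the
#' square-root magnitude spectrum is interpolated onto an ERB-spaced
#' frequency grid and matched (normalized inner product) against kernels
#' with positive cosine lobes at each pitch candidate's prime harmonics.
#' Candidates are log-spaced at 1/96 octave between `f_min` and `f_max`;
#' the best candidate is refined parabolically on the log-frequency grid.
#' Pitch strength is the harmonic contrast of the winning candidate
#' (computed in a second, pitch-matched analysis pass over the first three
#' harmonics): the spectral energy under the positive kernel lobes minus
#' the energy in the inter-harmonic valleys, over their sum — near 1 for
#' periodic voice, near 0 for broadband noise; frames below
#' `voicing_threshold` are marked unvoiced (`NA` in `f0`). Analysis windows near the signal edges are
#' shifted inward so the full 10 ms grid is covered.
#'
#' @param p A [phonation()] (8 kHz telephone-band material or higher rates).
#' @param f_min,f_max Pitch search bounds in Hz.
#' @param voicing_threshold Pitch-strength threshold below which a frame is
#'   unvoiced (default 0.2: broadband noise scores ~0.1 on the harmonic
#'   contrast scale, clean voice >= 0.5, severely jittered voice ~ 0.3).
#' @return An object of class `f0_contour`: list with `times` (s, 10 ms
#'   grid), `f0` (Hz, `NA` when unvoiced), `strength` (in \[0, 1\]).
#' @export
estimate_f0_contour <- function(p, f_min = 50, f_max = 500,
                                voicing_threshold = 0.2) {
  stopifnot(inherits(p, "phonation"))
  if (f_min >= f_max) stop("f_min must be below f_max")
  fs <- p$fs
  x <- p$samples
  n <- length(x)

  win_len <- min(round(4 / f_min * fs), n)
  hop <- round(0.010 * fs)
  times <- seq(0, (n - 1) / fs, by = 0.010)
  times <- times[times <= (n - win_len) / fs + (win_len - 1) / fs]  # all grid points
  nfft <- 2^ceiling(log2(win_len) + 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))  # Hann

  freqs_fft <- (0:(nfft / 2)) * fs / nfft
  grid_e <- seq(erb_number(f_min / 2), erb_number(fs / 2), by = 0.05)
  grid_f <- (10^(grid_e / 21.4) - 1) / 0.00437
  cand <- f_min * 2^(seq(0, log2(f_max / f_min), by = 1 / 96))
  K <- swipe_kernel(grid_f, cand, fs / 2)

  n_frames <- length(times)
  S <- matrix(0, length(grid_f), n_frames)
  for (k in seq_len(n_frames)) {
    s0 <- round(times[k] * fs) + 1 - round(win_len / 2)
    s0 <- min(max(s0, 1), n - win_len + 1)     # shift window inside edges
    seg <- x[s0:(s0 + win_len - 1)] * w
    mag <- sqrt(Mod(stats::fft(c(seg, numeric(nfft - win_len)))[1:(nfft / 2 + 1)]))
    S[, k] <- stats::approx(freqs_fft, mag, xout = grid_f, rule = 2)$y
  }
  nrm <- sqrt(colSums(S^2))
  match_mat <- sweep(crossprod(K, S), 2, pmax(nrm, 1e-12), "/")

  f0 <- rep(NA_real_, n_frames)
  strength <- numeric(n_frames)
  lc <- log2(cand)
  for (k in seq_len(n_frames)) {
    if (nrm[k] < 1e-9) next                       # silent frame
    sc <- match_mat[, k]
    i <- which.max(sc)
    f_hat <- cand[i]
    if (i > 1 && i < length(cand)) {              # parabolic refinement
      y1 <- sc[i - 1]; y2 <- sc[i]; y3 <- sc[i + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) {
        d <- 0.5 * (y1 - y3) / den
        d <- max(min(d, 0.5), -0.5)
        f_hat <- 2^(lc[i] + d * (lc[2] - lc[1]))
      }
    }
    strength[k] <- harmonic_contrast(x, fs, times[k], f_hat)
    f0[k] <- f_hat
  }

  # temporal-continuity pass: sustained phonations have one slowly varying
  # F0, but with a missing fundamental (telephone highpass) a formant-
  # supported wrong candidate can win individual frames. Frames deviating
  # more than 25% from the contour median are re-localized among
  # candidates within +/-25% of the median.
  # reference pitch from the highest-contrast frames (wrong candidates
  # score systematically lower contrast than the true pitch)
  hi <- !is.na(f0) & strength >= stats::quantile(strength, 0.6, na.rm = TRUE)
  f0_ref <- stats::median(f0[hi])
  if (is.finite(f0_ref)) {
    near <- which(cand >= 0.75 * f0_ref & cand <= 1.25 * f0_ref)
    outlier <- which(!is.na(f0) & abs(f0 - f0_ref) / f0_ref > 0.25)
    for (k in outlier) {
      sc <- match_mat[near, k]
      i <- near[which.max(sc)]
      f_hat <- cand[i]
      if (i > 1 && i < length(cand)) {
        y1 <- match_mat[i - 1, k]; y2 <- match_mat[i, k]
        y3 <- match_mat[i + 1, k]
        den <- y1 - 2 * y2 + y3
        if (den < 0) {
          d <- max(min(0.5 * (y1 - y3) / den, 0.5), -0.5)
          f_hat <- 2^(lc[i] + d * (lc[2] - lc[1]))
        }
      }
      f0[k] <- f_hat
      strength[k] <- harmonic_contrast(x, fs, times[k], f_hat)
    }
  }
  f0[strength < voicing_threshold] <- NA_real_
  structure(list(times = times, f0 = f0, strength = strength,
                 voicing_threshold = voicing_threshold),
            class = "f0_contour")
}

#' @export
print.f0_contour <- function(x, ...) {
  v <- sum(!is.na(x$f0))
  cat(sprintf("<f0_contour> %d frames (10 ms grid), %d voiced, median F0 %.1f Hz\n",
              length(x$times), v, stats::median(x$f0, na.rm = TRUE)))
  invisible(x)
}

#' Extract glottal cycle marks, periods, and peak amplitudes
#'
#' Cycle marks are located by picking one dominant waveform extremum per
#' expected period: starting from the first voiced frame, the next mark is
#' the largest (polarity-normalized) peak in a search window 0.7-1.3 times
#' the current period ahead, with parabolic sub-sample refinement of the
#' peak position. Cycle `i`'s amplitude is the absolute waveform extremum
#' between marks `i` and `i + 1`.
#'
#' @param p A [phonation()].
#' @param f0 Its [estimate_f0_contour()] contour (>= 3 voiced frames).
#' @return An object of class `cycle_sequence`: `marks` (s), `periods` (s,
#'   one fewer than marks), `amplitudes` (one per period).
#' @export
extract_cycles <- function(p, f0) {
  stopifnot(inherits(p, "phonation"), inherits(f0, "f0_contour"))
  voiced <- which(!is.na(f0$f0))
  if (length(voiced) < 3) stop("fewer than 3 voiced frames")
  fs <- p$fs
  x <- p$samples
  s <- if (max(x) >= max(-x)) x else -x          # polarity normalization
  n <- length(s)

  f0_med <- stats::median(f0$f0[voiced])
  t_start <- f0$times[voiced[1]]
  T_cur <- 1 / f0_med

  refine <- function(i) {                         # parabolic peak refinement
    if (i <= 1 || i >= n) return(0)
    y1 <- s[i - 1]; y2 <- s[i]; y3 <- s[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den >= 0) return(0)
    max(min(0.5 * (y1 - y3) / den, 0.5), -0.5)
  }

  i0 <- max(round(t_start * fs) + 1, 1)
  i1 <- min(i0 + round(1.5 * T_cur * fs), n)
  if (i1 <= i0) stop("fewer than 3 cycles found")
  i_pk <- i0 + which.max(s[i0:i1]) - 1
  marks <- (i_pk - 1 + refine(i_pk)) / fs
  t_end <- f0$times[voiced[length(voiced)]] + 0.01

  repeat {
    m <- marks[length(marks)]
    # track a running median of accepted periods (seeded from the contour
    # median), bounded so contour octave glitches cannot shrink the search
    np <- length(marks)
    if (np > 1) {
      recent <- diff(marks)[max(1, np - 5):(np - 1)]
      T_cur <- min(max(stats::median(recent), 0.7 / f0_med), 1.4 / f0_med)
    }
    lo <- round((m + 0.7 * T_cur) * fs) + 1
    hi <- round((m + 1.3 * T_cur) * fs) + 1
    # stop short of the signal edge, where zero-phase filter transients
    # distort the waveform peaks
    if (hi > n - round(0.015 * fs) || m + T_cur > t_end) break
    lo <- max(lo, 1)
    i_pk <- lo + which.max(s[lo:hi]) - 1
    marks <- c(marks, (i_pk - 1 + refine(i_pk)) / fs)
  }
  if (length(marks) < 4) stop("fewer than 3 cycles found")

  periods <- diff(marks)
  amplitudes <- vapply(seq_len(length(marks) - 1), function(i) {
    a <- max(round(marks[i] * fs) + 1, 1)
    b <- min(round(marks[i + 1] * fs), n)
    max(abs(x[a:b]))
  }, numeric(1))
  structure(list(marks = marks, periods = periods, amplitudes = amplitudes),
            class = "cycle_sequence")
}

#' @export
print.cycle_sequence <- function(x, ...) {
  cat(sprintf("<cycle_sequence> %d cycles, mean period %.4f s\n",
              length(x$periods), mean(x$periods)))
  invisible(x)
}
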