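# Noise-related families: autocorrelation HNR/NHR, glottal-to-noise
# excitation (GNE), vocal fold excitation ratios (VFER), and EMD-based
# excitation ratios.

hnr_names <- function() paste0("hnr.", c("hnr_mean", "hnr_sd",
                                         "nhr_mean", "nhr_sd"))

#' HNR/NHR family: 4 autocorrelation-based measures
#'
#' Per 50 ms frame (10 ms hop), `r` is the maximum normalized
#' autocorrelation in a lag window 0.7-1.3 times the frame period (from the
#' F0 contour; the full 50-500 Hz lag range when the frame is unvoiced).
#' HNR = 10 log10(r / (1 - r)) dB and NHR = (1 - r) / r, reported as mean
#' and SD over frames. `r` is clamped to (1e-12, 1 - 1e-12).
#'
#' @param segment A [phonation()] analysis segment.
#' @param f0 Its [estimate_f0_contour()] contour.
#' @return Named numeric vector of length 4.
#' @export
hnr_nhr <- function(segment, f0) {
  fs <- segment$fs
  frame_len <- round(0.050 * fs)
  hop <- round(0.010 * fs)
  fr <- frame_signal(segment$samples, frame_len, hop)
  if (ncol(fr) < 2) flag_family("hnr", "segment too short")
  med_f0 <- stats::median(f0$f0, na.rm = TRUE)

  r_of <- function(col_idx) {
    x <- fr[, col_idx]
    if (sum(x^2) < 1e-12) return(NA_real_)
    t_fr <- (col_idx - 1) * 0.010 + 0.025
    k <- which.min(abs(f0$times - t_fr))
    f0_fr <- f0$f0[k]
    if (is.na(f0_fr)) f0_fr <- med_f0
    lags <- if (is.na(f0_fr)) round(fs / 500):round(fs / 50)
            else round(0.7 * fs / f0_fr):round(1.3 * fs / f0_fr)
    lags <- lags[lags >= 1 & lags < length(x)]
    if (length(lags) == 0) return(NA_real_)
    n <- length(x)
    r_at <- function(l) {
      a <- x[1:(n - l)]; b <- x[(l + 1):n]
      den <- sqrt(sum(a^2) * sum(b^2))
      if (den < 1e-300) 0 else sum(a * b) / den
    }
    rv <- vapply(lags, r_at, numeric(1))
    i <- which.max(rv)
    rmax <- rv[i]
    # parabolic refinement: the true period is rarely an integer number of
    # samples, and the lattice maximum understates r for bright spectra
    l <- lags[i]
    y1 <- if (i > 1) rv[i - 1] else if (l > 1) r_at(l - 1) else NA
    y3 <- if (i < length(rv)) rv[i + 1] else if (l + 1 < n) r_at(l + 1) else NA
    if (is.finite(y1) && is.finite(y3)) {
      den <- y1 - 2 * rmax + y3
      if (den < 0) rmax <- rmax - (y1 - y3)^2 / (8 * den)
    }
    min(max(rmax, 1e-12), 1 - 1e-12)
  }
  r <- vapply(seq_len(ncol(fr)), r_of, numeric(1))
  r <- r[!is.na(r)]
  if (length(r) < 2) flag_family("hnr", "no usable frames")
  hnr <- 10 * log10(r / (1 - r))
  nhr <- (1 - r) / r
  stats::setNames(c(mean(hnr), stats::sd(hnr), mean(nhr), stats::sd(nhr)),
                  hnr_names())
}

gne_names <- function() paste0("gne.", c("gne_mean", "gne_sd",
                                         "snr_e_mean", "snr_e_sd",
                                         "snr_tkeo_mean", "snr_tkeo_sd"))

# FFT band-pass and Hilbert envelope of one frame.
band_envelope <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)
  X[!(f_fold >= lo & f_fold <= hi)] <- 0
  hilbert_envelope(Re(stats::fft(X, inverse = TRUE) / n))
}

#' GNE family: 6 glottal-to-noise excitation measures
#'
#' Per 50 ms frame (25 ms hop): the frame is inverse-filtered with a
#' 13th-order linear predictor; Hilbert envelopes of the residual are
#' computed in overlapping 1000 Hz bands (centers every 500 Hz, adapted to
#' the 8 kHz telephone rate, so up to 3.5 kHz); GNE is the maximum
#' correlation — over band pairs at least 1500 Hz apart and small
#' inter-band lags (up to 0.4 ms, absorbing dispersion of the excitation
#' across bands) — between the band envelopes.
#' Energy-based SNR = 10 log10(GNE^2 / (1 - GNE^2)); the TKEO-based SNR
#' uses the same formula with correlations of the TKEO-processed
#' envelopes. All three are reported as mean and SD over frames.
#'
#' @param segment A [phonation()] analysis segment (8 kHz material).
#' @return Named numeric vector of length 6.
#' @export
gne_family <- function(segment) {
  fs <- segment$fs
  frame_len <- round(0.050 * fs)
  hop <- round(0.025 * fs)
  fr <- frame_signal(segment$samples, frame_len, hop)
  if (ncol(fr) < 2) flag_family("gne", "segment too short")
  centers <- seq(500, fs / 2 - 500, by = 500)
  half_bw <- 500
  far <- abs(outer(centers, centers, "-")) >= 1500
  max_lag <- round(0.0004 * fs)

  lag_cor_max <- function(a, b) {
    n <- length(a)
    best <- -1
    for (l in -max_lag:max_lag) {
      r <- if (l >= 0) stats::cor(a[1:(n - l)], b[(1 + l):n])
           else stats::cor(a[(1 - l):n], b[1:(n + l)])
      if (!is.na(r) && r > best) best <- r
    }
    best
  }
  max_far_cor <- function(env) {
    best <- -1
    nb <- ncol(env)
    for (i in 1:(nb - 1)) for (j in (i + 1):nb) if (far[i, j])
      best <- max(best, lag_cor_max(env[, i], env[, j]))
    best
  }
  one_frame <- function(x) {
    if (sum(x^2) < 1e-12) return(c(NA, NA))
    a <- try(lpc_coeffs(x, 13), silent = TRUE)
    if (inherits(a, "try-error")) return(c(NA, NA))
    resid <- as.numeric(stats::filter(x, a, method = "convolution",
                                      sides = 1))
    resid[is.na(resid)] <- 0
    env <- vapply(centers, function(fc)
      band_envelope(resid, fs, fc - half_bw, fc + half_bw),
      numeric(length(resid)))
    tk <- apply(env, 2, function(e) tkeo(e))
    c(max_far_cor(env), max_far_cor(tk))
  }
  cors <- vapply(seq_len(ncol(fr)), function(i) one_frame(fr[, i]),
                 numeric(2))
  gne <- cors[1, ]; gne <- gne[!is.na(gne)]
  gnt <- cors[2, ]; gnt <- gnt[!is.na(gnt)]
  if (length(gne) < 2) flag_family("gne", "LPC failed on all frames")
  clamp <- function(r) min(max(r, 1e-6), 1 - 1e-6)
  snr_e <- vapply(gne, function(r) {
    r <- clamp(r); 10 * log10(r^2 / (1 - r^2))
  }, numeric(1))
  snr_t <- vapply(gnt, function(r) {
    r <- clamp(r); 10 * log10(r^2 / (1 - r^2))
  }, numeric(1))
  stats::setNames(c(mean(gne), stats::sd(gne), mean(snr_e), stats::sd(snr_e),
                    mean(snr_t), stats::sd(snr_t)), gne_names())
}

vfer_names <- function() paste0("vfer.", c("energy_mean", "energy_sd",
                                           "tkeo_mean", "tkeo_sd",
                                           "entropy_mean", "entropy_sd",
                                           "energy_seg", "tkeo_seg",
                                           "entropy_seg"))

#' VFER family: 9 vocal fold excitation ratio measures
#'
#' The spectrum is split at 2.5 kHz: the "signal" band below, the "noise"
#' band above (bounded by the 4 kHz Nyquist limit of telephone material).
#' Per 25 ms frame (10 ms hop): band-energy ratio, TKEO-energy ratio of the
#' band-filtered signals, and Shannon-entropy ratio of the normalized
#' squared spectra within each band — mean and SD over frames (silent
#' frames skipped), plus whole-segment aggregates of the three ratios.
#'
#' @param segment A [phonation()] analysis segment.
#' @return Named numeric vector of length 9.
#' @export
vfer_family <- function(segment) {
  fs <- segment$fs
  split_hz <- 2500
  ratios <- function(x) {
    if (sum(x^2) < 1e-12) return(c(NA, NA, NA))
    n <- length(x)
    X <- stats::fft(x)[1:(floor(n / 2) + 1)]
    f <- (0:floor(n / 2)) * fs / n
    lo <- Mod(X[f < split_hz])^2
    hi <- Mod(X[f >= split_hz])^2
    xlo <- band_pass_fft(x, fs, 0, split_hz)
    xhi <- band_pass_fft(x, fs, split_hz, fs / 2)
    tk_lo <- sum(abs(tkeo(xlo))); tk_hi <- sum(abs(tkeo(xhi)))
    e_hi <- max(sum(hi), 1e-300)
    ent_lo <- shannon_entropy(lo / max(sum(lo), 1e-300))
    ent_hi <- shannon_entropy(hi / e_hi)
    c(sum(lo) / e_hi, tk_lo / max(tk_hi, 1e-300),
      ent_lo / max(ent_hi, 1e-300))
  }
  frame_len <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  fr <- frame_signal(segment$samples, frame_len, hop)
  if (ncol(fr) < 2) flag_family("vfer", "segment too short")
  per_frame <- vapply(seq_len(ncol(fr)), function(i) ratios(fr[, i]),
                      numeric(3))
  keep <- !is.na(per_frame[1, ])
  if (sum(keep) < 2) flag_family("vfer", "all frames silent")
  pf <- per_frame[, keep, drop = FALSE]
  seg <- ratios(segment$samples)
  stats::setNames(c(mean(pf[1, ]), stats::sd(pf[1, ]),
                    mean(pf[2, ]), stats::sd(pf[2, ]),
                    mean(pf[3, ]), stats::sd(pf[3, ]),
                    seg), vfer_names())
}

# FFT brick-wall band-pass (time-domain output).
band_pass_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)
  X[!(f_fold >= lo & f_fold < hi)] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

emd_er_names <- function() paste0("emd.", c("er_raw", "er_db",
                                            "tkeo_raw", "tkeo_db",
                                            "entropy_raw", "entropy_db"))

#' EMD excitation ratio family: 6 measures
#'
#' The segment is decomposed by empirical mode decomposition
#' ([emd_decompose()], SD stopping criterion 0.2). The first two IMFs
#' (highest-frequency content) form the "noise" part; the remainder is the
#' "signal" part. Reported: energy ratio, TKEO-energy ratio (sum of
#' absolute TKEO), and Shannon-entropy ratio (normalized squared samples),
#' each raw and in dB.
#'
#' @param segment A [phonation()] analysis segment of at least 1 s.
#' @return Named numeric vector of length 6.
#' @export
emd_er_family <- function(segment) {
  if (duration(segment) < 1) flag_family("emd", "segment shorter than 1 s")
  dec <- emd_decompose(segment$samples)
  if (length(dec$imfs) < 3)
    flag_family("emd", "decomposition yielded fewer than 3 IMFs")
  noise <- dec$imfs[[1]] + dec$imfs[[2]]
  signal_part <- segment$samples - noise
  er <- sum(signal_part^2) / max(sum(noise^2), 1e-300)
  tr <- sum(abs(tkeo(signal_part))) / max(sum(abs(tkeo(noise))), 1e-300)
  hr <- coef_entropy(signal_part) / max(coef_entropy(noise), 1e-300)
  v <- c(er, 10 * log10(er), tr, 10 * log10(tr), hr, 10 * log10(hr))
  stats::setNames(v, emd_er_names())
}
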