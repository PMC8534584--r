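# Spectral-envelope and contour families: MFCCs, normative F0 comparisons,
# and wavelet statistics of the F0 contour.

mfcc_names <- function() {
  c(sprintf("mfcc.c%02d", 0:12),
    sprintf("mfcc.d%02d", 0:12),
    sprintf("mfcc.dd%02d", 0:12))
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, nfft, fs, f_lo = 0, f_hi = fs / 2) {
  mels <- seq(hz_to_mel(f_lo), hz_to_mel(f_hi), length.out = n_filters + 2)
  edges <- mel_to_hz(mels)
  bins <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, n_filters, nfft / 2 + 1)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ce <- edges[i + 1]; hi <- edges[i + 2]
    up <- bins >= lo & bins <= ce
    dn <- bins > ce & bins <= hi
    fb[i, up] <- (bins[up] - lo) / max(ce - lo, 1e-12)
    fb[i, dn] <- (hi - bins[dn]) / max(hi - ce, 1e-12)
  }
  fb
}

# Orthonormal DCT-II basis (n_out x n_in); row 0 is constant, so gain
# changes move only c0.
dct_basis <- function(n_out, n_in) {
  k <- 0:(n_out - 1)
  m <- 0:(n_in - 1)
  B <- sqrt(2 / n_in) * cos(pi * outer(k, m + 0.5) / n_in)
  B[1, ] <- B[1, ] / sqrt(2)
  B
}

#' MFCC family: 39 mel-cepstral measures
#'
#' 25 ms Hamming frames with 10 ms hop; 26 triangular mel filters over
#' 0-4000 Hz; log filter energies -> orthonormal DCT-II -> coefficients
#' c0..c12; first and second temporal differences (central differences)
#' appended; each of the 39 trajectories averaged over frames.
#'
#' @param segment A [phonation()] analysis segment with >= 10 frames.
#' @return Named numeric vector of length 39.
#' @export
mfcc_family <- function(segment) {
  fs <- segment$fs
  frame_len <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  fr <- frame_signal(segment$samples, frame_len, hop)
  if (ncol(fr) < 10) flag_family("mfcc", "fewer than 10 frames")
  nfft <- 2^ceiling(log2(frame_len))
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(frame_len) - 1) / (frame_len - 1))
  fb <- mel_filterbank(26, nfft, fs, 0, min(4000, fs / 2))
  B <- dct_basis(13, 26)

  pow <- apply(fr * ham, 2, function(x) {
    X <- stats::fft(c(x, numeric(nfft - frame_len)))
    Mod(X[1:(nfft / 2 + 1)])^2
  })
  logmel <- log(pmax(fb %*% pow, 1e-300))
  cc <- B %*% logmel                          # 13 x frames
  delta <- function(M) {
    nf <- ncol(M)
    (M[, c(2:nf, nf), drop = FALSE] - M[, c(1, 1:(nf - 1)), drop = FALSE]) / 2
  }
  d1 <- delta(cc)
  d2 <- delta(d1)
  stats::setNames(c(rowMeans(cc), rowMeans(d1), rowMeans(d2)), mfcc_names())
}

#' Normative log-F0 table for healthy adults
#'
#' Per-gender mean and SD of log-F0 used by the F0-comparison measures.
#' Defaults (male 120 Hz, female 200 Hz, SD 0.15 in natural-log Hz units)
#' are replaceable configuration, not population claims.
#'
#' @param male_mean_hz,female_mean_hz Normative mean F0 per gender in Hz.
#' @param sd_log SD of log-F0 (natural log).
#' @return An object of class `normative_f0_table`.
#' @export
normative_f0_table <- function(male_mean_hz = 120, female_mean_hz = 200,
                               sd_log = 0.15) {
  stopifnot(sd_log > 0)
  structure(list(M = list(mean_log = log(male_mean_hz), sd_log = sd_log),
                 F = list(mean_log = log(female_mean_hz), sd_log = sd_log)),
            class = "normative_f0_table")
}

f0_related_names <- function() paste0("f0.", c("z_mean", "tail_prob", "sd_ratio"))

#' F0-related family: 3 normative-comparison measures
#'
#' (1) z-score of the observed mean log-F0 against the gender's normative
#' log-F0 distribution; (2) the two-sided Gaussian tail probability of that
#' mean; (3) the ratio of the observed log-F0 SD to the normative SD.
#'
#' @param f0 An [estimate_f0_contour()] contour.
#' @param age Age in years (recorded for provenance; the default table is
#'   not age-banded).
#' @param gender `"M"` or `"F"`.
#' @param norms A [normative_f0_table()].
#' @return Named numeric vector of length 3.
#' @export
f0_related_family <- function(f0, age, gender, norms = normative_f0_table()) {
  if (is.null(gender) || !gender %in% c("M", "F"))
    flag_family("f0_related", "missing or unknown gender")
  if (is.null(age) || is.na(age))
    flag_family("f0_related", "missing age")
  lf <- log(f0$f0[!is.na(f0$f0)])
  if (length(lf) < 10) flag_family("f0_related", "too few voiced frames")
  nm <- norms[[gender]]
  z <- (mean(lf) - nm$mean_log) / nm$sd_log
  stats::setNames(c(z, 2 * (1 - stats::pnorm(abs(z))),
                    stats::sd(lf) / nm$sd_log),
                  f0_related_names())
}

wavelet_names <- function() {
  bands <- c(paste0("d", 1:10), "a")
  per_band <- c("logE", "entropy", "logEent", "tkeo_mean", "tkeo_sd",
                "maxabs", "iqr", "sd")
  one_input <- c(as.vector(t(outer(bands, per_band, paste, sep = "_"))),
                 c("total_logE", "band_entropy", "detail_approx_ratio"))
  paste0("wav.", c(paste0("f0_", one_input), paste0("logf0_", one_input)))
}

wavelet_band_stats <- function(coefs) {
  e <- sum(coefs^2)
  tk <- tkeo(coefs)
  if (length(tk) < 2) tk <- c(0, 0)
  c(log(e + 1e-300),
    coef_entropy(coefs),
    sum(log(coefs^2 + 1e-300)),
    mean(tk), stats::sd(tk),
    max(abs(coefs)),
    stats::IQR(coefs))
}

wavelet_input_stats <- function(x) {
  n <- 1024L                      # pad so 10 decomposition levels exist
  if (length(x) > n) x <- x[seq_len(n)]
  xp <- c(x, numeric(n - length(x)))
  dec <- dwt_db8(xp, levels = 10)
  band_e <- vapply(dec, function(c) sum(c^2), numeric(1))
  per_band <- unlist(lapply(dec, function(c)
    c(wavelet_band_stats(c),
      if (length(c) > 1) stats::sd(c) else 0)), use.names = FALSE)
  tot <- sum(band_e)
  p <- band_e / max(tot, 1e-300)
  global <- c(log(tot + 1e-300),
              shannon_entropy(p[p > 0]),
              log((sum(band_e[1:10]) + 1e-300) / (band_e[11] + 1e-300)))
  c(per_band, global)
}

#' Wavelet family: 182 F0-contour fluctuation measures
#'
#' The voiced F0 contour and its natural log are each linearly detrended,
#' zero-padded to 1024 samples, and decomposed with a 10-level periodized
#' db8 wavelet transform ([dwt_db8()]). Per band (10 detail + 1
#' approximation) and per input: log total energy, Shannon entropy of the
#' normalized squared coefficients, log-energy entropy, TKEO mean and SD,
#' maximum absolute coefficient, interquartile range, and coefficient SD
#' (8 statistics x 11 bands = 88); plus per input the log total energy
#' across bands, the entropy of the band-energy distribution, and the
#' log detail-to-approximation energy ratio (3). Totals 2 x 91 = 182.
#'
#' @param f0 An [estimate_f0_contour()] contour with >= 128 voiced frames.
#' @return Named numeric vector of length 182.
#' @export
wavelet_family <- function(f0) {
  v <- f0$f0[!is.na(f0$f0)]
  if (length(v) < 128) flag_family("wavelet", "fewer than 128 voiced frames")
  detrend <- function(x) stats::resid(stats::lm(x ~ seq_along(x)))
  out <- c(wavelet_input_stats(detrend(v)),
           wavelet_input_stats(detrend(log(v))))
  stats::setNames(out, wavelet_names())
}
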