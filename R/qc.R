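# Automated quality screening and most-stationary 2 s segment selection.

#' Default quality-screening thresholds
#'
#' All screening rules are reconstructions with configuration-exposed
#' defaults: minimum duration 2.5 s, voiced fraction >= 0.6, clipping
#' fraction <= 0.01, SNR estimate >= 10 dB.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(min_duration = 2.5, min_voiced_fraction = 0.6,
       max_clipping_fraction = 0.01, min_snr_db = 10)
}

#' Screen a phonation for automated quality exclusion
#'
#' Deterministic pass/fail with all failing reasons listed. Checks recording
#' duration, voiced fraction (share of 10 ms frames with pitch strength at
#' or above the voicing threshold), clipping fraction (share of samples at
#' or beyond 0.99 full scale), and a crude high-band SNR estimate: power
#' above 3 kHz is taken as a white-noise floor, extrapolated across the
#' band, and compared with the remaining signal power.
#'
#' @param p A [phonation()].
#' @param thresholds Threshold list as from [qc_thresholds()].
#' @param f0 Optional precomputed [estimate_f0_contour()] contour (computed
#'   internally when missing).
#' @return An object of class `qc_report`: `passed`, `reasons` (subset of
#'   `too_short`, `unvoiced`, `clipped`, `low_snr`), `voiced_fraction`,
#'   `clipping_fraction`, `snr_estimate` (dB), `duration` (s).
#' @export
screen_quality <- function(p, thresholds = qc_thresholds(), f0 = NULL) {
  stopifnot(inherits(p, "phonation"))
  reasons <- character(0)
  dur <- duration(p)
  if (dur < thresholds$min_duration) reasons <- c(reasons, "too_short")

  if (is.null(f0) && dur >= 0.1) f0 <- estimate_f0_contour(p)
  voiced_fraction <- if (is.null(f0)) 0 else mean(!is.na(f0$f0))
  if (voiced_fraction < thresholds$min_voiced_fraction)
    reasons <- c(reasons, "unvoiced")

  clipping_fraction <- mean(abs(p$samples) >= 0.99)
  if (clipping_fraction > thresholds$max_clipping_fraction)
    reasons <- c(reasons, "clipped")

  p_total <- mean(p$samples^2)
  p_high <- mean(butter_zerophase(p$samples, p$fs, 3000, "high", order = 3)^2)
  noise_total <- p_high * (p$fs / 2) / (p$fs / 2 - 3000)
  snr_estimate <- 10 * log10(max(p_total - noise_total, 1e-12) /
                               max(noise_total, 1e-12))
  if (snr_estimate < thresholds$min_snr_db) reasons <- c(reasons, "low_snr")

  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 voiced_fraction = voiced_fraction,
                 clipping_fraction = clipping_fraction,
                 snr_estimate = snr_estimate, duration = dur),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s%s (voiced %.2f, clipped %.4f, SNR %.1f dB)\n",
              if (x$passed) "PASSED" else "FAILED",
              if (x$passed) "" else paste0(" [", paste(x$reasons, collapse = ","), "]"),
              x$voiced_fraction, x$clipping_fraction, x$snr_estimate))
  invisible(x)
}

#' Select the most stationary 2 s analysis segment
#'
#' Among all candidate 2 s windows aligned to the 10 ms contour grid with
#' at least `min_voiced` of their 200 frames voiced, returns the window
#' minimizing the standard deviation of F0 over its voiced frames; ties
#' break to the earliest window.
#'
#' @param p A [phonation()] of at least 2 s.
#' @param f0 Its [estimate_f0_contour()] contour.
#' @param min_voiced Minimum voiced fraction for a candidate window
#'   (default 0.75; highly aperiodic voices drop occasional frames below
#'   the voicing threshold without invalidating the segment).
#' @return An object of class `segment_window`: `start`, `end` (s, exactly
#'   2 s apart), `f0_dispersion` (Hz), `frame_idx` (contour frames inside).
#' @export
select_stationary_segment <- function(p, f0, min_voiced = 0.75) {
  stopifnot(inherits(p, "phonation"), inherits(f0, "f0_contour"))
  n_frames <- length(f0$times)
  w <- 200L                     # 200 frames x 10 ms = 2 s
  if (duration(p) < 2 || n_frames < w)
    stop("recording shorter than 2 s of contour frames")
  voiced <- !is.na(f0$f0)
  n_win <- n_frames - w + 1L
  # running mean/SD over the voiced frames of each window
  f0v <- ifelse(voiced, f0$f0, 0)
  cs  <- cumsum(c(0, f0v))
  cs2 <- cumsum(c(0, f0v^2))
  cv  <- cumsum(c(0, as.numeric(voiced)))
  starts <- seq_len(n_win)
  nv <- cv[starts + w] - cv[starts]
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  sd_win <- sqrt(pmax((s2 - s1^2 / pmax(nv, 1)) / pmax(nv - 1, 1), 0))
  sd_win[nv < ceiling(min_voiced * w)] <- Inf
  if (all(!is.finite(sd_win)))
    stop("no fully voiced 2 s window available (recording should have been screened out)")
  best <- which.min(sd_win)     # which.min takes the earliest tie
  structure(list(start = f0$times[best], end = f0$times[best] + 2,
                 f0_dispersion = sd_win[best],
                 frame_idx = best:(best + w - 1L)),
            class = "segment_window")
}

#' Crop a phonation to a time window
#'
#' @param p A [phonation()].
#' @param start,end Window bounds in seconds; samples in `[start, end)`.
#' @return A cropped [phonation()].
#' @export
crop_phonation <- function(p, start, end) {
  a <- max(round(start * p$fs) + 1, 1)
  b <- min(round(end * p$fs), length(p$samples))
  phonation(p$samples[a:b], p$fs, meta = p$meta)
}
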