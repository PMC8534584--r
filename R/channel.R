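#' Specification of a standard-telephone-network channel
#'
#' Generic landline degradation: down-sampling to the telephone rate,
#' band-limiting to the voice passband, PCM quantization, and optional
#' additive channel noise. Codec-specific behaviour (GSM/AMR) is out of
#' scope.
#'
#' @param target_fs Output sampling rate in Hz (default 8000).
#' @param bit_depth Output quantization depth, 8 or 16 bits.
#' @param passband `(low, high)` passband edges in Hz (default 300-3400).
#' @param channel_snr Channel signal-to-noise ratio in dB, or `NULL` for a
#'   noiseless channel.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(target_fs = 8000, bit_depth = 16,
                         passband = c(300, 3400), channel_snr = NULL) {
  stopifnot(bit_depth %in% c(8, 16), length(passband) == 2,
            passband[1] > 0, passband[1] < passband[2])
  if (passband[2] >= target_fs / 2)
    stop("passband infeasible: high edge must be below target Nyquist")
  structure(list(target_fs = target_fs, bit_depth = as.integer(bit_depth),
                 passband = passband, channel_snr = channel_snr),
            class = "channel_spec")
}

#' Pass a phonation through a telephone-channel model
#'
#' Resamples to `target_fs`, band-limits to the passband with a zero-phase
#' Butterworth filter, optionally adds white channel noise at `channel_snr`
#' dB, and quantizes to `bit_depth`. Output duration matches the input
#' within one sample.
#'
#' @param p A [phonation()] with `fs >= 2 * passband high`.
#' @param ch A [channel_spec()].
#' @param noise_seed Seed for the channel-noise stream (used only when
#'   `channel_snr` is set).
#' @return A degraded [phonation()] at `ch$target_fs`.
#' @export
apply_telephone_channel <- function(p, ch = channel_spec(), noise_seed = 1L) {
  stopifnot(inherits(p, "phonation"), inherits(ch, "channel_spec"))
  if (p$fs < 2 * ch$passband[2])
    stop("input sampling rate too low for requested passband")

  x <- p$samples
  n_out <- round(length(x) * ch$target_fs / p$fs)
  if (p$fs != ch$target_fs) {
    g <- gcd_int(round(ch$target_fs), round(p$fs))
    x <- signal::resample(x, round(ch$target_fs) / g, round(p$fs) / g)
    if (length(x) >= n_out) x <- x[seq_len(n_out)]
    else x <- c(x, numeric(n_out - length(x)))
  }

  x <- butter_zerophase(x, ch$target_fs, ch$passband, "pass", order = 3)

  if (!is.null(ch$channel_snr)) {
    x <- with_local_seed(noise_seed, {
      sigma <- rms(x) * 10^(-ch$channel_snr / 20)
      x + stats::rnorm(length(x), sd = sigma)
    })
  }

  full <- 2^(ch$bit_depth - 1)
  x <- pmin(pmax(x, -1), (full - 1) / full)
  x <- round(x * full) / full
  phonation(x, ch$target_fs, meta = c(p$meta, list(channel = ch)))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
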