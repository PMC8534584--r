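#' Specification of a synthetic sustained /a/ phonation
#'
#' Defines the source-filter synthesis parameters for one phonation:
#' a Rosenberg-type glottal pulse train with per-cycle period perturbation
#' (jitter), per-cycle peak-amplitude perturbation (shimmer), additive
#' band-limited aspiration noise, slow sinusoidal F0 tremor, and cascaded
#' formant resonators shaping the vowel /a/.
#'
#' @param duration Phonation length in seconds.
#' @param base_f0 Mean fundamental frequency in Hz (50-500).
#' @param jitter_level Cycle-to-cycle period perturbation, SD relative to the
#'   mean period (dimensionless fraction, >= 0).
#' @param shimmer_level Cycle peak-amplitude perturbation, SD relative to the
#'   mean amplitude (dimensionless fraction, >= 0).
#' @param noise_level Aspiration-noise RMS relative to the voiced-signal RMS
#'   (dimensionless, >= 0).
#' @param tremor_extent Depth of slow sinusoidal F0 modulation in Hz.
#' @param tremor_rate Tremor modulation rate in Hz.
#' @param formants Matrix-like list of `(center Hz, bandwidth Hz)` pairs for
#'   the vowel resonances; defaults to conventional adult /a/ values.
#' @param source_fs Synthesis sampling rate in Hz before any channel
#'   degradation.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   waveform.
#' @return An object of class `phonation_spec`.
#' @export
phonation_spec <- function(duration = 5, base_f0 = 150,
                           jitter_level = 0, shimmer_level = 0,
                           noise_level = 0,
                           tremor_extent = 0, tremor_rate = 5,
                           formants = default_formants(),
                           source_fs = 44100, seed = 1L) {
  stopifnot(duration > 0, base_f0 >= 50, base_f0 <= 500,
            jitter_level >= 0, shimmer_level >= 0, noise_level >= 0,
            tremor_extent >= 0, tremor_rate > 0, source_fs > 0)
  structure(list(duration = duration, base_f0 = base_f0,
                 jitter_level = jitter_level, shimmer_level = shimmer_level,
                 noise_level = noise_level,
                 tremor_extent = tremor_extent, tremor_rate = tremor_rate,
                 formants = formants, source_fs = source_fs,
                 seed = as.integer(seed)),
            class = "phonation_spec")
}

#' Conventional adult /a/ formants
#'
#' Centers (710, 1100, 2540) Hz with bandwidths (80, 90, 120) Hz; these are
#' configuration values, not physiological claims.
#'
#' @return A two-column matrix (center, bandwidth) in Hz.
#' @export
default_formants <- function() {
  cbind(center = c(710, 1100, 2540), bandwidth = c(80, 90, 120))
}

# Rosenberg-type glottal pulse sampled at phase in [0, 1): raised-cosine
# opening over [0, tp), cosine-quarter closing over [tp, tp + tn), zero
# (closed phase) elsewhere.
rosenberg_pulse <- function(phase, tp = 0.40, tn = 0.16) {
  g <- numeric(length(phase))
  op <- phase < tp
  g[op] <- 0.5 * (1 - cos(pi * phase[op] / tp))
  cl <- phase >= tp & phase < tp + tn
  g[cl] <- cos(0.5 * pi * (phase[cl] - tp) / tn)
  g
}

#' Evaluate an expression under a private RNG stream
#'
#' Seeds the generator with `seed`, evaluates `expr`, and restores the
#' caller's RNG state afterwards. All randomness in the package flows
#' through this helper so that cohorts, splits and rankings are
#' reproducible without disturbing the session RNG.
#'
#' @param seed Integer seed (reduced mod 2^31 - 1).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

#' Synthesize a sustained vowel phonation with known ground truth
#'
#' Generates a glottal pulse train cycle by cycle. Cycle `i` starting at time
#' `t_i` has period `T_i = (1 / f0(t_i)) * (1 + jitter_level * e_i)` with
#' `e_i` standard normal, and peak amplitude `A_i = 1 + shimmer_level * n_i`
#' (clipped to stay positive). The train is shaped by cascaded second-order
#' formant resonators, and band-limited aspiration noise is added at
#' `noise_level` relative to the voiced RMS. The realized cycle start times,
#' periods, amplitudes and instantaneous F0 are returned as ground truth.
#'
#' @param spec A [phonation_spec()].
#' @return A list with elements `p` (a [phonation()]) and `ground_truth`
#'   (data.frame: `t` cycle start s, `period` s, `amplitude`, `f0` Hz).
#' @export
synthesize_phonation <- function(spec) {
  stopifnot(inherits(spec, "phonation_spec"))
  fs <- spec$source_fs
  with_local_seed(spec$seed, {
    # realize cycles first so ground truth is exact regardless of sampling
    t_cur <- 0
    t0 <- numeric(0); Ti <- numeric(0); Ai <- numeric(0); f0i <- numeric(0)
    while (TRUE) {
      f0_t <- spec$base_f0 +
        spec$tremor_extent * sin(2 * pi * spec$tremor_rate * t_cur)
      Tn <- (1 / f0_t) * (1 + spec$jitter_level * stats::rnorm(1))
      Tn <- max(Tn, 0.25 / f0_t)           # guard against negative periods
      if (t_cur + Tn > spec$duration) break
      An <- max(1 + spec$shimmer_level * stats::rnorm(1), 0.05)
      t0 <- c(t0, t_cur); Ti <- c(Ti, Tn); Ai <- c(Ai, An); f0i <- c(f0i, f0_t)
      t_cur <- t_cur + Tn
    }
    if (length(Ti) < 3)
      stop("duration too short: fewer than 3 glottal cycles")

    n <- floor(spec$duration * fs)
    src <- numeric(n)
    for (i in seq_along(Ti)) {
      k0 <- ceiling(t0[i] * fs)
      k1 <- min(ceiling((t0[i] + Ti[i]) * fs) - 1, n - 1)
      if (k1 < k0) next
      k <- k0:k1
      # pulse shape follows the slow (unjittered) period so the acoustic
      # landmark sits at a fixed offset from the cycle onset: onset-to-onset
      # intervals in the waveform then carry the realized jitter T_i exactly
      phase <- (k / fs - t0[i]) * f0i[i]
      src[k + 1] <- Ai[i] * rosenberg_pulse(phase)
    }

    # lip-radiation characteristic: the pressure signal is (approximately)
    # the derivative of the glottal flow, giving the sharp closure
    # excitation real voices have
    voiced <- c(0, diff(src)) * fs / 1000
    for (j in seq_len(nrow(spec$formants))) {
      Fc <- spec$formants[j, 1]; Bw <- spec$formants[j, 2]
      r <- exp(-pi * Bw / fs)
      th <- 2 * pi * Fc / fs
      b0 <- 1 - 2 * r * cos(th) + r^2
      voiced <- as.numeric(
        signal::filter(b0, c(1, -2 * r * cos(th), r^2), voiced))
    }
    voiced <- voiced - mean(voiced)

    x <- voiced
    if (spec$noise_level > 0) {
      noise <- stats::rnorm(n)
      noise <- butter_zerophase(noise, fs, c(300, 0.45 * fs), "pass", order = 2)
      noise <- noise / rms(noise) * spec$noise_level * rms(voiced)
      x <- x + noise
    }
    x <- x / max(abs(x)) * 0.5    # uniform headroom scaling

    p <- phonation(x, fs, meta = list(spec = spec))
    list(p = p,
         ground_truth = data.frame(t = t0, period = Ti,
                                   amplitude = Ai, f0 = f0i))
  })
}

#' Perturbation statistics of realized ground-truth cycles
#'
#' Convenience accessor for tests and calibration: realized jitter
#' (SD of periods / mean period), realized shimmer (SD of amplitudes / mean
#' amplitude), and the mean-absolute-difference forms used by the classical
#' jitter/shimmer measures.
#'
#' @param gt Ground-truth data.frame from [synthesize_phonation()].
#' @return Named list of realized statistics.
#' @export
ground_truth_stats <- function(gt) {
  Ti <- gt$period; Ai <- gt$amplitude
  list(
    jitter_sd   = stats::sd(Ti) / mean(Ti),
    shimmer_sd  = stats::sd(Ai) / mean(Ai),
    jitter_local  = mean(abs(diff(Ti))) / mean(Ti),
    shimmer_local = mean(abs(diff(Ai))) / mean(Ai)
  )
}
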