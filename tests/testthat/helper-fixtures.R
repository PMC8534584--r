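# Shared fixtures, memoized per test session. All audio is generated in
# code; "tel_" fixtures have been passed through the default telephone
# channel (8 kHz, 300-3400 Hz, 16 bit).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    val <- switch(name,
      syn_clean = synthesize_phonation(
        phonation_spec(duration = 3, base_f0 = 150, seed = 2)),
      tel_clean = apply_telephone_channel(fixture("syn_clean")$p),
      f0_clean = estimate_f0_contour(fixture("tel_clean")),
      syn_jitter02 = synthesize_phonation(
        phonation_spec(duration = 5, base_f0 = 150, jitter_level = 0.02,
                       seed = 7)),
      tel_jitter02 = apply_telephone_channel(fixture("syn_jitter02")$p),
      syn_breathy = synthesize_phonation(
        phonation_spec(duration = 3, base_f0 = 150, noise_level = 0.3,
                       seed = 2)),
      tel_breathy = apply_telephone_channel(fixture("syn_breathy")$p),
      white_noise = {
        set.seed(501)
        phonation(stats::rnorm(16000), 8000)
      },
      stop("unknown fixture ", name))
    assign(name, val, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Segment + contour + cycles for a telephone phonation, as extract_all
# prepares them.
analysis_segment <- function(p, f0 = estimate_f0_contour(p)) {
  win <- select_stationary_segment(p, f0)
  seg <- crop_phonation(p, win$start, win$end)
  f0_seg <- structure(list(times = f0$times[win$frame_idx] - win$start,
                           f0 = f0$f0[win$frame_idx],
                           strength = f0$strength[win$frame_idx],
                           voicing_threshold = f0$voicing_threshold),
                      class = "f0_contour")
  list(seg = seg, f0 = f0_seg, win = win,
       cycles = extract_cycles(seg, f0_seg))
}

# Independent autocorrelation pitch oracle: max normalized autocorrelation
# over the lag range, taking the shortest lag within 1% of the maximum
# (avoids subharmonic ties on clean periodic input).
acf_pitch_oracle <- function(x, fs, f_min = 50, f_max = 500) {
  x <- x - mean(x)
  lags <- round(fs / f_max):round(fs / f_min)
  n <- length(x)
  r <- vapply(lags, function(l) {
    a <- x[1:(n - l)]; b <- x[(l + 1):n]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  best <- min(lags[r >= max(r) * 0.99])
  fs / best
}

# Synthetic contour object for contour-level features.
make_contour <- function(f0_values, dt = 0.01) {
  structure(list(times = (seq_along(f0_values) - 1) * dt, f0 = f0_values,
                 strength = rep(1, length(f0_values)),
                 voicing_threshold = 0.2),
            class = "f0_contour")
}
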