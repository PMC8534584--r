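# Quality screening and most-stationary 2 s segment selection.

test_that("clean synthetic phonations pass screening", {
  p <- apply_telephone_channel(synthesize_phonation(
    phonation_spec(duration = 5, base_f0 = 150, jitter_level = 0.006,
                   shimmer_level = 0.03, noise_level = 0.01, seed = 5))$p)
  rep <- screen_quality(p)
  expect_true(rep$passed)
  expect_length(rep$reasons, 0)
})

test_that("an all-zero signal fails as unvoiced", {
  rep <- screen_quality(phonation(numeric(40000) + 0, 8000))
  expect_false(rep$passed)
  expect_true("unvoiced" %in% rep$reasons)
})

test_that("heavy additive noise triggers the low-SNR rule", {
  p <- fixture("tel_clean")
  set.seed(31)
  noise <- stats::rnorm(length(p$samples)) * sqrt(mean(p$samples^2)) *
    10^(5 / 20)                                   # -5 dB SNR mixture
  rep <- screen_quality(phonation(pmin(pmax(p$samples + noise, -1), 1),
                                  p$fs))
  expect_false(rep$passed)
  expect_true("low_snr" %in% rep$reasons)
})

test_that("clipping is detected and is amplitude-referenced", {
  p <- fixture("tel_clean")
  clipped <- phonation(pmin(pmax(p$samples * 8, -1), 1), p$fs)
  rep <- screen_quality(clipped)
  expect_true("clipped" %in% rep$reasons)
  # gain scaling below clipping leaves the voicing decision unchanged
  r1 <- screen_quality(p)
  r2 <- screen_quality(phonation(p$samples * 0.25, p$fs))
  expect_equal(r1$voiced_fraction, r2$voiced_fraction, tolerance = 1e-6)
})

test_that("segment selection matches a brute-force minimizer", {
  brute_force <- function(f0, min_voiced = 0.75) {
    w <- 200L
    n <- length(f0$times)
    best_sd <- Inf; best <- NA
    for (s in 1:(n - w + 1)) {
      vals <- f0$f0[s:(s + w - 1)]
      nv <- sum(!is.na(vals))
      if (nv < ceiling(min_voiced * w)) next
      sdv <- sd(vals[!is.na(vals)])
      if (sdv < best_sd - 1e-15) { best_sd <- sdv; best <- s }
    }
    best
  }
  p <- fixture("tel_jitter02")
  f0 <- estimate_f0_contour(p)
  win <- select_stationary_segment(p, f0)
  expect_equal(win$frame_idx[1], brute_force(f0))

  # ramp case: constant 150 Hz for t < 3 s then a ramp; the chosen window
  # must lie in the flat region
  syn <- synthesize_phonation(phonation_spec(duration = 5, base_f0 = 150,
                                             seed = 4))
  x <- syn$p$samples
  fs <- syn$p$fs
  t <- (seq_along(x) - 1) / fs
  ramp <- sin(2 * pi * (150 * t + 30 * pmax(t - 3, 0)^2 / 4))
  pr <- apply_telephone_channel(phonation(ifelse(t < 3, x, 0.5 * ramp), fs))
  f0r <- estimate_f0_contour(pr)
  winr <- select_stationary_segment(pr, f0r)
  expect_equal(winr$frame_idx[1], brute_force(f0r))
  expect_lt(winr$end, 3.05)
})

test_that("constant contours tie-break to the earliest window", {
  p <- fixture("tel_clean")
  f0 <- make_contour(rep(150, 300))
  win <- select_stationary_segment(p, f0)
  expect_equal(win$start, 0)
  expect_equal(win$end - win$start, 2)
  expect_equal(win$f0_dispersion, 0)
})

test_that("an exactly 2 s recording yields the single full-length window", {
  p2 <- crop_phonation(fixture("tel_clean"), 0, 2)
  f0 <- make_contour(rep(150, 200))
  win <- select_stationary_segment(p2, f0)
  expect_equal(win$start, 0)
  expect_length(win$frame_idx, 200)
})

test_that("unvoiced recordings cannot yield a window", {
  p <- fixture("white_noise")
  f0 <- estimate_f0_contour(p)
  expect_error(select_stationary_segment(p, f0), "window")
})
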