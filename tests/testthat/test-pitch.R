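# Pitch contour estimation and cycle extraction.

test_that("clean 150 Hz phonation is tracked within 1.5 Hz", {
  f0 <- fixture("f0_clean")
  est <- f0$f0[!is.na(f0$f0)]
  expect_gt(length(est), 200)
  expect_true(all(abs(est - 150) < 1.5))
})

test_that("all-zero input yields no voiced frames", {
  f0 <- estimate_f0_contour(phonation(numeric(24000), 8000))
  expect_true(all(is.na(f0$f0)))
  expect_true(all(f0$strength == 0))
})

test_that("a linear F0 ramp yields a monotone contour", {
  fs <- 44100
  t <- (0:(fs * 3 - 1)) / fs
  # 120 -> 180 Hz chirp through the channel
  x <- sin(2 * pi * (120 * t + 10 * t^2))
  p <- apply_telephone_channel(phonation(x, fs))
  f0 <- estimate_f0_contour(p)
  v <- !is.na(f0$f0)
  expect_gt(mean(v), 0.8)
  rho <- cor(f0$times[v], f0$f0[v], method = "spearman")
  expect_gt(rho, 0.99)
  expect_true(all(abs(f0$f0[v] - (120 + 20 * f0$times[v])) < 6))
})

test_that("pitch is invariant to gain and polarity", {
  p <- fixture("tel_clean")
  f0a <- estimate_f0_contour(p)
  f0b <- estimate_f0_contour(phonation(-3 * p$samples, p$fs))
  expect_equal(f0a$f0, f0b$f0, tolerance = 1e-10)
})

test_that("estimator agrees with the autocorrelation oracle across 70-400 Hz", {
  # pitches chosen so the period is an integer number of samples at 8 kHz,
  # keeping the lattice autocorrelation oracle free of interpolation bias
  for (f0_true in c(80, 100, 125, 160, 200, 250, 320, 400)) {
    syn <- synthesize_phonation(phonation_spec(duration = 2.5,
                                               base_f0 = f0_true, seed = 3))
    p <- apply_telephone_channel(syn$p)
    f0 <- estimate_f0_contour(p)
    mid <- which(f0$times > 1 & f0$times < 1.5 & !is.na(f0$f0))
    est <- median(f0$f0[mid])
    seg <- p$samples[8001:12000]
    oracle <- acf_pitch_oracle(seg, p$fs)
    expect_lt(abs(est - oracle) / oracle, 0.01)
    expect_gt(est / f0_true, 0.9)    # no octave errors
    expect_lt(est / f0_true, 1.1)
  }
})

test_that("zero-jitter cycles have near-constant extracted periods", {
  p <- fixture("tel_clean")
  cyc <- extract_cycles(p, fixture("f0_clean"))
  expect_lt(max(cyc$periods) - min(cyc$periods), 1 / 8000)
  expect_equal(length(cyc$periods), length(cyc$marks) - 1)
  expect_equal(length(cyc$amplitudes), length(cyc$periods))
  expect_true(all(cyc$periods > 0))
})

test_that("cycle extraction recovers realized jitter within 20%", {
  syn <- fixture("syn_jitter02")
  p <- fixture("tel_jitter02")
  f0 <- estimate_f0_contour(p)
  cyc <- extract_cycles(p, f0)
  est <- sd(cyc$periods) / mean(cyc$periods)
  gt <- syn$ground_truth
  realized <- sd(gt$period) / mean(gt$period)
  expect_lt(abs(est - realized) / realized, 0.20)
})

test_that("cycle extraction recovers realized shimmer within 20%", {
  syn <- synthesize_phonation(phonation_spec(duration = 5, base_f0 = 150,
                                             shimmer_level = 0.05, seed = 3))
  p <- apply_telephone_channel(syn$p)
  f0 <- estimate_f0_contour(p)
  cyc <- extract_cycles(p, f0)
  est <- sd(cyc$amplitudes) / mean(cyc$amplitudes)
  gt <- syn$ground_truth
  realized <- sd(gt$amplitude) / mean(gt$amplitude)
  expect_lt(abs(est - realized) / realized, 0.20)
})

test_that("degenerate inputs are rejected", {
  expect_error(estimate_f0_contour(fixture("tel_clean"), f_min = 300,
                                   f_max = 200), "f_min")
  f0_empty <- make_contour(rep(NA_real_, 100))
  expect_error(extract_cycles(fixture("tel_clean"), f0_empty), "voiced")
})
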