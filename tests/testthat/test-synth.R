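# Synthetic phonation generator: ground-truth contracts, determinism,
# and telephone-channel behaviour.

test_that("zero-perturbation synthesis gives exactly periodic ground truth", {
  syn <- synthesize_phonation(phonation_spec(duration = 2, base_f0 = 150,
                                             seed = 1))
  expect_true(all(abs(syn$ground_truth$period - 1 / 150) < 1e-12))
  expect_true(all(abs(syn$ground_truth$amplitude - 1) < 1e-12))
  # waveform periodicity: period is exactly 294 samples at 44.1 kHz
  x <- syn$p$samples
  per <- 44100 / 150
  a <- x[20001:30000]; b <- x[(20001 + per):(30000 + per)]
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("realized jitter statistics converge to the requested level", {
  gt <- fixture("syn_jitter02")$ground_truth   # 5 s at 150 Hz, ~750 cycles
  realized <- sd(gt$period) / mean(gt$period)
  expect_lt(abs(realized - 0.02) / 0.02, 0.15)
})

test_that("same spec and seed give bit-identical output", {
  s1 <- synthesize_phonation(phonation_spec(duration = 1.5, jitter_level = 0.01,
                                            noise_level = 0.05, seed = 7))
  s2 <- synthesize_phonation(phonation_spec(duration = 1.5, jitter_level = 0.01,
                                            noise_level = 0.05, seed = 7))
  expect_identical(s1$p$samples, s2$p$samples)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("invalid specs and too-short durations are rejected", {
  expect_error(phonation_spec(base_f0 = 30))
  expect_error(phonation_spec(jitter_level = -0.1))
  expect_error(synthesize_phonation(phonation_spec(duration = 0.01)),
               "3 glottal cycles")
})

test_that("shimmer ground truth scales amplitudes", {
  syn <- synthesize_phonation(phonation_spec(duration = 5, base_f0 = 150,
                                             shimmer_level = 0.05, seed = 3))
  gt <- syn$ground_truth
  expect_lt(abs(sd(gt$amplitude) / mean(gt$amplitude) - 0.05) / 0.05, 0.15)
})

test_that("telephone channel preserves in-band tones and rejects out-of-band", {
  fs <- 44100
  tone <- phonation(sin(2 * pi * 1000 * (0:(fs * 2 - 1)) / fs), fs)
  out <- apply_telephone_channel(tone)
  expect_equal(out$fs, 8000)
  expect_equal(length(out$samples), 16000)
  X <- Mod(stats::fft(out$samples))[1:8000]
  f <- (0:7999) / 16000 * 8000
  expect_lt(abs(f[which.max(X)] - 1000), 1)
  expect_lt(20 * log10(max(X[f > 3700]) / max(X)), -40)

  low <- phonation(sin(2 * pi * 100 * (0:(fs * 2 - 1)) / fs), fs)
  out_low <- apply_telephone_channel(low)
  atten <- 20 * log10(sqrt(mean(out_low$samples^2)) /
                        sqrt(mean(low$samples^2)))
  expect_lt(atten, -20)
})

test_that("telephone channel maps silence to silence and keeps duration", {
  sil <- apply_telephone_channel(phonation(numeric(44100), 44100))
  expect_true(all(sil$samples == 0))
  expect_equal(length(sil$samples), 8000)
})

test_that("channel is near-idempotent in the passband interior", {
  # content away from the 300 / 3400 Hz edges passes a second application
  # essentially unchanged (the Butterworth skirts re-attenuate edge
  # content, so exact idempotence holds only in the interior)
  t <- (0:15999) / 8000
  x <- 0.3 * (sin(2 * pi * 500 * t) + sin(2 * pi * 1000 * t) +
                sin(2 * pi * 2000 * t))
  p1 <- apply_telephone_channel(phonation(x, 8000))
  p2 <- apply_telephone_channel(p1)
  rel <- sqrt(mean((p2$samples - p1$samples)^2)) / sqrt(mean(p1$samples^2))
  expect_lt(rel, 0.02)
})

test_that("infeasible passbands are rejected", {
  expect_error(channel_spec(target_fs = 6000, passband = c(300, 3400)),
               "infeasible")
  expect_error(apply_telephone_channel(phonation(stats::rnorm(4000), 4000)),
               "sampling rate too low")
})
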