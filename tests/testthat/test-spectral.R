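# MFCC, normative F0 comparisons, wavelet contour statistics, and the
# underlying wavelet transform.

test_that("periodized db8 DWT matches frozen reference band energies", {
  # expected values computed offline with an independent wavelet library
  # (wavedec, db8, periodization, 3 levels) on this deterministic signal
  x <- sin(2 * pi * (0:63) * 5 / 64) + 0.25 * cos(2 * pi * (0:63) * 13 / 64)
  d <- dwt_db8(x, levels = 3)
  expect_equal(sum(d$d1^2), 0.242612294525, tolerance = 1e-9)
  expect_equal(sum(d$d2^2), 2.024231578480, tolerance = 1e-9)
  # deeper bands share a boundary-phase convention; their sum is invariant
  expect_equal(sum(d$a^2) + sum(d$d3^2), 1.857334797588 + 29.875821329407,
               tolerance = 1e-9)
  # orthogonality: band energies sum to the signal energy
  expect_equal(sum(x^2), sum(vapply(d, function(c) sum(c^2), numeric(1))),
               tolerance = 1e-10)
  expect_error(dwt_db8(rnorm(100), levels = 3), "divisible")
})

test_that("MFCC family has 39 measures with the documented structure", {
  a <- analysis_segment(fixture("tel_clean"))
  m <- mfcc_family(a$seg)
  expect_length(m, 39)
  expect_identical(names(m), pdvoice:::mfcc_names())
  expect_true(all(is.finite(m)))
})

test_that("gain scaling moves only c0", {
  a <- analysis_segment(fixture("tel_clean"))
  m1 <- mfcc_family(a$seg)
  m2 <- mfcc_family(phonation(a$seg$samples * 10, a$seg$fs))
  expect_gt(abs(m2[1] - m1[1]), 1)
  expect_lt(max(abs(m2[2:13] - m1[2:13])), 1e-6)
})

test_that("stationary input has vanishing delta trajectories", {
  s <- phonation(sin(2 * pi * 150 * (0:15999) / 8000), 8000)
  m <- mfcc_family(s)
  expect_lt(max(abs(m[14:39])), 1e-3)
})

test_that("normative F0 comparison follows the Gaussian model", {
  norms <- normative_f0_table()
  # observed mean log-F0 equal to the normative mean
  f0 <- make_contour(rep(120, 100))
  v <- f0_related_family(f0, age = 60, gender = "M", norms)
  expect_length(v, 3)
  expect_equal(unname(v["f0.z_mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["f0.tail_prob"]), 1, tolerance = 1e-9)
  # one normative SD above: z = 1, tail = 2 (1 - Phi(1)) = 0.3173
  f0_hi <- make_contour(rep(120 * exp(0.15), 100))
  v2 <- f0_related_family(f0_hi, age = 60, gender = "M", norms)
  expect_equal(unname(v2["f0.z_mean"]), 1, tolerance = 1e-9)
  expect_equal(unname(v2["f0.tail_prob"]), 2 * (1 - pnorm(1)),
               tolerance = 1e-9)
  expect_error(f0_related_family(f0, age = 60, gender = "X", norms),
               "gender")
})

test_that("wavelet family has 182 measures and a silent detail on constants", {
  f0c <- make_contour(rep(150, 300))
  v <- wavelet_family(f0c)
  expect_length(v, 182)
  expect_identical(names(v), pdvoice:::wavelet_names())
  # constant contour: all detail energy vanishes (log of ~0 energy)
  d_logE <- v[grep("^wav.f0_d[0-9]+_logE$", names(v))]
  expect_true(all(d_logE < log(1e-10)))
})

test_that("a 5 Hz tremor concentrates energy in the matching scale band", {
  f0v <- 150 + 3 * sin(2 * pi * 5 * (0:299) * 0.01)
  v <- wavelet_family(make_contour(f0v))
  eng <- v[grep("^wav.f0_d[0-9]+_logE$", names(v))]
  # 100 Hz contour rate: d4 covers 3.125-6.25 Hz
  expect_equal(which.max(eng), 4, ignore_attr = TRUE)
  expect_error(wavelet_family(make_contour(rep(150, 50))), "128")
})
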