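# Jitter, shimmer and glottis-quotient families: hand-computed oracles,
# degenerate cases, and the frozen family sizes.

make_cycles <- function(periods, amplitudes = rep(1, length(periods))) {
  structure(list(marks = c(0, cumsum(periods)), periods = periods,
                 amplitudes = amplitudes),
            class = "cycle_sequence")
}

test_that("local jitter matches the hand-evaluated formula", {
  # periods 5.0, 5.1, 4.9, 5.0, 5.2 ms:
  # mean(|0.1|,|0.2|,|0.1|,|0.2|) / 5.04 = 0.0297619...
  s <- c(5.0, 5.1, 4.9, 5.0, 5.2) / 1000
  expect_equal(pdvoice:::local_stat(s), 0.15 / 5.04, tolerance = 1e-12)
  expect_equal(pdvoice:::local_stat(s), 0.0297619048, tolerance = 1e-8)
})

test_that("jitter family is 28 zeros on constant periods", {
  cyc <- make_cycles(rep(0.005, 20))
  f0 <- make_contour(rep(200, 60))
  v <- jitter_family(cyc, f0)
  expect_length(v, 28)
  expect_identical(names(v), pdvoice:::jitter_names())
  expect_true(all(abs(v) < 1e-12))
})

test_that("jitter family responds to period perturbation", {
  set.seed(4)
  per <- 0.005 * (1 + 0.02 * rnorm(100))
  cyc <- make_cycles(per)
  f0 <- make_contour(200 * (1 + 0.01 * rnorm(100)))
  v <- jitter_family(cyc, f0)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["jitter.local_mean"]),
               mean(abs(diff(per))) / mean(per), tolerance = 1e-12)
  expect_error(jitter_family(make_cycles(rep(0.005, 5)), f0), "12")
})

test_that("shimmer family matches the hand-evaluated local formula", {
  # amplitudes 1.0, 1.1, 0.9, 1.0 -> mean(0.1, 0.2, 0.1) / 1.0 = 0.13333
  cyc <- make_cycles(rep(0.005, 12), c(1.0, 1.1, 0.9, 1.0, 1.0, 1.1,
                                       0.9, 1.0, 1.0, 1.1, 0.9, 1.0))
  v <- shimmer_family(cyc)
  first4 <- c(1.0, 1.1, 0.9, 1.0)
  expect_equal(unname(shimmer_family(make_cycles(rep(0.005, 12),
    rep(first4, 3)))["shimmer.local_mean"]),
    mean(abs(diff(rep(first4, 3)))) / 1.0, tolerance = 1e-12)
  expect_length(v, 21)
  expect_identical(names(v), pdvoice:::shimmer_names())
})

test_that("shimmer family is 21 zeros on constant amplitudes", {
  cyc <- make_cycles(rep(0.005, 20), rep(0.7, 20))
  v <- shimmer_family(cyc)
  expect_length(v, 21)
  expect_true(all(abs(v) < 1e-12))
  expect_error(shimmer_family(make_cycles(rep(0.005, 20),
                                          c(rep(1, 19), -0.1))),
               "non-positive")
})

test_that("glottis quotient measures match direct evaluation", {
  cyc <- make_cycles(rep(0.005, 20))
  expect_equal(unname(gq_family(cyc)), c(0, 0, 0))
  # alternating 4.5 / 5.5 ms: every cycle deviates 10% from the 5.0 median
  alt <- make_cycles(rep(c(4.5e-3, 5.5e-3), 10))
  v <- gq_family(alt)
  expect_length(v, 3)
  expect_equal(unname(v["gq.frac_dev5"]), 1.0)
  expect_equal(unname(v["gq.sd_rel"]),
               sd(rep(c(4.5e-3, 5.5e-3), 10)) / 5e-3, tolerance = 1e-12)
})

test_that("perturbation measures are invariant to waveform gain", {
  p <- fixture("tel_jitter02")
  f0 <- estimate_f0_contour(p)
  a1 <- analysis_segment(p, f0)
  p2 <- phonation(p$samples * 0.3, p$fs)
  a2 <- analysis_segment(p2, estimate_f0_contour(p2))
  j1 <- jitter_family(a1$cycles, a1$f0)
  j2 <- jitter_family(a2$cycles, a2$f0)
  expect_equal(j1, j2, tolerance = 1e-6)
  s1 <- shimmer_family(a1$cycles, a1$seg)
  s2 <- shimmer_family(a2$cycles, a2$seg)
  scale_free <- setdiff(names(s1), "shimmer.abs")
  expect_equal(s1[scale_free], s2[scale_free], tolerance = 1e-6)
  # the declared absolute measure scales with gain
  expect_equal(unname(s2["shimmer.abs"] / s1["shimmer.abs"]), 0.3,
               tolerance = 1e-6)
})
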