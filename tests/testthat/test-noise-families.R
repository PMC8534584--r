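# Noise-related families: HNR/NHR, GNE, VFER, EMD excitation ratios.

test_that("HNR is high for a pure sine and low for white noise", {
  s <- phonation(sin(2 * pi * 150 * (0:15999) / 8000), 8000)
  f0s <- estimate_f0_contour(s)
  v <- hnr_nhr(s, f0s)
  expect_length(v, 4)
  expect_gt(v["hnr.hnr_mean"], 30)
  expect_lt(v["hnr.nhr_mean"], 0.001)

  nz <- fixture("white_noise")
  vn <- hnr_nhr(nz, estimate_f0_contour(nz))
  expect_lt(vn["hnr.hnr_mean"], 3)
})

test_that("HNR decreases with aspiration noise level", {
  h <- sapply(c(0, 0.1, 0.3), function(nl) {
    p <- apply_telephone_channel(synthesize_phonation(
      phonation_spec(duration = 3, base_f0 = 150, noise_level = nl,
                     seed = 6))$p)
    a <- analysis_segment(p)
    hnr_nhr(a$seg, a$f0)["hnr.hnr_mean"]
  })
  expect_true(all(diff(h) < 0))
})

test_that("GNE is high for noise-free phonation and lower for noise", {
  a <- analysis_segment(fixture("tel_clean"))
  g <- gne_family(a$seg)
  expect_length(g, 6)
  expect_identical(names(g), pdvoice:::gne_names())
  expect_gte(g["gne.gne_mean"], 0.8)

  gn <- gne_family(fixture("white_noise"))
  expect_lt(gn["gne.gne_mean"], g["gne.gne_mean"])
  ab <- analysis_segment(fixture("tel_breathy"))
  gb <- gne_family(ab$seg)
  expect_lt(gb["gne.gne_mean"], g["gne.gne_mean"])
})

test_that("VFER energy ratio reflects the band split", {
  v <- vfer_family(fixture("white_noise"))
  expect_length(v, 9)
  expect_identical(names(v), pdvoice:::vfer_names())
  # flat spectrum: ratio ~ bandwidth ratio 2.5 / 1.5
  expect_lt(abs(v["vfer.energy_seg"] - 2.5 / 1.5) / (2.5 / 1.5), 0.10)
  expect_lt(abs(v["vfer.energy_mean"] - 2.5 / 1.5) / (2.5 / 1.5), 0.10)

  # band-limited (< 2 kHz) clean signal strongly favors the low band
  t <- (0:15999) / 8000
  lowb <- phonation(sin(2 * pi * 500 * t) + 0.5 * sin(2 * pi * 1500 * t),
                    8000)
  vl <- vfer_family(lowb)
  expect_gt(vl["vfer.energy_mean"], 10)
  expect_gt(vl["vfer.energy_seg"], 10)
})

test_that("EMD excitation ratio matches an analytic tone decomposition", {
  t <- (0:15999) / 8000
  x <- sin(2 * pi * 50 * t) + 0.3 * sin(2 * pi * 1000 * t) +
    0.2 * sin(2 * pi * 3000 * t)
  e <- emd_er_family(phonation(x, 8000))
  expect_length(e, 6)
  expect_identical(names(e), pdvoice:::emd_er_names())
  # IMF1 ~ 3 kHz tone, IMF2 ~ 1 kHz tone, remainder ~ 50 Hz tone:
  # energy ratio = 1 / (0.3^2 + 0.2^2)
  analytic <- 1 / (0.09 + 0.04)
  expect_lt(abs(e["emd.er_raw"] - analytic) / analytic, 0.05)
  expect_equal(unname(e["emd.er_db"]), unname(10 * log10(e["emd.er_raw"])),
               tolerance = 1e-9)
})

test_that("degenerate input is flagged rather than imputed", {
  ramp <- phonation(seq(0, 1, length.out = 12000), 8000)
  expect_error(emd_er_family(ramp), "IMF")
  expect_error(emd_er_family(crop_phonation(fixture("tel_clean"), 0, 0.5)),
               "1 s")
})
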