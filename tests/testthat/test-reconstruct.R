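test_that("carrier location finds the true carrier to one frequency bin", {
  m <- generate_phantom(small_params(band_limit = 0.08), seed = 1)
  ig <- synthesize(m, carrier_spec(0.125, 0.125), noise_model("none"))
  est <- locate_carrier(ig)
  expect_lt(max(abs(est - c(0.125, 0.125))), 1 / 256)
  expect_error(locate_carrier(matrix(5, 64, 64)), "no carrier detected")
  expect_error(locate_carrier(matrix(1, 8, 8)), "16 px")
})

test_that("conjugate sidebands map to one half-plane representative", {
  ph <- phase_map(matrix(0, 64, 64), 0.108)
  a <- locate_carrier(synthesize(ph, carrier_spec(-0.125, 0.125),
                                 noise_model("none")))
  b <- locate_carrier(synthesize(ph, carrier_spec(0.125, -0.125),
                                 noise_model("none")))
  expect_equal(a, b)
  expect_gte(a[["fy"]], 0)
})

test_that("demodulation recovers constant and smooth phase", {
  ph <- phase_map(matrix(0.7, 128, 128), 0.108)
  ig <- synthesize(ph, carrier_spec(), noise_model("none"))
  wp <- demodulate(ig, sideband_filter(c(0.125, 0.125)))
  expect_s3_class(wp, "wrapped_phase")
  expect_lt(max(abs(trim_border(wp$values) - 0.7)), 1e-6)
  # smooth Gaussian bump, peak 2 rad, sigma 30 px
  n <- 256
  bump <- 2 * outer(seq_len(n), seq_len(n), function(r, c)
    exp(-((r - 128)^2 + (c - 128)^2) / (2 * 30^2)))
  igb <- synthesize(phase_map(bump, 0.108), carrier_spec(),
                    noise_model("none"))
  wpb <- demodulate(igb, sideband_filter(locate_carrier(igb)))
  uw <- unwrap_goldstein(wpb)
  err <- trim_border(remove_plane(uw$phase$values - bump, 16), 16)
  expect_lt(sqrt(mean(err^2)), 1e-3)
})

test_that("wrapping contract and conjugate antisymmetry hold", {
  # ramp exceeding the principal interval: wraps appear at odd pi crossings
  # (slope chosen so exp(i*phi) is FFT-periodic: 4 cycles across the field)
  n <- 128
  ramp <- outer(seq_len(n), seq_len(n),
                function(r, c) 2 * pi * 4 * (c - 1) / n)
  ig <- synthesize(phase_map(ramp, 0.108), carrier_spec(0.25, 0.25),
                   noise_model("none"))
  f <- sideband_filter(c(0.25, 0.25), radius = 0.08)
  wp <- demodulate(ig, f)
  expect_true(all(wp$values > -pi & wp$values <= pi))
  interior <- trim_border(wp$values - wrap_phase(ramp))
  expect_lt(max(abs(wrap_phase(interior))), 1e-3)
  # mirrored sideband yields the negated phase (mod 2 pi)
  fm <- sideband_filter(c(-0.25, -0.25), radius = 0.08)
  wm <- demodulate(ig, fm)
  s <- trim_border(wrap_phase(wm$values + wp$values))
  expect_lt(max(abs(s)), 1e-3)
})

test_that("sideband filter guards against DC overlap", {
  ph <- generate_phantom(small_params(), seed = 1)
  ig <- synthesize(ph, carrier_spec(), noise_model("none"))
  expect_error(demodulate(ig, sideband_filter(c(0.125, 0.125), radius = 0.2)),
               "overlaps DC")
  wide <- sideband_filter(c(0.125, 0.125), radius = 0.1)
  wp <- demodulate(ig, wide)
  expect_match(wp$provenance$warnings, "half the carrier distance")
})

test_that("polynomial and reference background subtraction behave", {
  n <- 128
  tilt <- outer(seq_len(n), seq_len(n), function(r, c) 0.01 * c - 0.004 * r)
  pm <- phase_map(tilt, 0.108, provenance = "reconstructed")
  flat <- subtract_background(pm, "polynomial", poly_order = 1,
                              cell_mask = matrix(FALSE, n, n))
  expect_lt(max(abs(flat$values)), 1e-9)
  # phantom + tilt + offset: cell region recovered to < 2 mrad RMS
  ph <- generate_phantom(small_params(), seed = 3)
  noisy <- phase_map(ph$values + 0.3 +
                       outer(seq_len(256), seq_len(256),
                             function(r, c) 0.002 * c - 0.001 * r),
                     ph$pixel_pitch)
  rec <- subtract_background(noisy, "polynomial", poly_order = 1)
  cell <- ph$values > 0
  expect_lt(sqrt(mean((rec$values[cell] - ph$values[cell])^2)), 2e-3)
  expect_lt(abs(mean(rec$values[!cell])), 1e-3)
  # self-subtraction in reference mode is identically zero
  ref <- subtract_background(noisy, "reference_frame", reference = noisy)
  expect_true(all(ref$values == 0))
  # underdetermined fit
  tiny <- phase_map(matrix(1, 16, 16), 0.108)
  expect_error(subtract_background(tiny, "polynomial", poly_order = 3,
                                   cell_mask = matrix(TRUE, 16, 16)),
               "underdetermined")
})
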