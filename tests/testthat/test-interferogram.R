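test_that("noise-free synthesis follows the fringe equation exactly", {
  ph <- phase_map(matrix(0, 64, 64), 0.108)
  # zero modulation: constant image at the DC level
  ig0 <- synthesize(ph, carrier_spec(0.125, 0),
                    noise_model("none", modulation = 0, background_dc = 100))
  expect_true(all(ig0$intensity == 100))
  # phi = 0, a0 = 100, b0 = 50, fx = 1/8: period-8 vertical fringes
  ig <- synthesize(ph, carrier_spec(1 / 8, 0),
                   noise_model("none", background_dc = 100, modulation = 50))
  x <- matrix(rep(0:63, each = 64), 64, 64)
  expect_equal(ig$intensity, 100 + 50 * cos(2 * pi * x / 8),
               tolerance = 1e-12)
  expect_equal(ig$intensity[1, 1], 150)
  expect_true(all(apply(ig$intensity, 2, function(cc) length(unique(cc))) == 1))
})

test_that("spectrum of a noise-free interferogram is DC plus two sidebands", {
  m <- generate_phantom(small_params(band_limit = 0.08), seed = 1)
  ig <- synthesize(m, carrier_spec(0.25, 0.25), noise_model("none"))
  S <- Mod(fft(ig$intensity))^2
  ord <- order(-S)[1:3]
  expect_gt(sum(S[ord]) / sum(S), 0.99)
  # the three dominant bins are DC and the +/- carrier bins
  n <- 256
  bins <- arrayInd(ord, c(n, n)) - 1L
  expected <- rbind(c(0, 0), c(64, 64), c(192, 192))
  expect_setequal(paste(bins[, 1], bins[, 2]),
                  paste(expected[, 1], expected[, 2]))
})

test_that("carrier separation and intensity invariants are enforced", {
  ph <- phase_map(matrix(0, 64, 64), 0.108)
  expect_error(carrier_spec(0.4, 0.4), "0.5")
  expect_error(carrier_spec(0, 0), "0.5")
  expect_error(synthesize(ph, carrier_spec(0.02, 0), noise_model("none")),
               "3 bins")
  expect_error(noise_model("psc", background_dc = 10, modulation = 20),
               "a0 > b0")
  ig <- synthesize(ph, carrier_spec(), noise_model("psc"), seed = 1)
  expect_true(all(ig$intensity >= 0 & ig$intensity <= 2^16 - 1))
  expect_true(all(ig$intensity == round(ig$intensity)))
})

test_that("synthesis is deterministic given the seed in every regime", {
  m <- generate_phantom(small_params(), seed = 2)
  for (regime in c("none", "psc", "coherent")) {
    a <- synthesize(m, carrier_spec(), noise_model(regime), seed = 42)
    b <- synthesize(m, carrier_spec(), noise_model(regime), seed = 42)
    d <- synthesize(m, carrier_spec(), noise_model(regime), seed = 43)
    expect_identical(a$intensity, b$intensity)
    if (regime != "none") expect_false(identical(a$intensity, d$intensity))
  }
})

test_that("quantization perturbs each pixel by at most half a count", {
  m <- generate_phantom(small_params(), seed = 2)
  # psc path with all stochastic terms silenced isolates the quantizer
  nm <- noise_model("psc", shot_noise = FALSE, phase_noise_std = 0,
                    dc_nonuniformity = 0)
  ig <- synthesize(m, carrier_spec(), nm, seed = 5)
  raw <- synthesize(m, carrier_spec(),
                    noise_model("none", background_dc = nm$background_dc,
                                modulation = nm$modulation), seed = 5)
  expect_lte(max(abs(ig$intensity - raw$intensity)), 0.5)
  expect_gt(max(abs(ig$intensity - raw$intensity)), 0)
})

test_that("empty-field calibration hits the regime's sensitivity ordering", {
  expect_lt(calibrate_phase_noise(noise_model("none"), 2, seed = 3), 1e-3)
  psc <- calibrate_phase_noise(noise_model("psc"), 4, seed = 3)
  expect_gt(psc, 0.010)
  expect_lt(psc, 0.030)
  coh <- calibrate_phase_noise(noise_model("coherent"), 4, seed = 3)
  expect_gt(coh, psc)
})
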