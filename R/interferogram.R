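#' Spatial-carrier specification for an off-axis interferogram
#'
#' @param fx,fy carrier frequencies (cycles/pixel). The carrier magnitude
#'   must lie strictly between 0 and the Nyquist limit 0.5.
#' @return object of class `carrier_spec`.
#' @export
carrier_spec <- function(fx = 0.125, fy = 0.125) {
  mag <- sqrt(fx^2 + fy^2)
  if (!is.finite(mag) || mag <= 0 || mag >= 0.5) {
    stop("carrier magnitude must lie strictly between 0 and 0.5 cycles/pixel")
  }
  structure(list(fx = fx, fy = fy, magnitude = mag), class = "carrier_spec")
}

#' Noise model for interferogram synthesis
#'
#' Three regimes: `"none"` (ideal fringes, no quantization), `"psc"`
#' (partially spatially coherent source: smooth correlated background phase
#' noise, the instrument class whose empty-field phase noise is of order
#' +/-20 mrad), and `"coherent"` (direct laser: the same correlated noise
#' plus broadband speckle-like phase noise and a parasitic fringe, giving a
#' strictly worse empty-field phase noise).
#'
#' @param regime `"psc"`, `"coherent"` or `"none"`.
#' @param background_dc DC intensity a0 (counts).
#' @param modulation fringe modulation b0 (counts); must satisfy a0 > b0 > 0.
#' @param dc_nonuniformity relative amplitude of a smooth polynomial
#'   variation of the background a(x, y).
#' @param phase_noise_std standard deviation (radians) of the correlated
#'   background phase-noise field; the empty-field calibration set-point.
#' @param speckle_amplitude std (radians) of unfiltered speckle-like phase
#'   noise (coherent regime only).
#' @param parasitic_amplitude amplitude (radians) of a low-frequency
#'   parasitic fringe term (coherent regime only).
#' @param shot_noise add Poisson shot noise before quantization.
#' @param bit_depth camera bit depth for quantization.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(regime = c("psc", "coherent", "none"),
                        background_dc = 20000, modulation = 8000,
                        dc_nonuniformity = 0.10,
                        phase_noise_std = 0.020,
                        speckle_amplitude = 0.15,
                        parasitic_amplitude = 0.04,
                        shot_noise = TRUE, bit_depth = 16L) {
  regime <- match.arg(regime)
  if (regime == "none") {
    dc_nonuniformity <- 0
    phase_noise_std <- 0
    speckle_amplitude <- 0
    parasitic_amplitude <- 0
    shot_noise <- FALSE
  }
  if (!(background_dc > modulation && modulation >= 0)) {
    stop("intensity nonnegativity requires a0 > b0 >= 0")
  }
  if (phase_noise_std < 0) stop("phase_noise_std must be >= 0")
  structure(list(regime = regime, background_dc = background_dc,
                 modulation = modulation,
                 dc_nonuniformity = dc_nonuniformity,
                 phase_noise_std = phase_noise_std,
                 speckle_amplitude = speckle_amplitude,
                 parasitic_amplitude = parasitic_amplitude,
                 shot_noise = shot_noise, bit_depth = as.integer(bit_depth)),
            class = "noise_model")
}

#' Synthesize an off-axis interferogram from a phase map
#'
#' Forward model
#' `I(x, y) = a(x, y) + b0 * cos(2*pi*(fx*x + fy*y) + phi(x, y) + eta(x, y))`
#' with `eta` the regime's background phase-noise field, followed by optional
#' Poisson shot noise and quantization to the camera bit depth. `x` is the
#' zero-based column index and `y` the zero-based row index.
#'
#' @param phase a [phase_map()] (radians).
#' @param carrier a [carrier_spec()].
#' @param noise a [noise_model()].
#' @param seed integer seed; the output is deterministic given it.
#' @return object of class `interferogram` with fields `intensity`,
#'   `carrier`, `noise`, `pixel_pitch`.
#' @export
synthesize <- function(phase, carrier = carrier_spec(),
                       noise = noise_model("none"), seed = 1L) {
  stopifnot(inherits(phase, "phase_map"), inherits(carrier, "carrier_spec"),
            inherits(noise, "noise_model"))
  nr <- nrow(phase$values); nc <- ncol(phase$values)
  # the sideband must be resolvable: at least 3 frequency bins from DC
  if (carrier$magnitude < 3 / min(nr, nc)) {
    stop("carrier too close to DC: sideband does not separate (< 3 bins)")
  }
  x <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1), times = nc), nr, nc)

  out <- with_seed(seed, {
    eta <- matrix(0, nr, nc)
    if (noise$regime %in% c("psc", "coherent") && noise$phase_noise_std > 0) {
      eta <- eta + noise$phase_noise_std * smooth_noise_field(nr, nc, 10)
    }
    if (noise$regime == "coherent") {
      if (noise$speckle_amplitude > 0) {
        eta <- eta + noise$speckle_amplitude * matrix(rnorm(nr * nc), nr, nc)
      }
      if (noise$parasitic_amplitude > 0) {
        # weak parasitic reflection: low-frequency fringe inside the passband
        eta <- eta + noise$parasitic_amplitude *
          cos(2 * pi * (0.021 * x + 0.034 * y) + runif(1, 0, 2 * pi))
      }
    }
    a <- noise$background_dc
    if (noise$dc_nonuniformity > 0) {
      xb <- x / (nc - 1) - 0.5; yb <- y / (nr - 1) - 0.5
      a <- a * (1 + noise$dc_nonuniformity *
                  (0.8 * xb + 0.5 * yb - 1.2 * xb * yb - 0.9 * (xb^2 + yb^2)))
    }
    intensity <- a + noise$modulation *
      cos(2 * pi * (carrier$fx * x + carrier$fy * y) + phase$values + eta)
    if (noise$shot_noise) {
      intensity <- matrix(rpois(nr * nc, pmax(0, intensity)), nr, nc)
    }
    if (noise$regime != "none") {
      intensity <- pmin(pmax(round(intensity), 0), 2^noise$bit_depth - 1)
    }
    intensity
  })
  structure(list(intensity = out, carrier = carrier, noise = noise,
                 pixel_pitch = phase$pixel_pitch),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf(
    "<interferogram> %d x %d px, carrier (%.4g, %.4g) cyc/px, regime %s\n",
    nrow(x$intensity), ncol(x$intensity), x$carrier$fx, x$carrier$fy,
    x$noise$regime))
  invisible(x)
}

#' Calibrate the empty-field phase noise of a simulated regime
#'
#' Runs the full round trip (synthesize an empty-field interferogram,
#' demodulate, unwrap, remove piston/tilt) `n_trials` times and returns the
#' mean spatial standard deviation of the recovered phase — the simulated
#' instrument's spatial phase sensitivity. With the default PSC regime this
#' lands near the 0.020 rad set-point.
#'
#' @param noise a [noise_model()].
#' @param n_trials number of independent empty fields.
#' @param seed integer seed.
#' @param size field size in pixels (square).
#' @return mean empty-field spatial phase std (radians).
#' @export
calibrate_phase_noise <- function(noise, n_trials = 10L, seed = 1L,
                                  size = 256L) {
  seeds <- derive_seeds(seed, n_trials)
  vals <- vapply(seeds, function(s) {
    ph <- phase_map(matrix(0, size, size), pixel_pitch = 0.108)
    ig <- synthesize(ph, carrier_spec(), noise, seed = s)
    est <- locate_carrier(ig)
    wp <- demodulate(ig, sideband_filter(center = est))
    uw <- unwrap_goldstein(wp)
    flat <- remove_plane(uw$phase$values, border = 16L)
    sd(trim_border(flat, 16L))
  }, numeric(1))
  mean(vals)
}
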