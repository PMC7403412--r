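#' Parameters of the synthetic sperm-cell phase object
#'
#' Bundles the geometry and optical parameters of a single simulated sperm
#' cell imaged in reflection on a silicon substrate. All lengths are in
#' micrometres. The default geometry follows WHO-typical head dimensions
#' (ellipse 4.5 x 3.0 um), a 4 um midpiece, and a 40 um tail whose thickness
#' defaults to 0.1 um — the ~100 nm scale that makes the tail the hardest
#' structure to image and motivates a high-sensitivity instrument.
#'
#' Phase is accumulated in double pass (reflection off the substrate), so a
#' local thickness `t` maps to phase `(4*pi/wavelength) * delta_n * t`.
#' Transmission users should halve this.
#'
#' @param image_height_px,image_width_px field of view in pixels.
#' @param pixel_pitch object-plane sampling (um/pixel); default 0.108
#'   (6.5 um camera pixel through a 60x objective).
#' @param wavelength illumination wavelength (um); default the He-Ne line.
#' @param refractive_index_contrast cell-medium refractive index difference.
#' @param head_axes length-2 numeric, full head ellipse axes (um).
#' @param head_max_thickness peak head thickness (um).
#' @param midpiece_length,midpiece_width,midpiece_thickness midpiece
#'   dimensions (um).
#' @param tail_length,tail_thickness,tail_width tail dimensions (um).
#' @param tail_waviness dimensionless multiplier on the lateral tail wave
#'   amplitude (1 = normal).
#' @param condition one of `"normal"`, `"cryo"`, `"h2o2"`, `"ethanol"`.
#' @param effect_size perturbation scale in \[0, 1\]; 0 reproduces the normal
#'   class exactly for any condition.
#' @param center cell centre in the image (um, `c(x, y)`); default field
#'   centre.
#' @param orientation head major-axis angle (radians).
#' @param scale isotropic size factor applied to the whole cell.
#' @param band_limit optional spectral band limit (cycles/pixel). When set,
#'   the phase map is low-pass apodized with a smooth (order-8
#'   super-Gaussian) window, emulating the finite optical resolution of the
#'   microscope. Band-limited maps are no longer exactly zero outside the
#'   cell silhouette.
#' @return object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(image_height_px = 512L, image_width_px = 512L,
                           pixel_pitch = 0.108, wavelength = 0.6328,
                           refractive_index_contrast = 0.05,
                           head_axes = c(4.5, 3.0), head_max_thickness = 2.5,
                           midpiece_length = 4.0, midpiece_width = 0.6,
                           midpiece_thickness = 0.6,
                           tail_length = 40, tail_thickness = 0.1,
                           tail_width = 0.45, tail_waviness = 1.0,
                           condition = "normal", effect_size = 1.0,
                           center = NULL, orientation = 0, scale = 1,
                           band_limit = NULL) {
  p <- list(image_height_px = as.integer(image_height_px),
            image_width_px = as.integer(image_width_px),
            pixel_pitch = pixel_pitch, wavelength = wavelength,
            refractive_index_contrast = refractive_index_contrast,
            head_axes = head_axes, head_max_thickness = head_max_thickness,
            midpiece_length = midpiece_length,
            midpiece_width = midpiece_width,
            midpiece_thickness = midpiece_thickness,
            tail_length = tail_length, tail_thickness = tail_thickness,
            tail_width = tail_width, tail_waviness = tail_waviness,
            condition = condition, effect_size = effect_size,
            center = center, orientation = orientation, scale = scale,
            band_limit = band_limit)
  validate_phantom_params(p)
  if (is.null(p$center)) {
    p$center <- c(p$image_width_px, p$image_height_px) / 2 * p$pixel_pitch
  }
  class(p) <- "phantom_params"
  p
}

validate_phantom_params <- function(p) {
  lens <- c(p$pixel_pitch, p$wavelength, p$head_axes, p$midpiece_length,
            p$midpiece_width, p$tail_length, p$tail_width)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all length parameters must be positive and finite")
  }
  # thicknesses may be zero (empty-object limit) but not negative
  if (p$head_max_thickness < 0 || p$tail_thickness < 0 ||
      p$midpiece_thickness < 0) {
    stop("thickness parameters must be non-negative")
  }
  if (p$image_height_px < 16L || p$image_width_px < 16L) {
    stop("field of view must be at least 16x16 pixels")
  }
  if (!p$condition %in% CLASS_LEVELS) {
    stop("unknown condition: ", p$condition)
  }
  if (p$effect_size < 0 || p$effect_size > 1) {
    stop("effect_size must lie in [0, 1]")
  }
  fw <- p$image_width_px * p$pixel_pitch
  fh <- p$image_height_px * p$pixel_pitch
  # conservative in-field check for the head at its nominal centre
  r <- max(p$head_axes) / 2 * p$scale * 1.25
  ctr <- if (is.null(p$center)) c(fw, fh) / 2 else p$center
  if (ctr[1] - r < 0 || ctr[1] + r > fw || ctr[2] - r < 0 || ctr[2] + r > fh) {
    stop("cell geometry exceeds the field of view")
  }
  invisible(p)
}

#' Construct a phase map object
#'
#' @param values numeric matrix of phase values (radians).
#' @param pixel_pitch sampling (um/pixel).
#' @param provenance `"phantom"` or `"reconstructed"`.
#' @param wavelength illumination wavelength (um), if known.
#' @param label optional class label.
#' @param meta free-form provenance list.
#' @return object of class `phase_map`.
#' @export
phase_map <- function(values, pixel_pitch, provenance = "phantom",
                      wavelength = NA_real_, label = NA_character_,
                      meta = list()) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 provenance = provenance, wavelength = wavelength,
                 label = label, meta = meta),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px, pitch %.4g um/px, provenance %s\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$provenance))
  cat(sprintf("  phase range [%.4g, %.4g] rad", min(x$values), max(x$values)))
  if (!is.na(x$label)) cat(", label ", x$label)
  cat("\n")
  invisible(x)
}

#' Generate a synthetic sperm-cell phase object
#'
#' Renders the three-compartment anatomy (elliptical head with cosine-taper
#' thickness, capsule midpiece, curved wavy tail) as a thickness map and
#' converts it to reflection-geometry phase
#' `phi = (4*pi/wavelength) * delta_n * t(x, y)`. The phase map is exactly
#' zero outside the cell silhouette (unless `band_limit` is set). Condition
#' perturbations encoded in `params$condition` / `params$effect_size` are
#' applied via [apply_condition()].
#'
#' @param params a [phantom_params()] object.
#' @param seed integer seed controlling the condition-perturbation textures.
#' @return a [phase_map()] with provenance `"phantom"`; `meta` carries the
#'   generating parameters, the tail-centerline curvature energy and the true
#'   head area.
#' @export
generate_phantom <- function(params, seed = 1L) {
  validate_phantom_params(params)
  base <- render_phantom(params, perturb = NULL)
  if (params$condition == "normal" || params$effect_size == 0) {
    out <- base
  } else {
    out <- apply_condition(base, params$condition, params$effect_size, seed)
  }
  if (!is.null(params$band_limit)) {
    out$values <- band_limit_field(out$values, params$band_limit)
    out$meta$band_limit <- params$band_limit
  }
  out
}

# Internal renderer: geometry -> thickness -> phase. `perturb` is NULL or a
# list(head_scale_a, head_scale_b, head_thickness_factor, waviness_factor,
#      roughness = list(amp, coef), texture = list(sd, field)).
render_phantom <- function(params, perturb = NULL) {
  p <- params
  nr <- p$image_height_px; nc <- p$image_width_px; pp <- p$pixel_pitch
  a <- p$head_axes[1] / 2
  b <- p$head_axes[2] / 2
  tmax <- p$head_max_thickness
  wav <- p$tail_waviness
  if (!is.null(perturb)) {
    a <- a * perturb$head_scale_a
    b <- b * perturb$head_scale_b
    tmax <- tmax * perturb$head_thickness_factor
    wav <- wav * perturb$waviness_factor
  }
  th <- p$orientation; sc <- p$scale
  cx <- p$center[1]; cy <- p$center[2]

  # cell-local coordinates (um): u along head major axis, tail towards -u
  X <- matrix(rep((seq_len(nc) - 1) * pp, each = nr), nr, nc)
  Y <- matrix(rep((seq_len(nr) - 1) * pp, times = nc), nr, nc)
  u <- (cos(th) * (X - cx) + sin(th) * (Y - cy)) / sc
  v <- (-sin(th) * (X - cx) + cos(th) * (Y - cy)) / sc

  t_map <- matrix(0, nr, nc)

  # head: normalized elliptical radius with optional boundary roughness
  rn <- sqrt((u / a)^2 + (v / b)^2)
  cand <- which(rn < 1.35)           # roughness never exceeds this margin
  if (length(cand)) {
    rr <- rn[cand]
    if (!is.null(perturb) && perturb$roughness$amp > 0) {
      ang <- atan2(v[cand], u[cand])
      rr <- rr / (1 + perturb$roughness$amp *
                    fourier_roughness(ang, perturb$roughness$coef))
    }
    inside <- rr < 1
    # flat top with a cosine edge taper over the outer 15% of the radius
    r0 <- 0.85
    t_head <- tmax *
      ifelse(rr[inside] <= r0, 1, cos(pi / 2 * (rr[inside] - r0) / (1 - r0)))
    if (!is.null(perturb) && perturb$texture$sd > 0) {
      g <- perturb$texture$field[cand][inside]
      t_head <- pmax(0, t_head * (1 + perturb$texture$sd * g))
    }
    idx <- cand[inside]
    t_map[idx] <- pmax(t_map[idx], t_head)
  }

  # midpiece: capsule from the head rim along -u with elliptic cross-section
  mp <- which(u < -0.85 * a & u > -(a + p$midpiece_length) &
                abs(v) < p$midpiece_width / 2)
  if (length(mp)) {
    t_mp <- p$midpiece_thickness *
      sqrt(pmax(0, 1 - (2 * v[mp] / p$midpiece_width)^2))
    t_map[mp] <- pmax(t_map[mp], t_mp)
  }

  # tail: quadratic bend + sinusoidal waviness, stamped along the centerline
  tl <- render_tail(p, a, wav, th, sc, cx, cy, nr, nc, pp)
  if (length(tl$idx)) {
    t_map[tl$idx] <- pmax(t_map[tl$idx], p$tail_thickness)
  }

  values <- (4 * pi / p$wavelength) * p$refractive_index_contrast * t_map
  phase_map(values, pp, provenance = "phantom", wavelength = p$wavelength,
            label = p$condition,
            meta = list(params = p,
                        tail_curvature_energy = tl$curv_energy,
                        head_area_um2 = pi * a * b * sc^2,
                        head_axes_eff = c(2 * a, 2 * b)))
}

# Tail centerline y(s) = q s^2 + A * wav * (s / L) * sin(2 pi s / P);
# returns stamped pixel indices and the centerline bending energy.
render_tail <- function(p, a, wav, th, sc, cx, cy, nr, nc, pp) {
  L <- p$tail_length
  A <- 1.0      # base lateral wave amplitude (um)
  P <- 12       # wave period along the tail (um)
  q <- 0.002    # quadratic bend (1/um)
  ds <- pp / 2
  s <- seq(0, L, by = ds)
  ys <- q * s^2 + A * wav * (s / L) * sin(2 * pi * s / P)
  us <- -(a + p$midpiece_length) - s
  # bending energy of the centerline (um^-1 scale), the h2o2 dose statistic
  ypp <- diff(diff(ys)) / ds^2
  curv_energy <- sum(ypp^2) * ds
  # to image coordinates (um)
  Xs <- cx + sc * (cos(th) * us - sin(th) * ys)
  Ys <- cy + sc * (sin(th) * us + cos(th) * ys)
  half_w <- p$tail_width / 2 * sc
  dw <- ceiling(half_w / pp) + 1L
  offs <- expand.grid(dr = -dw:dw, dc = -dw:dw)
  ns <- length(s)
  ctr_c <- round(Xs / pp) + 1L
  ctr_r <- round(Ys / pp) + 1L
  rr <- rep(ctr_r, times = nrow(offs)) + rep(offs$dr, each = ns)
  cc <- rep(ctr_c, times = nrow(offs)) + rep(offs$dc, each = ns)
  px_x <- (cc - 1L) * pp
  px_y <- (rr - 1L) * pp
  d2 <- (px_x - rep(Xs, times = nrow(offs)))^2 +
    (px_y - rep(Ys, times = nrow(offs)))^2
  keep <- d2 <= half_w^2 & rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  list(idx = unique((cc[keep] - 1L) * nr + rr[keep]),
       curv_energy = curv_energy)
}

# Low-order random Fourier series on the boundary angle, ~unit variance.
fourier_roughness <- function(theta, coef) {
  k <- seq_len(nrow(coef)) + 2L   # harmonics 3..(2+K)
  out <- 0
  for (i in seq_along(k)) {
    out <- out + coef[i, 1] * cos(k[i] * theta) + coef[i, 2] * sin(k[i] * theta)
  }
  out / sqrt(sum(coef^2) / 2 + 1e-12)
}

# Smooth order-8 super-Gaussian spectral apodization at radius f_b (cyc/px).
band_limit_field <- function(values, f_b) {
  nr <- nrow(values); nc <- ncol(values)
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  f <- sqrt(outer(fy^2, fx^2, `+`))
  h <- exp(-(f / f_b)^8)
  Re(fft(fft(values) * h, inverse = TRUE)) / (nr * nc)
}

#' Apply a stress-condition perturbation to a phantom phase map
#'
#' The four classes use parametric proxies for the qualitative membrane and
#' tail mechanisms reported for each stressor: cryopreservation reduces the
#' peak head phase (up to 30%) and roughens the head boundary; hydrogen
#' peroxide increases tail waviness (up to 3x) and adds head phase-texture
#' variance; ethanol increases head eccentricity and roughens the boundary.
#' All perturbation magnitudes scale monotonically with `effect_size`, and
#' `effect_size = 0` returns the input unchanged. These are tunable,
#' learnable class signatures, not biophysically validated models.
#'
#' @param base a phantom-provenance [phase_map()] (carries its generating
#'   parameters in `meta$params`).
#' @param condition one of `"normal"`, `"cryo"`, `"h2o2"`, `"ethanol"`.
#' @param effect_size perturbation scale in \[0, 1\].
#' @param seed integer seed for the roughness/texture draws.
#' @return a perturbed [phase_map()] (deterministic given arguments).
#' @export
apply_condition <- function(base, condition, effect_size, seed = 1L) {
  stopifnot(inherits(base, "phase_map"))
  if (base$provenance != "phantom" || is.null(base$meta$params)) {
    stop("apply_condition requires a phantom-provenance phase map")
  }
  if (!condition %in% CLASS_LEVELS) stop("unknown condition: ", condition)
  if (effect_size < 0 || effect_size > 1) stop("effect_size must be in [0, 1]")
  if (condition == "normal" || effect_size == 0) return(base)

  p <- base$meta$params
  e <- effect_size
  perturb <- with_seed(seed, {
    coef <- matrix(rnorm(12), ncol = 2)    # 6 boundary harmonics
    tex <- NULL
    if (condition == "h2o2") {
      tex <- smooth_noise_field(p$image_height_px, p$image_width_px, 4)
    }
    switch(condition,
      cryo = list(head_scale_a = 1, head_scale_b = 1,
                  head_thickness_factor = 1 - 0.30 * e,
                  waviness_factor = 1,
                  roughness = list(amp = 0.06 * e, coef = coef),
                  texture = list(sd = 0, field = NULL)),
      h2o2 = list(head_scale_a = 1, head_scale_b = 1,
                  head_thickness_factor = 1,
                  waviness_factor = 1 + 2 * e,
                  roughness = list(amp = 0, coef = coef),
                  texture = list(sd = 0.25 * e, field = tex)),
      ethanol = list(head_scale_a = 1 + 0.15 * e,
                     head_scale_b = 1 - 0.15 * e,
                     head_thickness_factor = 1,
                     waviness_factor = 1,
                     roughness = list(amp = 0.08 * e, coef = coef),
                     texture = list(sd = 0, field = NULL)))
  })
  p$condition <- condition
  p$effect_size <- e
  out <- render_phantom(p, perturb = perturb)
  out$label <- condition
  out
}

#' Generate a labeled four-class phantom dataset
#'
#' Draws `n_per_class` cells per condition class with per-cell pose jitter
#' (rotation uniform on \[0, 2*pi), translation uniform within a margin that
#' keeps the head in-field) and isotropic size jitter of +/-10%. Class sizes
#' in the source study were of order 2,400-2,750 per class; this generator
#' produces the same structure at whatever scale fits the analysis.
#'
#' @param n_per_class images per condition class (>= 1).
#' @param params base [phantom_params()]; pose fields are overridden by the
#'   jitter draws.
#' @param effect_size perturbation scale shared by the three stress classes.
#' @param seed master seed; the collection is deterministic given it.
#' @return a `phantom_dataset`: list with `maps` (list of [phase_map()]),
#'   `labels` (factor with levels normal, ethanol, h2o2, cryo) and `seed`.
#' @export
generate_dataset <- function(n_per_class, params = phantom_params(),
                             effect_size = 1.0, seed = 1L) {
  stopifnot(n_per_class >= 1)
  n_total <- 4L * n_per_class
  seeds <- derive_seeds(seed, n_total)
  fw <- params$image_width_px * params$pixel_pitch
  fh <- params$image_height_px * params$pixel_pitch
  margin <- max(params$head_axes) * 1.1 / 2 * 1.25  # head stays in-field
  poses <- with_seed(seed + 1L, list(
    rot = runif(n_total, 0, 2 * pi),
    cx = runif(n_total, margin, fw - margin),
    cy = runif(n_total, margin, fh - margin),
    sc = runif(n_total, 0.9, 1.1)))
  labels <- factor(rep(CLASS_LEVELS, each = n_per_class),
                   levels = CLASS_LEVELS)
  maps <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- params
    p$condition <- as.character(labels[i])
    p$effect_size <- effect_size
    p$orientation <- poses$rot[i]
    p$center <- c(poses$cx[i], poses$cy[i])
    p$scale <- poses$sc[i]
    maps[[i]] <- generate_phantom(p, seed = seeds[i])
  }
  structure(list(maps = maps, labels = labels, seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d phase maps (%s)\n", length(x$maps),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-condition class-separating summary statistic
#'
#' The dose statistic expected to grow with `effect_size` for each stress
#' class: `cryo` - reduction of the mean head phase relative to the head
#' peak scale; `h2o2` - tail-centerline curvature energy (from generator
#' metadata); `ethanol` - head eccentricity measured from image moments.
#'
#' @param map a phantom [phase_map()].
#' @param condition which statistic to compute (`"cryo"`, `"h2o2"`,
#'   `"ethanol"`).
#' @return scalar statistic.
#' @export
condition_statistic <- function(map, condition) {
  switch(condition,
    cryo = -head_mean_phase(map),
    h2o2 = map$meta$tail_curvature_energy,
    ethanol = {
      m <- segment_head(map)
      mask_eccentricity(m)
    },
    stop("no dose statistic defined for condition: ", condition))
}

head_mean_phase <- function(map) {
  m <- segment_head(map)
  mean(map$values[m])
}

# Eccentricity of a boolean mask from second-order central moments.
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- var(x) ; mu02 <- var(y)
  mu11 <- stats::cov(x, y)
  tr <- mu20 + mu02
  d <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + d) / 2; l2 <- (tr - d) / 2
  sqrt(pmax(0, 1 - l2 / l1))
}

#' Head-boundary roughness of a phantom
#'
#' Standard deviation of the radial deviation of the segmented head boundary
#' from its smooth (harmonics 0-2) description, in pixels. Grows with the
#' boundary-roughening perturbations of the cryo and ethanol classes.
#'
#' @param map a [phase_map()].
#' @return scalar roughness (pixels).
#' @export
head_boundary_roughness <- function(map) {
  mask <- segment_head(map)
  er <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(3, "box"))
  boundary <- mask & !(as.matrix(er) > 0.5)
  idx <- which(boundary, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)
  r <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
  basis <- cbind(1, cos(ang), sin(ang), cos(2 * ang), sin(2 * ang))
  fit <- stats::lm.fit(basis, r)
  sd(fit$residuals)
}
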