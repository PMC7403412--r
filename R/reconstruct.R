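#' Sideband filter for Fourier-transform demodulation
#'
#' @param center length-2 numeric, filter centre (cycles/pixel), typically
#'   the carrier estimate from [locate_carrier()].
#' @param radius filter radius (cycles/pixel); default 0.45 x the centre
#'   magnitude.
#' @param profile `"gaussian_soft"` (flat passband with a Gaussian edge
#'   rolloff — avoids the ringing of a hard mask at the low-amplitude tail)
#'   or `"hard"` (binary disk).
#' @return object of class `sideband_filter`.
#' @export
sideband_filter <- function(center, radius = NULL,
                            profile = c("gaussian_soft", "hard")) {
  profile <- match.arg(profile)
  mag <- sqrt(sum(center^2))
  if (is.null(radius)) radius <- 0.45 * mag
  if (radius <= 0) stop("filter radius must be positive")
  structure(list(center = as.numeric(center), radius = radius,
                 profile = profile), class = "sideband_filter")
}

# centred frequency coordinate grids (cycles/pixel) in fft bin order
freq_grids <- function(nr, nc) {
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  list(FY = matrix(rep(fy, times = nc), nr, nc),
       FX = matrix(rep(fx, each = nr), nr, nc))
}

# wrap a frequency difference into [-0.5, 0.5)
wrap_freq <- function(f) (f + 0.5) %% 1 - 0.5

#' Locate the carrier peak of an off-axis interferogram
#'
#' Finds the dominant magnitude-spectrum peak outside a DC exclusion disk,
#' reported in the half-plane `fy >= 0` (ties towards `fx > 0`) so that the
#' two conjugate sidebands of a real image map to one representative.
#'
#' @param igram an [interferogram()][synthesize()] or a plain intensity
#'   matrix.
#' @param dc_radius DC exclusion radius (cycles/pixel).
#' @param peak_factor detection threshold: the peak must exceed this factor
#'   times the median non-DC spectral magnitude.
#' @return length-2 numeric `c(fx, fy)` in cycles/pixel.
#' @export
locate_carrier <- function(igram, dc_radius = 0.02, peak_factor = 20) {
  intensity <- if (inherits(igram, "interferogram")) igram$intensity else igram
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (nr < 16L || nc < 16L) stop("image must be at least 16 px per dimension")
  S <- Mod(fft(intensity))
  g <- freq_grids(nr, nc)
  fmag <- sqrt(g$FX^2 + g$FY^2)
  dc_radius <- max(dc_radius, 3 / min(nr, nc))
  half <- (g$FY > 0) | (g$FY == 0 & g$FX > 0)
  valid <- half & fmag > dc_radius
  floor_level <- stats::median(S[fmag > dc_radius])
  peak <- which.max(ifelse(valid, S, -Inf))
  if (!valid[peak] || S[peak] <= peak_factor * floor_level) {
    stop("no carrier detected")
  }
  c(fx = g$FX[peak], fy = g$FY[peak])
}

#' Demodulate an off-axis interferogram to wrapped phase
#'
#' The Fourier-transform method: take the 2-D spectrum, select one sideband
#' with the filter, shift its centre bin to DC, inverse-transform to the
#' complex analytic signal `c(x, y)`, and read the wrapped phase as
#' `atan2(Im(c), Re(c))`, mapped into (-pi, pi].
#'
#' @param igram an [interferogram()][synthesize()] or intensity matrix.
#' @param filter a [sideband_filter()]; defaults to a filter at the located
#'   carrier.
#' @return object of class `wrapped_phase`: `values` in (-pi, pi],
#'   `modulation` = |c(x, y)|, `pixel_pitch`, and a `provenance` list
#'   (carrier, filter, warnings).
#' @export
demodulate <- function(igram, filter = NULL) {
  intensity <- if (inherits(igram, "interferogram")) igram$intensity else igram
  pitch <- if (inherits(igram, "interferogram")) igram$pixel_pitch else NA_real_
  if (is.null(filter)) filter <- sideband_filter(locate_carrier(igram))
  nr <- nrow(intensity); nc <- ncol(intensity)
  g <- freq_grids(nr, nc)
  d <- sqrt(wrap_freq(g$FX - filter$center[1])^2 +
              wrap_freq(g$FY - filter$center[2])^2)
  dc_dist <- sqrt(sum(filter$center^2))
  if (dc_dist <= filter$radius) {
    stop("sideband filter support overlaps DC; reduce the radius")
  }
  warnings <- character()
  if (filter$radius > dc_dist / 2) {
    warnings <- c(warnings,
                  "filter radius exceeds half the carrier distance")
  }
  W <- if (filter$profile == "hard") {
    (d <= filter$radius) * 1
  } else {
    r0 <- 0.6 * filter$radius
    sig <- 0.15 * filter$radius
    exp(-(pmax(d - r0, 0) / sig)^2 / 2)
  }
  W[1, 1] <- 0   # the filter support never includes the DC bin
  S <- fft(intensity) * W
  # circular shift so the carrier's integer bin moves to DC
  ky <- round(filter$center[2] * nr) %% nr
  kx <- round(filter$center[1] * nc) %% nc
  S <- S[c((ky + 1):nr, seq_len(ky))[seq_len(nr)], , drop = FALSE]
  S <- S[, c((kx + 1):nc, seq_len(kx))[seq_len(nc)], drop = FALSE]
  cxy <- fft(S, inverse = TRUE) / (nr * nc)
  values <- wrap_phase(atan2(Im(cxy), Re(cxy)))
  structure(list(values = values, modulation = Mod(cxy), pixel_pitch = pitch,
                 provenance = list(filter = filter, warnings = warnings)),
            class = "wrapped_phase")
}

#' @export
print.wrapped_phase <- function(x, ...) {
  cat(sprintf("<wrapped_phase> %d x %d px in (-pi, pi]\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subtract the background field from a reconstructed phase map
#'
#' `"reference_frame"` subtracts a cell-free reconstructed field pixel-wise;
#' `"polynomial"` fits a 2-D polynomial of the given order to the pixels
#' outside the cell mask and subtracts the fitted surface everywhere. After
#' subtraction the cell-free region has mean approximately zero.
#'
#' @param phase a [phase_map()].
#' @param mode `"polynomial"` (default) or `"reference_frame"`.
#' @param reference cell-free [phase_map()] (reference mode).
#' @param poly_order polynomial surface order (polynomial mode).
#' @param cell_mask logical matrix of cell pixels to exclude from the fit;
#'   when `NULL` it is derived automatically: the input is flattened with a
#'   first-order plane fit and pixels whose residual exceeds
#'   `max(0.05, 4 * mad)` are taken as cell, then dilated to be safe.
#' @return background-subtracted [phase_map()].
#' @export
subtract_background <- function(phase,
                                mode = c("polynomial", "reference_frame"),
                                reference = NULL, poly_order = 2L,
                                cell_mask = NULL) {
  mode <- match.arg(mode)
  v <- phase$values
  if (mode == "reference_frame") {
    if (is.null(reference)) stop("reference mode requires a reference frame")
    out <- v - reference$values
  } else {
    if (is.null(cell_mask)) {
      flat0 <- remove_plane(v)
      cell_mask <- flat0 > max(0.05, 4 * stats::mad(flat0))
      if (any(cell_mask)) {
        cell_mask <- as.matrix(EBImage::dilate(
          EBImage::Image(cell_mask * 1), EBImage::makeBrush(9, "disc"))) > 0.5
      }
    }
    nr <- nrow(v); nc <- ncol(v)
    xs <- rep(seq_len(nc), each = nr) / nc - 0.5
    ys <- rep(seq_len(nr), times = nc) / nr - 0.5
    terms <- expand.grid(i = 0:poly_order, j = 0:poly_order)
    terms <- terms[terms$i + terms$j <= poly_order, , drop = FALSE]
    basis <- mapply(function(i, j) xs^i * ys^j, terms$i, terms$j)
    bg <- !as.vector(cell_mask)
    if (sum(bg) < 10 * ncol(basis)) {
      stop("underdetermined background fit: too few cell-free pixels")
    }
    fit <- stats::lm.fit(basis[bg, , drop = FALSE], as.vector(v)[bg])
    out <- v - matrix(basis %*% fit$coefficients, nr, nc)
  }
  phase_map(out, phase$pixel_pitch, provenance = "reconstructed",
            wavelength = phase$wavelength, label = phase$label,
            meta = c(phase$meta, list(background_mode = mode)))
}
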