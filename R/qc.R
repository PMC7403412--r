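#' Binarize a phase map for cell detection
#'
#' Otsu thresholding on the positive-phase histogram (background pixels sit
#' at ~0 after background subtraction and would otherwise dominate the
#' histogram), followed by morphological closing with a 3-pixel disc — so
#' the thin, low-phase tail joins the head instead of fragmenting into many
#' components — and removal of components smaller than `min_component`.
#'
#' @param phase a [phase_map()].
#' @param threshold `"otsu"` or a fixed threshold in radians.
#' @param min_component components smaller than this many pixels are
#'   discarded as noise specks.
#' @return list with `mask` (logical), `threshold` (radians), `labels`
#'   (integer component matrix, 8-connected) and `component_count`.
#' @export
binarize_phase <- function(phase, threshold = "otsu", min_component = 50L) {
  v <- phase$values
  if (identical(threshold, "otsu")) {
    pos <- v[v > 0]
    threshold <- if (length(pos) > 100) otsu_threshold(pos) else 0.1
  }
  mask <- v > threshold
  if (any(mask)) {
    img <- EBImage::closing(EBImage::Image(mask * 1),
                            EBImage::makeBrush(7, "disc"))
    mask <- as.matrix(img) > 0.5
    lab <- label_components(mask)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes < min_component)
      if (length(drop)) {
        mask[lab %in% drop] <- FALSE
        lab <- label_components(mask)
      }
    }
  } else {
    lab <- matrix(0L, nrow(v), ncol(v))
  }
  list(mask = mask, threshold = threshold, labels = lab,
       component_count = max(lab))
}

# Otsu's threshold on a numeric sample (maximizes between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Check that an unwrapped phase map is trustworthy
#'
#' An image counts as correctly unwrapped when the residue density of its
#' wrapped input is at most `residue_density_max` residues per kilopixel and
#' at most a fraction `jump_fraction_max` of neighbouring-pixel differences
#' in the unwrapped map exceed pi.
#'
#' @param report the `report` from [unwrap_goldstein()], or `NULL` to derive
#'   the residue density by re-wrapping `phase`.
#' @param phase the unwrapped [phase_map()].
#' @param residue_density_max residues per kilopixel.
#' @param jump_fraction_max allowed fraction of > pi neighbour jumps.
#' @return logical.
#' @export
check_unwrap <- function(report, phase, residue_density_max = 1.0,
                         jump_fraction_max = 0.001) {
  v <- phase$values
  dens <- if (!is.null(report)) report$residue_density else
    nrow(compute_residues(wrap_phase(v))) / (length(v) / 1000)
  jumps <- c(abs(diff(v)), abs(t(diff(t(v)))))
  frac <- mean(jumps > pi)
  dens <= residue_density_max && frac <= jump_fraction_max
}

#' Check that the background of a phase map is flat
#'
#' @param phase a [phase_map()].
#' @param cell_mask logical matrix marking cell pixels (excluded).
#' @param rms_max maximum background RMS (radians).
#' @return logical.
#' @export
check_background <- function(phase, cell_mask, rms_max = 0.05) {
  bg <- phase$values[!cell_mask]
  if (!length(bg)) stop("empty background region: cell mask covers the image")
  sqrt(mean(bg^2)) <= rms_max
}

#' Single-cell retention check
#'
#' Binarizes the phase image, cleans it morphologically, and retains the
#' image only when exactly one connected component remains and its white
#' pixel count lies inside `[min_pixels, max_pixels]` — the automated
#' counterpart of the study's "one cell in the field of view" screen.
#'
#' @param phase a [phase_map()].
#' @param binarize_threshold `"otsu"` or radians.
#' @param min_pixels,max_pixels admissible white-pixel range; `max_pixels`
#'   defaults to 30% of the image area.
#' @return list `(ok, white_pixel_count, component_count)`.
#' @export
select_single_cell <- function(phase, binarize_threshold = "otsu",
                               min_pixels = 500L, max_pixels = NULL) {
  if (is.null(max_pixels)) max_pixels <- floor(0.3 * length(phase$values))
  if (is.numeric(binarize_threshold) && binarize_threshold <= 0) {
    stop("binarize_threshold must be positive")
  }
  stopifnot(min_pixels < max_pixels)
  b <- binarize_phase(phase, binarize_threshold)
  count <- sum(b$mask)
  ok <- b$component_count == 1L && count >= min_pixels && count <= max_pixels
  list(ok = ok, white_pixel_count = count,
       component_count = b$component_count)
}

#' Estimate the spatial phase sensitivity from empty-field maps
#'
#' Mean over the stack of the spatial standard deviation of each
#' reconstructed empty-field phase map after piston/tilt removal — the
#' figure of merit whose value is ~0.020 rad for a partially spatially
#' coherent instrument.
#'
#' @param phase_stack list of empty-field [phase_map()]s (>= 1).
#' @param border border width excluded from the statistics.
#' @return mean spatial phase std (radians).
#' @export
estimate_sensitivity <- function(phase_stack, border = 16L) {
  if (!length(phase_stack)) stop("empty phase stack")
  vals <- vapply(phase_stack, function(m) {
    flat <- remove_plane(m$values, border = border)
    sd(trim_border(flat, border))
  }, numeric(1))
  mean(vals)
}

#' Run the three-criterion retention screen over a dataset
#'
#' Applies, per image: the unwrap check, the background-flatness check, and
#' the single-cell check. An image is retained only if all three pass.
#'
#' @param dataset a `phantom_dataset` or plain list of [phase_map()]s.
#' @param residue_density_max,jump_fraction_max passed to [check_unwrap()].
#' @param background_rms_max passed to [check_background()].
#' @param min_pixels,max_pixels passed to [select_single_cell()].
#' @return list with `table` (one [data.frame] row per image: the three
#'   flags, `retained`, white-pixel and component counts, residue density
#'   and background RMS) and `retained` (indices of retained images).
#' @export
run_qc <- function(dataset, residue_density_max = 1.0,
                   jump_fraction_max = 0.001, background_rms_max = 0.05,
                   min_pixels = 500L, max_pixels = NULL) {
  maps <- if (inherits(dataset, "phantom_dataset")) dataset$maps else dataset
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    report <- m$meta$unwrap_report
    v <- m$values
    dens <- if (!is.null(report)) report$residue_density else
      nrow(compute_residues(wrap_phase(v))) / (length(v) / 1000)
    unwrap_ok <- check_unwrap(list(residue_density = dens), m,
                              residue_density_max, jump_fraction_max)
    sc <- select_single_cell(m, min_pixels = min_pixels,
                             max_pixels = max_pixels)
    cell_mask <- binarize_phase(m)$mask
    if (any(cell_mask)) {
      cell_mask <- as.matrix(EBImage::dilate(
        EBImage::Image(cell_mask * 1), EBImage::makeBrush(9, "disc"))) > 0.5
    }
    bg_rms <- if (all(cell_mask)) Inf else sqrt(mean(v[!cell_mask]^2))
    background_ok <- is.finite(bg_rms) && bg_rms <= background_rms_max
    data.frame(unwrap_ok = unwrap_ok, background_ok = background_ok,
               single_cell_ok = sc$ok,
               retained = unwrap_ok && background_ok && sc$ok,
               white_pixel_count = sc$white_pixel_count,
               component_count = sc$component_count,
               residue_density = dens, background_rms = bg_rms)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, retained = which(tab$retained))
}
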