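#' Segment the sperm head from a phase map
#'
#' Thresholds at 50% of the 99th percentile of the positive phase (the head
#' carries by far the largest optical thickness, so this isolates it from
#' midpiece and tail), opens with a small disc, and keeps the largest
#' 8-connected component.
#'
#' @param map a [phase_map()].
#' @return logical head mask (single connected component).
#' @export
segment_head <- function(map) {
  v <- map$values
  pos <- v[v > 0]
  if (!length(pos)) stop("cannot segment head: phase map has no positive phase")
  thr <- 0.5 * quantile(pos, 0.99, names = FALSE)
  mask <- v > thr
  if (!any(mask)) stop("cannot segment head: empty mask after thresholding")
  img <- EBImage::opening(EBImage::Image(mask * 1),
                          EBImage::makeBrush(5, "disc"))
  mask <- as.matrix(img) > 0.5
  lab <- label_components(mask)
  if (max(lab) == 0L) stop("cannot segment head: mask vanished after opening")
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Extract the 11 head features used by the classical classifiers
#'
#' Morphology of the segmented head (in physical units via the pixel pitch)
#' plus phase-texture statistics over the head region: area, perimeter,
#' major/minor axis, eccentricity, circularity, mean/max phase, phase
#' variance, skewness and entropy.
#'
#' @param phase a [phase_map()].
#' @param mask logical head mask, e.g. from [segment_head()].
#' @return named numeric vector of length 11.
#' @export
extract_features <- function(phase, mask) {
  npx <- sum(mask)
  if (npx < 2L) stop("degenerate head mask (fewer than 2 pixels)")
  pp <- phase$pixel_pitch
  mi <- EBImage::Image(mask * 1)
  shp <- EBImage::computeFeatures.shape(mi)
  mom <- EBImage::computeFeatures.moment(mi)
  area <- npx * pp^2
  perimeter <- shp[1, "s.perimeter"] * pp
  major <- mom[1, "m.majoraxis"] * pp
  ecc <- mom[1, "m.eccentricity"]
  minor <- major * sqrt(pmax(0, 1 - ecc^2))
  circularity <- min(1, 4 * pi * area / perimeter^2)
  ph <- phase$values[mask]
  p <- hist(ph, breaks = 32, plot = FALSE)$counts
  p <- p[p > 0] / sum(p)
  c(area = area, perimeter = perimeter, major_axis = major,
    minor_axis = minor, eccentricity = ecc, circularity = circularity,
    mean_phase = mean(ph), max_phase = max(ph), phase_variance = var(ph),
    phase_skewness = e1071::skewness(ph), phase_entropy = -sum(p * log(p)))
}

#' Extract the feature table for a whole dataset
#'
#' @param dataset a `phantom_dataset` or list of [phase_map()]s.
#' @return data frame with the 11 feature columns (and a `label` column when
#'   the dataset carries labels).
#' @export
extract_feature_table <- function(dataset) {
  maps <- if (inherits(dataset, "phantom_dataset")) dataset$maps else dataset
  feats <- t(vapply(maps, function(m) extract_features(m, segment_head(m)),
                    numeric(11)))
  out <- as.data.frame(feats)
  if (inherits(dataset, "phantom_dataset")) out$label <- dataset$labels
  out
}
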