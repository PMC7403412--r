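#' Write a phase map as 32-bit float TIFF with a JSON sidecar
#'
#' The TIFF stores values rescaled to \[0, 1\]; the affine mapping back to
#' radians (`scale`, `offset`) plus pixel pitch, wavelength, label and
#' generating parameters travel in `<path>.json`.
#'
#' @param map a [phase_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(map, path) {
  v <- map$values
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none")
  side <- list(scale = scale, offset = lo, pixel_pitch = map$pixel_pitch,
               wavelength = map$wavelength, provenance = map$provenance,
               label = map$label)
  if (!is.null(map$meta$params)) {
    side$params <- unclass(map$meta$params)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a phase map written by [write_phase_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return a [phase_map()].
#' @export
read_phase_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  phase_map(x * side$scale + side$offset, side$pixel_pitch,
            provenance = side$provenance %||% "reconstructed",
            wavelength = side$wavelength %||% NA_real_,
            label = side$label %||% NA_character_)
}

#' Write an interferogram as 16-bit grayscale TIFF with a JSON sidecar
#'
#' @param igram an interferogram from [synthesize()].
#' @param path output TIFF path.
#' @param label optional class label carried in the sidecar (so labels can
#'   follow simulated data through reconstruction).
#' @return `path`, invisibly.
#' @export
write_interferogram_tiff <- function(igram, path, label = NA_character_) {
  depth <- igram$noise$bit_depth
  tiff::writeTIFF(igram$intensity / (2^depth - 1), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(carrier = list(fx = igram$carrier$fx, fy = igram$carrier$fy),
         regime = igram$noise$regime, bit_depth = depth,
         pixel_pitch = igram$pixel_pitch, label = label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an interferogram written by [write_interferogram_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return an `interferogram` object.
#' @export
read_interferogram_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(intensity = round(x * (2^side$bit_depth - 1)),
                 carrier = carrier_spec(side$carrier$fx, side$carrier$fy),
                 noise = NULL, pixel_pitch = side$pixel_pitch,
                 label = side$label %||% NA_character_),
            class = "interferogram")
}
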