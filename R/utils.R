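#' Wrap phase values into the half-open interval (-pi, pi]
#'
#' Principal-value wrapping used throughout the pipeline: the convention keeps
#' +pi and maps -pi to +pi, so the interval is half-open.
#'
#' @param x numeric vector, matrix or array of phase values (radians).
#' @return object of the same shape with all values in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi))
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of per-item 31-bit seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Remove the best-fit plane (piston and tilt) from a phase image
#'
#' Least-squares fit of a + b*x + c*y over the (optionally border-trimmed)
#' image, subtracted everywhere. Used before computing spatial phase noise so
#' that residual carrier tilt does not inflate the estimate.
#'
#' @param values numeric matrix of phase values (radians).
#' @param border integer border width (pixels) excluded from the fit.
#' @return matrix of the same shape with the fitted plane removed.
#' @export
remove_plane <- function(values, border = 0L) {
  nr <- nrow(values); nc <- ncol(values)
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  keep <- rep(TRUE, length(values))
  if (border > 0L) {
    keep <- ys > border & ys <= nr - border & xs > border & xs <= nc - border
  }
  z <- as.vector(values)
  fit <- stats::lm.fit(cbind(1, xs[keep], ys[keep]), z[keep])
  b <- fit$coefficients
  matrix(z - (b[1] + b[2] * xs + b[3] * ys), nr, nc)
}

#' Interior of a matrix with a fixed border excluded
#'
#' Quantitative comparisons exclude a 16-pixel border by default, where FFT
#' periodicity artifacts live.
#'
#' @param values numeric matrix.
#' @param border border width (pixels).
#' @return the interior submatrix.
#' @export
trim_border <- function(values, border = 16L) {
  nr <- nrow(values); nc <- ncol(values)
  stopifnot(nr > 2 * border, nc > 2 * border)
  values[(border + 1L):(nr - border), (border + 1L):(nc - border)]
}

# Smooth unit-variance correlated Gaussian field: white noise convolved with
# a Gaussian of standard deviation `corr_len` pixels (circular convolution).
smooth_noise_field <- function(nr, nc, corr_len) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return(w)
  fy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  f2 <- outer(fy^2, fx^2, `+`)
  h <- exp(-2 * pi^2 * corr_len^2 * f2)
  g <- Re(fft(fft(w) * h, inverse = TRUE)) / length(w)
  g / sd(g)
}

# 8-connected component labelling (C++ backend); returns integer matrix.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_label8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}
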