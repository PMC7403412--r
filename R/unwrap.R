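#' Compute phase residues of a wrapped-phase image
#'
#' For every 2x2 pixel loop, sums the four wrapped pairwise differences taken
#' around the loop; a nonzero sum is +/-2*pi and marks a residue of charge
#' +/-1 — the obstruction to path-independent unwrapping that the Goldstein
#' algorithm neutralizes with branch cuts.
#'
#' @param wrapped a `wrapped_phase` or numeric matrix in (-pi, pi].
#' @return object of class `residue_map`: data frame with columns `row`,
#'   `col` (top-left pixel of the loop) and `charge` in \{-1, +1\}; the image
#'   dimensions are kept in `attr(, "dims")`.
#' @export
compute_residues <- function(wrapped) {
  psi <- if (inherits(wrapped, "wrapped_phase")) wrapped$values else wrapped
  nr <- nrow(psi); nc <- ncol(psi)
  stopifnot(nr >= 2L, nc >= 2L)
  A <- psi[-nr, -nc]; B <- psi[-nr, -1]; C <- psi[-1, -1]; D <- psi[-1, -nc]
  loop <- wrap_phase(B - A) + wrap_phase(C - B) +
    wrap_phase(D - C) + wrap_phase(A - D)
  charge <- round(loop / (2 * pi))
  idx <- which(charge != 0L, arr.ind = TRUE)
  res <- data.frame(row = idx[, 1], col = idx[, 2],
                    charge = as.integer(charge[idx]))
  if (nrow(res) && any(abs(res$charge) > 1L)) {
    stop("degenerate loop with |charge| > 1 encountered")
  }
  res <- res[order(res$row, res$col), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, dims = c(nr, nc), class = c("residue_map", "data.frame"))
}

#' Place Goldstein branch cuts
#'
#' Pairs opposite-charge residues by a growing-radius nearest-neighbour
#' search (residues visited in row-major order; equal distances broken by
#' row-major order of the candidate) and grounds a residue to the image
#' border when the border is strictly nearer than any available partner, or
#' when no partner lies within `max_search_radius`. Every residue ends up
#' discharged. Cut segments are rasterized onto a pixel mask with
#' 4-connected Bresenham lines.
#'
#' @param residues a [compute_residues()] result.
#' @param max_search_radius pairing search limit (pixels).
#' @return object of class `cut_mask`: `mask` (logical matrix) and
#'   `segments` (data frame of endpoints; border cuts have `to_border` TRUE).
#' @export
place_branch_cuts <- function(residues, max_search_radius = 64) {
  dims <- attr(residues, "dims")
  nr <- dims[1]; nc <- dims[2]
  mask <- matrix(FALSE, nr, nc)
  segs <- list()
  n <- nrow(residues)
  if (n > 0L) {
    done <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (done[i]) next
      ri <- residues$row[i]; ci <- residues$col[i]
      cand <- which(!done & residues$charge == -residues$charge[i])
      d_opp <- Inf; j <- NA_integer_
      if (length(cand)) {
        dd <- sqrt((residues$row[cand] - ri)^2 + (residues$col[cand] - ci)^2)
        j <- cand[which.min(dd)]       # ties: lowest row-major index wins
        d_opp <- min(dd)
      }
      d_border <- min(ri, ci, nr - ri, nc - ci)
      if (is.na(j) || d_border < d_opp || d_opp > max_search_radius) {
        # ground to the nearest border along a straight line
        end <- switch(which.min(c(ri, ci, nr - ri, nc - ci)),
                      c(1L, ci), c(ri, 1L), c(nr, ci), c(ri, nc))
        segs[[length(segs) + 1L]] <- data.frame(
          r1 = ri, c1 = ci, r2 = end[1], c2 = end[2], to_border = TRUE)
        mask <- rasterize_cut(mask, ri, ci, end[1], end[2])
        done[i] <- TRUE
      } else {
        segs[[length(segs) + 1L]] <- data.frame(
          r1 = ri, c1 = ci, r2 = residues$row[j], c2 = residues$col[j],
          to_border = FALSE)
        mask <- rasterize_cut(mask, ri, ci, residues$row[j], residues$col[j])
        done[i] <- TRUE; done[j] <- TRUE
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(r1 = integer(), c1 = integer(), r2 = integer(),
               c2 = integer(), to_border = logical())
  structure(list(mask = mask, segments = segments), class = "cut_mask")
}

# 4-connected Bresenham rasterization of one cut segment
rasterize_cut <- function(mask, r1, c1, r2, c2) {
  dr <- abs(r2 - r1); dc <- abs(c2 - c1)
  sr <- sign(r2 - r1); sc <- sign(c2 - c1)
  r <- r1; c <- c1
  mask[r, c] <- TRUE
  err <- dr - dc
  while (r != r2 || c != c2) {
    e2 <- 2 * err
    if (e2 > -dc && r != r2) {       # 4-connected: one axis step at a time
      err <- err - dc; r <- r + sr
    } else {
      err <- err + dr; c <- c + sc
    }
    mask[r, c] <- TRUE
  }
  mask
}

#' Flood-fill integration of wrapped phase behind branch cuts
#'
#' Breadth-first integration from a seed pixel: each newly reached pixel gets
#' its 4-neighbour's unwrapped value plus the wrapped difference. Cut pixels
#' act as barriers and are filled last by nearest-neighbour extension (also
#' congruent mod 2*pi) and flagged low-confidence.
#'
#' @param wrapped `wrapped_phase` or matrix in (-pi, pi].
#' @param cuts a [place_branch_cuts()] result (or NULL for no cuts).
#' @param seed_pixel integer `c(row, col)` to start from; must not lie on a
#'   cut.
#' @return list with `values` (unwrapped matrix) and `low_confidence`
#'   (logical matrix of cut/unreached pixels filled by extension).
#' @export
integrate_phase <- function(wrapped, cuts = NULL, seed_pixel = c(1L, 1L)) {
  psi <- if (inherits(wrapped, "wrapped_phase")) wrapped$values else wrapped
  cut <- if (is.null(cuts)) matrix(FALSE, nrow(psi), ncol(psi)) else cuts$mask
  if (cut[seed_pixel[1], seed_pixel[2]]) {
    stop("seed pixel lies on a branch cut; choose another seed")
  }
  res <- cpp_integrate(psi, matrix(as.integer(cut), nrow(cut), ncol(cut)),
                       as.integer(seed_pixel[1] - 1L),
                       as.integer(seed_pixel[2] - 1L))
  list(values = res$values, low_confidence = res$low_confidence > 0L)
}

#' Goldstein branch-cut phase unwrapping
#'
#' Composes residue detection, branch-cut placement and flood-fill
#' integration. The seed is the pixel of maximum fringe modulation |c(x, y)|
#' when the input carries one (i.e. came from [demodulate()]), otherwise the
#' first non-cut pixel in row-major order.
#'
#' @param wrapped `wrapped_phase` or matrix in (-pi, pi].
#' @param max_search_radius passed to [place_branch_cuts()].
#' @return list with `phase` (a [phase_map()], provenance
#'   `"reconstructed"`), and `report`: residue count, cut length (pixels),
#'   low-confidence pixel fraction.
#' @export
unwrap_goldstein <- function(wrapped, max_search_radius = 64) {
  psi <- if (inherits(wrapped, "wrapped_phase")) wrapped$values else wrapped
  pitch <- if (inherits(wrapped, "wrapped_phase")) wrapped$pixel_pitch else
    NA_real_
  residues <- compute_residues(psi)
  cuts <- place_branch_cuts(residues, max_search_radius)
  seed <- NULL
  if (inherits(wrapped, "wrapped_phase") && !is.null(wrapped$modulation)) {
    ord <- order(-wrapped$modulation)
    ok <- ord[!cuts$mask[ord]]
    if (length(ok)) seed <- ok[1]
  }
  if (is.null(seed)) {
    free <- which(!t(cuts$mask))        # row-major scan
    if (!length(free)) stop("no seedable pixel: cuts cover the image")
    k <- free[1] - 1L
    seed <- (k %% ncol(psi)) * nrow(psi) + (k %/% ncol(psi)) + 1L
  }
  sp <- c((seed - 1L) %% nrow(psi) + 1L, (seed - 1L) %/% nrow(psi) + 1L)
  res <- integrate_phase(psi, cuts, sp)
  report <- list(residue_count = nrow(residues),
                 cut_length = sum(cuts$mask),
                 low_confidence_fraction = mean(res$low_confidence),
                 residue_density = nrow(residues) / (length(psi) / 1000))
  list(phase = phase_map(res$values, pitch, provenance = "reconstructed",
                         meta = list(unwrap_report = report)),
       report = report)
}
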