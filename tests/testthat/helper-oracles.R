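# Independent oracles, deliberately implemented differently from the package.

# Itoh sequential line integration: unwrap the first column, then each row.
# Exact whenever the wrapped field is residue-free.
itoh_unwrap <- function(psi) {
  w <- function(d) atan2(sin(d), cos(d))
  col1 <- cumsum(c(psi[1, 1], w(diff(psi[, 1]))))
  out <- matrix(0, nrow(psi), ncol(psi))
  for (r in seq_len(nrow(psi))) {
    out[r, ] <- cumsum(c(col1[r], w(diff(psi[r, ]))))
  }
  out
}

# Brute-force residue oracle: explicit loop over every 2x2 loop with an
# atan2-based wrap (different principal-value formula from the package).
brute_residues <- function(psi) {
  w <- function(d) atan2(sin(d), cos(d))
  nr <- nrow(psi); nc <- ncol(psi)
  out <- matrix(0L, nr - 1, nc - 1)
  for (i in seq_len(nr - 1)) {
    for (j in seq_len(nc - 1)) {
      s <- w(psi[i, j + 1] - psi[i, j]) + w(psi[i + 1, j + 1] - psi[i, j + 1]) +
        w(psi[i + 1, j] - psi[i + 1, j + 1]) + w(psi[i, j] - psi[i + 1, j])
      out[i, j] <- as.integer(round(s / (2 * pi)))
    }
  }
  out
}

# residue_map -> dense charge matrix for comparison against the oracle
residues_as_matrix <- function(res) {
  dims <- attr(res, "dims")
  out <- matrix(0L, dims[1] - 1, dims[2] - 1)
  if (nrow(res)) out[cbind(res$row, res$col)] <- res$charge
  out
}

# smooth random phase field with controllable amplitude (residue-free for
# moderate amplitude)
smooth_field <- function(n, amplitude, seed, corr = 6) {
  set.seed(seed)
  f <- spermqpi:::smooth_noise_field(n, n, corr)
  amplitude * f
}

make_vortex <- function(n = 64, yc = 31.6, xc = 32.3) {
  outer(seq_len(n), seq_len(n), function(r, c) atan2(r - yc, c - xc))
}
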