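test_that("residue charges match the brute-force loop-integral oracle", {
  # smooth fields are residue-free; strong fields develop genuine residues
  for (s in 1:20) {
    psi <- wrap_phase(smooth_field(32, amplitude = 12, seed = s, corr = 2))
    expect_identical(residues_as_matrix(compute_residues(psi)),
                     brute_residues(psi))
  }
  ramp <- outer(seq_len(64), seq_len(64), function(r, c) 0.1 * c)
  expect_equal(nrow(compute_residues(wrap_phase(ramp))), 0)
})

test_that("vortex fields carry unit residues of the right sign", {
  vx <- wrap_phase(make_vortex())
  res <- compute_residues(vx)
  expect_equal(nrow(res), 1)
  expect_equal(res$charge, 1L)
  expect_equal(c(res$row, res$col), c(31L, 32L))
  # vortex + antivortex: one of each charge, total zero
  anti <- make_vortex(yc = 40.5, xc = 44.5)
  pair <- wrap_phase(make_vortex() - anti)
  res2 <- compute_residues(pair)
  expect_equal(sort(res2$charge), c(-1L, 1L))
  expect_equal(sum(res2$charge), 0L)
})

test_that("branch cuts pair opposite charges or ground to the border", {
  empty <- compute_residues(matrix(0, 32, 32))
  expect_equal(sum(place_branch_cuts(empty)$mask), 0)
  one <- structure(data.frame(row = 32L, col = 32L, charge = 1L),
                   dims = c(64L, 64L), class = c("residue_map", "data.frame"))
  cm <- place_branch_cuts(one)
  expect_true(cm$segments$to_border)
  expect_equal(sum(cm$mask), 32)   # straight run to the nearest border
  adj <- structure(data.frame(row = c(30L, 30L), col = c(30L, 31L),
                              charge = c(1L, -1L)),
                   dims = c(64L, 64L), class = c("residue_map", "data.frame"))
  cm2 <- place_branch_cuts(adj)
  expect_equal(nrow(cm2$segments), 1)
  expect_false(cm2$segments$to_border)
  expect_equal(sum(cm2$mask), 2)
})

test_that("integration is exact, congruent and path independent", {
  ramp <- outer(seq_len(64), seq_len(64), function(r, c) 0.1 * c + 0.05 * r)
  out <- integrate_phase(wrap_phase(ramp), NULL, c(1L, 1L))
  dev <- out$values - ramp
  expect_lt(diff(range(dev)), 1e-9)
  # congruence everywhere, including on extended pixels
  psi <- wrap_phase(smooth_field(48, 5, seed = 3))
  g <- unwrap_goldstein(psi)
  expect_lt(max(abs(wrap_phase(g$phase$values - psi))), 1e-9)
  # ten random seeds agree up to a 2*pi*k piston (residue-free input)
  expect_equal(nrow(compute_residues(psi)), 0)
  set.seed(1)
  ref <- integrate_phase(psi, NULL, c(1L, 1L))$values
  for (i in 1:10) {
    sp <- c(sample(48, 1), sample(48, 1))
    v <- integrate_phase(psi, NULL, sp)$values
    piston <- v[1, 1] - ref[1, 1]
    expect_equal(piston - 2 * pi * round(piston / (2 * pi)), 0,
                 tolerance = 1e-9)
    expect_lt(max(abs(v - ref - piston)), 1e-9)
  }
})

test_that("Goldstein equals the Itoh oracle on residue-free inputs", {
  for (s in 1:10) {
    field <- smooth_field(48, 6, seed = 100 + s)
    psi <- wrap_phase(field)
    if (nrow(compute_residues(psi)) > 0) next
    g <- unwrap_goldstein(psi)$phase$values
    io <- itoh_unwrap(psi)
    d <- g - io
    expect_lt(diff(range(d)), 1e-9)
    k <- d[1, 1] / (2 * pi)
    expect_equal(k - round(k), 0, tolerance = 1e-9)
  }
})

test_that("full unwrapping reports degeneracy and handles edge cases", {
  z <- unwrap_goldstein(matrix(0, 32, 32))
  expect_true(all(z$phase$values == 0))
  expect_equal(z$report$residue_count, 0)
  expect_equal(z$report$cut_length, 0)
  set.seed(6)
  noise <- matrix(runif(64 * 64, -pi, pi), 64, 64)
  n <- unwrap_goldstein(noise)
  expect_gt(n$report$residue_count, 100)
  expect_gt(n$report$low_confidence_fraction, 0)
  cuts <- place_branch_cuts(compute_residues(noise))
  on_cut <- which(cuts$mask, arr.ind = TRUE)[1, ]
  expect_error(integrate_phase(noise, cuts, on_cut), "reseed|seed")
})
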