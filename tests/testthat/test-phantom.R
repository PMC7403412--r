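test_that("phase follows the reflection-geometry closed form", {
  p <- small_params()
  m <- generate_phantom(p, seed = 1)
  # double-pass conversion at the head plateau
  expect_equal(max(m$values),
               4 * pi / p$wavelength * p$refractive_index_contrast *
                 p$head_max_thickness, tolerance = 1e-12)
  # 100 nm tail: (4*pi/0.6328) * 0.05 * 0.1 = 0.0993 rad
  tail_only <- generate_phantom(small_params(head_max_thickness = 0,
                                             midpiece_thickness = 0), seed = 1)
  expect_equal(max(tail_only$values), 4 * pi * 0.05 * 0.1 / 0.6328,
               tolerance = 1e-9)
  expect_true(all(is.finite(m$values)))
})

test_that("phase is linear in thickness and zero outside the silhouette", {
  p <- small_params()
  m1 <- generate_phantom(p, seed = 3)
  p2 <- p
  p2$head_max_thickness <- 2 * p$head_max_thickness
  p2$midpiece_thickness <- 2 * p$midpiece_thickness
  p2$tail_thickness <- 2 * p$tail_thickness
  m2 <- generate_phantom(p2, seed = 3)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)
  # single cell occupies well under 30% of the default 512x512 field
  md <- generate_phantom(phantom_params(), seed = 1)
  expect_lt(mean(md$values != 0), 0.30)
})

test_that("empty object produces an all-zero phase map", {
  p <- small_params(head_max_thickness = 0, midpiece_thickness = 0,
                    tail_thickness = 0)
  m <- generate_phantom(p, seed = 1)
  expect_true(all(m$values == 0))
})

test_that("zero effect size reproduces the normal class bit-identically", {
  base <- generate_phantom(small_params(), seed = 5)
  for (cond in c("cryo", "h2o2", "ethanol")) {
    p <- small_params(condition = cond, effect_size = 0)
    expect_identical(generate_phantom(p, seed = 5)$values, base$values)
    expect_identical(apply_condition(base, cond, 0, seed = 9)$values,
                     base$values)
  }
  expect_identical(apply_condition(base, "normal", 1, seed = 9)$values,
                   base$values)
})

test_that("condition perturbations are deterministic and monotone", {
  base <- generate_phantom(small_params(), seed = 7)
  a <- apply_condition(base, "h2o2", 0.5, seed = 21)
  b <- apply_condition(base, "h2o2", 0.5, seed = 21)
  expect_identical(a$values, b$values)
  # ethanol roughens the head boundary
  eth <- apply_condition(base, "ethanol", 1.0, seed = 21)
  expect_gt(head_boundary_roughness(eth), head_boundary_roughness(base))
  # dose statistics are monotone along the effect-size ladder
  for (cond in c("cryo", "h2o2", "ethanol")) {
    stats <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(e) {
      mean(vapply(1:8, function(s) {
        condition_statistic(apply_condition(base, cond, e, seed = s), cond)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(stats) > -1e-8),
                info = paste("non-monotone dose response for", cond))
  }
})

test_that("invalid phantom geometry and conditions are rejected", {
  expect_error(phantom_params(head_axes = c(-1, 3)), "positive")
  expect_error(phantom_params(condition = "heat"), "unknown condition")
  expect_error(phantom_params(effect_size = 2), "effect_size")
  expect_error(phantom_params(center = c(0.5, 0.5)), "field of view")
  base <- generate_phantom(small_params(), seed = 1)
  expect_error(apply_condition(base, "uv", 1), "unknown condition")
})

test_that("generate_dataset is labeled, complete and seed-deterministic", {
  p <- small_params()
  d1 <- generate_dataset(5, p, effect_size = 1, seed = 4)
  expect_length(d1$maps, 20)
  expect_equal(as.vector(table(d1$labels)), rep(5L, 4))
  d2 <- generate_dataset(5, p, effect_size = 1, seed = 4)
  expect_identical(lapply(d1$maps, `[[`, "values"),
                   lapply(d2$maps, `[[`, "values"))
  d3 <- generate_dataset(5, p, effect_size = 1, seed = 8)
  expect_false(identical(d1$maps[[1]]$values, d3$maps[[1]]$values))
})

test_that("classes are indistinguishable at zero effect size", {
  ds <- classification_dataset(0, n_per_class = 50L, seed = 13L)
  heads <- vapply(ds$maps, spermqpi:::head_mean_phase, numeric(1))
  ref <- heads[ds$labels == "normal"]
  for (cond in c("ethanol", "h2o2", "cryo")) {
    p <- t.test(ref, heads[ds$labels == cond])$p.value
    expect_gt(p, 0.01)
  }
})
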