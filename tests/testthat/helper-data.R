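# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small field keeps unit tests fast; pose/geometry structure is unchanged
small_params <- function(...) {
  phantom_params(image_height_px = 256L, image_width_px = 256L, ...)
}

classification_dataset <- function(effect_size, n_per_class = 200L,
                                   seed = 11L) {
  cached(sprintf("ds_e%s_n%d_s%d", effect_size, n_per_class, seed),
         generate_dataset(n_per_class, small_params(),
                          effect_size = effect_size, seed = seed))
}

feature_table_of <- function(effect_size, n_per_class = 200L, seed = 11L) {
  cached(sprintf("ft_e%s_n%d_s%d", effect_size, n_per_class, seed), {
    ds <- classification_dataset(effect_size, n_per_class, seed)
    extract_feature_table(ds)
  })
}

two_cell_map <- function(seed = 2L) {
  cached(sprintf("twocell_s%d", seed), {
    p <- small_params()
    m1 <- generate_phantom(p, seed)
    p2 <- p
    p2$center <- c(8, 8)
    m2 <- generate_phantom(p2, seed + 1L)
    phase_map(pmax(m1$values, m2$values), p$pixel_pitch)
  })
}
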