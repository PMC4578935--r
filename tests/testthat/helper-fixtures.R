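# Shared fixtures: small geometric masks and coordinate helpers, plus a
# lazily built desk-small study reused by several acceptance checks.

coord_arrays <- function(d) {
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(a) seq_len(d[a]) - ctr[a])
  list(
    x = array(rep(ax[[1]], times = d[2] * d[3]), d),
    y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d),
    z = array(rep(ax[[3]], each = d[1] * d[2]), d))
}

sphere_mask <- function(d, radius, center_off = c(0, 0, 0)) {
  co <- coord_arrays(d)
  (co$x - center_off[1])^2 + (co$y - center_off[2])^2 +
    (co$z - center_off[3])^2 <= radius^2
}

ellipsoid_mask <- function(d, axes) {
  co <- coord_arrays(d)
  (co$x / axes[1])^2 + (co$y / axes[2])^2 + (co$z / axes[3])^2 <= 1
}

# brain-like wobbly blob and a mask with an interior hole
blob_mask <- function(d, seed = 7) {
  set.seed(seed)
  spec <- phantom_spec(matrix = d, n_vessels = 0L, n_ventricles = 0L,
                       n_cavities = 0L, chi_tissue_spread_ppm = 0,
                       margin = 2L, seed = seed)
  make_phantom(spec)$mask
}

holed_mask <- function(d, radius) {
  m <- sphere_mask(d, radius)
  m & !sphere_mask(d, radius / 3)
}

sd_pop_t <- function(x) sqrt(mean((x - mean(x))^2))

# Coordinates (mm) relative to the mask center of mass, as used by polf().
com_coords <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  phys <- sweep(idx - 1, 2, grid$voxel_size, `*`)
  sweep(phys, 2, colMeans(phys))
}

# Small, fast Monte Carlo samples used by evaluation and CLI tests.
make_tiny_samples <- function(n = 2, seed = 91) {
  spec <- phantom_spec(matrix = c(36L, 40L, 30L), margin = 3L,
                       n_vessels = 2L, n_ventricles = 1L, n_cavities = 1L,
                       seed = seed)
  ph <- make_phantom(spec)
  lapply(seq_len(n), function(i) simulate_sample(ph, seed = seed + i))
}

# One desk-small Monte Carlo study (n = 10) with the four standard filters,
# built on first use and cached for the whole test session.
desk_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- simulate_study(n = 10L, seed = 1L, preset = "desk-small")
      rep <- run_study(st, filters = default_filter_set(gf_sigma = 2))
      cache <<- list(study = st, report = rep)
    }
    cache
  }
})
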