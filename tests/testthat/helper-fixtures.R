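# Shared fixtures: small descriptors and deterministic phantoms sized for
# test budgets (tiles of ~100 px instead of the instrument's 2048).

small_descriptor <- function(n_cols = 2, n_rows = 2, n_cycles = 4,
                             n_channels = 4, n_z = 1, tile = 96L,
                             overlap = 0.1) {
  experiment_descriptor(
    name = "synthexp",
    grid = grid_spec(n_cols, n_rows, overlap),
    channels = default_channels()[seq_len(n_channels), ],
    cycles = default_cycles(n_channels, n_cycles),
    n_z = n_z, tile_width = tile, tile_height = tile)
}

# phantom with the module defaults at small scale
small_phantom <- function(desc = small_descriptor(), seed = 1, ...) {
  generate_phantom(desc, n_nuclei = 60L, seed = seed, ...)
}

# clean phantom: no noise, no drift, flat shading/AF, in-focus
clean_phantom <- function(desc = small_descriptor(), seed = 1, ...) {
  generate_phantom(desc, n_nuclei = 40L, seed = seed,
                   af_variation = 0, shading_amplitude = 0,
                   drift_max = 0, noise_gain = 0, noise_sigma = 0,
                   defocus_slope = 0, ...)
}

# paint hard-edged disks of given intensities onto a matrix
paint_disks <- function(nrow, ncol, centers, radius, value = 1000) {
  img <- matrix(0, nrow, ncol)
  value <- rep_len(value, length(centers))
  for (i in seq_along(centers)) {
    ctr <- centers[[i]]
    for (r in seq_len(nrow)) for (cc in seq_len(ncol))
      if ((r - ctr[1])^2 + (cc - ctr[2])^2 < radius^2) img[r, cc] <- value[i]
  }
  img
}

# textured test image: smoothed noise, reproducible
textured <- function(nrow, ncol, seed = 7, sigma = 2) {
  set.seed(seed)
  gaussian_blur(matrix(rnorm(nrow * ncol), nrow, ncol), sigma)
}
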