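# Shading estimation/interpolation, blank-cycle background subtraction
# and the negative-value cleanup rule.

test_that("shading profile of flat tiles is identically 1", {
  tiles <- replicate(4, matrix(37.5, 48, 48), simplify = FALSE)
  for (mode in c("ratio", "smooth")) {
    p <- compute_shading_profile(tiles, sigma = 8, mode = mode)
    expect_lt(max(abs(p$field - 1)), 1e-9)
  }
})

test_that("single-position profile evaluates the stated formula", {
  tile <- abs(textured(48, 48)) + 1
  p <- compute_shading_profile(list(tile), sigma = 8)
  manual <- tile / gaussian_blur(tile, 8)
  manual <- manual / mean(manual)
  expect_equal(p$field, manual, tolerance = 1e-12)
})

test_that("correcting simulated vignetting reduces flat-region variation", {
  desc <- small_descriptor(n_cycles = 2, tile = 128L)
  truth <- generate_phantom(desc, n_nuclei = 0L, seed = 4,
                            af_variation = 0, shading_amplitude = 0.3,
                            drift_max = 0, noise_gain = 0, noise_sigma = 0,
                            defocus_slope = 0)
  # blank channel 2 of anchor cycle 1: pure flat AF x vignette
  tiles <- lapply(1:4, function(p)
    render_tile(truth, tile_key(1, p, 1, 2)))
  prof <- compute_shading_profile(tiles, sigma = 64)
  corrected <- apply_shading(tiles[[1]], pmax(prof$field, 1e-6))
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(tiles[[1]]) / cv(corrected), 2)
})

test_that("profile interpolation is exact at anchors and affine between", {
  first <- matrix(runif(64, 0.5, 1.5), 8, 8)
  last <- matrix(runif(64, 0.5, 1.5), 8, 8)
  expect_equal(interpolate_profile(first, last, 1, 6), first)
  expect_equal(interpolate_profile(first, last, 6, 6), last)
  expect_equal(interpolate_profile(first, last, 3, 6),
               first + 0.4 * (last - first))
  # second difference across consecutive cycles is zero
  f <- sapply(1:6, function(k) interpolate_profile(first, last, k, 6)[3, 5])
  expect_lt(max(abs(diff(diff(f)))), 1e-12)
  expect_equal(interpolate_profile(first, last, 1, 1), first)
})

test_that("apply_shading divides and preserves mean for unit-mean profiles", {
  tile <- abs(textured(32, 32, seed = 9)) + 2
  expect_equal(apply_shading(tile, matrix(1, 32, 32)), tile)
  profile <- matrix(runif(32 * 32, 0.7, 1.3), 32, 32)
  profile <- profile / mean(profile)
  flat <- matrix(5, 32, 32)
  expect_lt(max(abs(apply_shading(flat * profile, profile) - flat)), 1e-6)
  corrected <- apply_shading(tile, profile)
  expect_lt(abs(mean(corrected) - mean(tile)) / mean(tile), 0.05)
  expect_error(apply_shading(tile, matrix(1, 8, 8)), "shape")
  expect_error(apply_shading(tile, matrix(-1, 32, 32)), "positive")
})

test_that("background fields blur blanks and keep analytic peak height", {
  expect_lt(max(abs(compute_background(matrix(7, 40, 40), 5) - 7)), 1e-9)
  imp <- matrix(0, 81, 81); imp[41, 41] <- 1000
  sigma <- 10
  bg <- compute_background(imp, sigma)
  expect_equal(max(bg), 1000 / (2 * pi * sigma^2), tolerance = 0.01)
  expect_equal(which.max(bg), (41L - 1L) * 81L + 41L)  # stays centred
  expect_true(all(bg >= 0))
})

test_that("background subtraction interpolates between the anchors", {
  tile <- abs(textured(32, 32, seed = 2)) + 3
  z <- matrix(0, 32, 32)
  expect_equal(subtract_background(tile, z, z, 3, 6), tile)
  first <- matrix(2, 32, 32); last <- matrix(4, 32, 32)
  interp <- first + 0.4 * (last - first)
  expect_lt(max(abs(subtract_background(interp, first, last, 3, 6))), 1e-12)
  expect_error(subtract_background(tile, matrix(0, 4, 4), z, 1, 6), "shape")
})

test_that("negative-value cleanup follows the clip-then-rebase rule", {
  expect_equal(remove_negative_values(matrix(c(-5, 0, 3, 7), 1)),
               matrix(c(0, 0, 0, 4), 1))
  img <- matrix(c(2, 5, 0, 9), 2)
  out <- remove_negative_values(img)
  expect_equal(out, matrix(c(0, 3, 0, 7), 2))
  expect_equal(remove_negative_values(matrix(0, 3, 3)), matrix(0, 3, 3))
  # property: nonnegative output, zeros map to zeros
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rnorm(64, sd = 5), 8, 8)
    m[sample(64, 10)] <- 0
    out <- remove_negative_values(m)
    expect_true(all(out >= 0))
    expect_true(all(out[m == 0] == 0))
    if (any(out > 0)) expect_equal(min(out[out >= 0]), 0)
  }
})

test_that("full correction chain recovers markers on simulator tiles", {
  desc <- small_descriptor(n_cycles = 4, tile = 128L)
  truth <- generate_phantom(desc, n_nuclei = 50L, seed = 6,
                            drift_max = 0, defocus_slope = 0)
  nC <- n_cycles(desc)
  ch <- 2L; pos <- 1L
  # shading profiles from the blank anchor cycles of this channel
  prof <- lapply(c(1L, nC), function(cyc) {
    tiles <- lapply(seq_len(4), function(p)
      render_tile(truth, tile_key(cyc, p, 1, ch)))
    compute_shading_profile(tiles, sigma = 64)
  })
  shaded <- function(cyc) {
    field <- pmax(interpolate_profile(prof[[1]], prof[[2]], cyc, nC), 1e-6)
    apply_shading(render_tile(truth, tile_key(cyc, pos, 1, ch)), field)
  }
  first_bg <- compute_background(shaded(1), 10)
  last_bg <- compute_background(shaded(nC), 10)
  cyc <- 2L
  corrected <- subtract_background(shaded(cyc), first_bg, last_bg, cyc, nC)
  gt <- truth$marker_maps[[cyc]][[ch]]
  o <- truth$origins[pos, ]
  gt_tile <- gt[o$y0 + seq_len(128), o$x0 + seq_len(128)]
  marker_free <- gt_tile == 0
  expect_lt(abs(mean(corrected[marker_free])), 2 * truth$noise_sigma)
  marker <- gt_tile > 0
  expect_gt(cor(corrected[marker], gt_tile[marker]), 0.95)
})
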