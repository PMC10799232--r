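# Phase-correlation registration, cropping, and grid stitching.

test_that("phase correlation recovers constructed shifts exactly", {
  a <- textured(64, 64, seed = 41)
  same <- estimate_translation(a, a)
  expect_equal(c(same$dx, same$dy), c(0, 0))
  expect_gt(same$quality, 0.999)
  b <- cycleproc:::circshift(a, 3, -2)
  tr <- estimate_translation(a, b)
  expect_equal(c(tr$dx, tr$dy), c(3, -2))
  expect_error(estimate_translation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("subpixel refinement recovers fractional simulator drifts", {
  desc <- small_descriptor(n_cycles = 2, tile = 96L)
  errs <- c()
  for (seed in 1:5) {
    truth <- generate_phantom(desc, n_nuclei = 60L, seed = seed,
                              drift_max = 4, subpixel_drift = TRUE,
                              noise_gain = 0, noise_sigma = 1,
                              defocus_slope = 0)
    a <- render_tile(truth, tile_key(1, 1, 1, 1))
    b <- render_tile(truth, tile_key(2, 1, 1, 1))
    tr <- estimate_translation(a, b, subpixel = TRUE)
    errs <- c(errs, abs(tr$dx - truth$drifts[2, 1]),
              abs(tr$dy - truth$drifts[2, 2]))
  }
  expect_lt(max(errs), 0.25)
})

test_that("register_cycles anchors the reference and shares translations", {
  a <- textured(48, 48, seed = 42)
  tr <- register_cycles(list(a))
  expect_equal(c(tr[[1]]$dx, tr[[1]]$dy), c(0, 0))
  tiles <- list(a, cycleproc:::circshift(a, 3, -2), cycleproc:::circshift(a, -1, 4))
  trs <- register_cycles(tiles)
  expect_equal(sapply(trs, `[[`, "dx"), c(0, 3, -1))
  expect_equal(sapply(trs, `[[`, "dy"), c(0, -2, 4))
  expect_error(register_cycles(list(a, NULL, a)), "cycle 2")
  expect_error(register_cycles(list(a), reference_cycle = 2), "reference")
})

test_that("crop_to_common uses symmetric ceil margins and aligns cycles", {
  a <- textured(64, 64, seed = 43)
  tiles <- list(list(a, a * 2),
                list(cycleproc:::circshift(a, 3, -2),
                     cycleproc:::circshift(a * 2, 3, -2)))
  trs <- register_cycles(lapply(tiles, `[[`, 1))
  cropped <- crop_to_common(tiles, trs)
  expect_equal(dim(cropped[[1]][[1]]), c(64 - 4, 64 - 6))
  expect_equal(dim(cropped[[2]][[2]]), c(60, 58))
  # all cycles overlay exactly after alignment (integer shifts)
  expect_equal(cropped[[1]][[1]], cropped[[2]][[1]])
  expect_equal(cropped[[1]][[2]], cropped[[2]][[2]])
  # zero translations: no cropping
  same <- crop_to_common(list(list(a)), list(cycleproc:::translation(0, 0)))
  expect_equal(dim(same[[1]][[1]]), c(64, 64))
  big <- list(cycleproc:::translation(0, 0), cycleproc:::translation(40, 0))
  expect_error(crop_to_common(list(list(a), list(a)), big), "too large")
})

stitch_fixture <- function(seed = 44, n_cols = 2, n_rows = 2, tile = 120L,
                           overlap = 0.1, n_nuclei = 80L) {
  desc <- small_descriptor(n_cols = n_cols, n_rows = n_rows, n_cycles = 2,
                           tile = tile, overlap = overlap)
  truth <- generate_phantom(desc, n_nuclei = n_nuclei, seed = seed,
                            drift_max = 0, noise_gain = 1, noise_sigma = 2,
                            defocus_slope = 0, shading_amplitude = 0,
                            af_variation = 0)
  tiles <- lapply(seq_len(n_positions(desc)), function(p)
    render_tile(truth, tile_key(1, p, 1, 1)))
  list(desc = desc, truth = truth, tiles = tiles)
}

test_that("pairwise offsets match the simulator's nominal spacing", {
  fx <- stitch_fixture()
  off <- estimate_pairwise_offsets(fx$tiles, fx$desc$grid)
  expect_equal(nrow(off), 4)  # 2 horizontal + 2 vertical seams on 2x2
  expect_true(all(abs(off$offset_x - off$nominal_x) <= 1))
  expect_true(all(abs(off$offset_y - off$nominal_y) <= 1))
  expect_false(any(off$fallback))
  # 1x1 grid: no seams
  d1 <- grid_spec(1, 1)
  expect_equal(nrow(estimate_pairwise_offsets(fx$tiles[1], d1)), 0)
})

test_that("an injected stage error on one seam is detected", {
  desc <- small_descriptor(n_cols = 2, n_rows = 2, n_cycles = 2, tile = 120L)
  truth <- generate_phantom(desc, n_nuclei = 80L, seed = 45, drift_max = 0,
                            noise_gain = 1, noise_sigma = 2,
                            defocus_slope = 0, shading_amplitude = 0,
                            af_variation = 0)
  truth$origins$x0[2] <- truth$origins$x0[2] + 2L  # tile 2 parked 2 px off
  tiles <- lapply(1:4, function(p) render_tile(truth, tile_key(1, p, 1, 1)))
  off <- estimate_pairwise_offsets(tiles, desc$grid)
  seam <- off[off$from == 1 & off$to == 2, ]
  expect_equal(seam$offset_x - seam$nominal_x, 2)
  other <- off[!(off$from == 1 & off$to == 2) & !(off$from == 2 | off$to == 2), ]
  expect_true(all(other$offset_x == other$nominal_x))
})

test_that("global positions follow nominal spacing and ground truth", {
  # nominal-offset row: W = 200, 10% overlap -> x = 0, 180, 360
  g <- grid_spec(3, 1, 0.1)
  off <- data.frame(from = c(1, 2), to = c(2, 3), direction = "h",
                    offset_x = c(180, 180), offset_y = c(0, 0),
                    nominal_x = 180, nominal_y = 0, quality = 1,
                    fallback = FALSE)
  lay <- solve_global_positions(off, g, 200L, 150L)
  expect_equal(lay$positions$x, c(0, 180, 360))
  expect_equal(lay$positions$y, c(0, 0, 0))
  expect_equal(lay$mosaic_width, 560L)

  # simulator 2x2: recovered within 1 px of the ground-truth origins
  fx <- stitch_fixture(seed = 46)
  off <- estimate_pairwise_offsets(fx$tiles, fx$desc$grid)
  lay <- solve_global_positions(off, fx$desc$grid, 120L, 120L)
  gt <- fx$truth$origins
  expect_true(all(abs(lay$positions$x - (gt$x0 - min(gt$x0))) <= 1))
  expect_true(all(abs(lay$positions$y - (gt$y0 - min(gt$y0))) <= 1))

  single <- solve_global_positions(off[0, ], grid_spec(1, 1), 64L, 32L)
  expect_equal(single$mosaic_width, 64L)
  expect_equal(single$mosaic_height, 32L)
  expect_error(solve_global_positions(off[1, , drop = FALSE],
                                      grid_spec(3, 1, 0.1), 10L, 10L),
               "disconnected")
})

test_that("mosaic composition blends seams and preserves single tiles", {
  tile <- textured(32, 32, seed = 47) + 10
  lay <- solve_global_positions(data.frame()[0, ], grid_spec(1, 1), 32L, 32L)
  expect_equal(compose_mosaic(list(tile), lay), tile)

  # two tiles cut from one plane: overlap blend reproduces the plane
  plane <- textured(32, 60, seed = 48) + 10
  t1 <- plane[, 1:32]; t2 <- plane[, 29:60]
  g <- grid_spec(2, 1, 0.125)
  off <- data.frame(from = 1, to = 2, direction = "h", offset_x = 28,
                    offset_y = 0, nominal_x = 28, nominal_y = 0,
                    quality = 1, fallback = FALSE)
  lay2 <- solve_global_positions(off, g, 32L, 32L)
  mosaic <- compose_mosaic(list(t1, t2), lay2)
  expect_equal(dim(mosaic), c(32, 60))
  expect_equal(mosaic, plane, tolerance = 1e-12)

  # simulator 2x2 mosaic approximates the ground-truth plane off-seam
  fx <- stitch_fixture(seed = 49)
  off2 <- estimate_pairwise_offsets(fx$tiles, fx$desc$grid)
  lay3 <- solve_global_positions(off2, fx$desc$grid, 120L, 120L)
  m <- compose_mosaic(fx$tiles, lay3)
  truth_plane <- (fx$truth$marker_maps[[1]][[1]] +
                    fx$truth$autofluorescence[[1]]$first)
  o <- fx$truth$origins
  mg <- fx$truth$margin
  gt_crop <- truth_plane[mg + seq_len(nrow(m)), mg + seq_len(ncol(m))]
  resid <- m - gt_crop
  noise_sd <- sqrt(mean(gt_crop) + 4)  # Poisson + read noise
  expect_lt(sqrt(mean(resid^2)), 3 * noise_sd)
})
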