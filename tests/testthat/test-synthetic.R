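# Simulator: determinism, forward-model limits, and the on-disk layout.

test_that("phantom generation and rendering are deterministic in the seed", {
  desc <- small_descriptor(n_cycles = 2, tile = 64L)
  t1 <- generate_phantom(desc, n_nuclei = 20L, seed = 9)
  t2 <- generate_phantom(desc, n_nuclei = 20L, seed = 9)
  expect_equal(t1$nuclei, t2$nuclei)
  expect_equal(t1$drifts, t2$drifts)
  k <- tile_key(2, 3, 1, 1)
  expect_identical(render_tile(t1, k), render_tile(t2, k))
  t3 <- generate_phantom(desc, n_nuclei = 20L, seed = 10)
  expect_false(identical(t1$nuclei, t3$nuclei))
})

test_that("n_nuclei = 0 leaves only autofluorescence in marker maps", {
  desc <- small_descriptor(n_cycles = 2, tile = 64L)
  truth <- generate_phantom(desc, n_nuclei = 0L, seed = 2,
                            noise_gain = 0, noise_sigma = 0,
                            drift_max = 0, defocus_slope = 0)
  blank <- blank_matrix(desc)
  tile <- render_tile(truth, tile_key(1, 1, 1, 2))
  af <- truth$autofluorescence[[2]]$first
  o <- truth$origins[1, ]
  expected <- af[o$y0 + seq_len(64), o$x0 + seq_len(64)] *
    truth$shading[[2]]$first
  expect_equal(tile, expected, tolerance = 1e-12)
})

test_that("clean in-focus tiles equal the cropped ground-truth field", {
  desc <- small_descriptor(n_cycles = 2, tile = 64L, n_z = 3)
  truth <- clean_phantom(desc, seed = 5)
  z_focus <- (desc$n_z + 1) / 2
  key <- tile_key(1, 2, z_focus, 1)
  tile <- render_tile(truth, key)
  field <- truth$marker_maps[[1]][[1]] + truth$autofluorescence[[1]]$first
  o <- truth$origins[2, ]
  expect_equal(tile, field[o$y0 + seq_len(64), o$x0 + seq_len(64)],
               tolerance = 1e-12)
})

test_that("injected drift appears as the cross-correlation peak", {
  desc <- small_descriptor(n_cycles = 2, tile = 96L)
  truth <- clean_phantom(desc, seed = 3)
  truth$drifts[2, ] <- c(3, -2)
  a <- render_tile(truth, tile_key(1, 1, 1, 1))
  b <- render_tile(truth, tile_key(2, 1, 1, 1))
  # brute-force integer cross-correlation over a +/- 5 px search
  best <- c(NA, NA); best_v <- -Inf
  for (dx in -5:5) for (dy in -5:5) {
    rs <- (1 + abs(dy)):(96 - abs(dy)); cs <- (1 + abs(dx)):(96 - abs(dx))
    v <- cor(as.vector(a[rs - dy, cs - dx]), as.vector(b[rs, cs]))
    if (v > best_v) { best_v <- v; best <- c(dx, dy) }
  }
  expect_equal(best, c(3, -2))
})

test_that("blank-cycle tiles contain only autofluorescence and shading", {
  desc <- small_descriptor(n_cycles = 3, tile = 64L)
  truth <- generate_phantom(desc, n_nuclei = 30L, seed = 8,
                            noise_gain = 0, noise_sigma = 0,
                            drift_max = 0, defocus_slope = 0)
  expect_null(truth$marker_maps[[1]][[3]])
  tile <- render_tile(truth, tile_key(1, 1, 1, 3))
  o <- truth$origins[1, ]
  af <- truth$autofluorescence[[3]]$first
  expect_equal(tile, af[o$y0 + seq_len(64), o$x0 + seq_len(64)] *
                 truth$shading[[3]]$first, tolerance = 1e-12)
})

test_that("ground-truth nuclei per tile match the global list geometrically", {
  desc <- small_descriptor(tile = 96L)
  truth <- generate_phantom(desc, n_nuclei = 50L, seed = 12)
  total <- 0
  for (pos in 1:4) {
    local <- nuclei_in_tile(truth, pos)
    o <- truth$origins[pos, ]
    expect_true(all(local$x >= 0 & local$x <= 96))
    back_global <- local$x + o$x0
    sel <- truth$nuclei$x > o$x0 & truth$nuclei$x <= o$x0 + 96 &
      truth$nuclei$y > o$y0 & truth$nuclei$y <= o$y0 + 96
    expect_equal(sort(back_global), sort(truth$nuclei$x[sel]))
    total <- total + nrow(local)
  }
  expect_gte(total, 50)  # overlap regions counted in two tiles
})

test_that("write_acquisition emits the documented layout and counts", {
  desc <- small_descriptor(n_cols = 2, n_rows = 2, n_cycles = 2,
                           n_channels = 4, n_z = 11, tile = 16L)
  truth <- generate_phantom(desc, n_nuclei = 5L, seed = 1)
  dir <- withr::local_tempdir()
  write_acquisition(truth, dir)
  # 4 positions x 11 Z x 4 channels = 176 files per cycle folder
  for (cyc in 1:2)
    expect_length(list.files(file.path(dir, cycle_folder_name(cyc)),
                             pattern = "\\.tif$"), 176)
  expect_true(file.exists(file.path(dir, "Experiment.json")))
  expect_true(file.exists(file.path(dir, "channelNames.txt")))
  expect_length(list.files(dir, pattern = "^cyc"), 2)

  # single-everything acquisition: exactly one TIFF
  d1 <- experiment_descriptor(name = "one", grid = grid_spec(1, 1),
                              channels = default_channels()[1, , drop = FALSE],
                              cycles = list("DAPI"), n_z = 1,
                              tile_width = 16L, tile_height = 16L)
  t1 <- generate_phantom(d1, n_nuclei = 1L, seed = 1)
  dir1 <- withr::local_tempdir()
  write_acquisition(t1, dir1, write_ground_truth = FALSE)
  expect_length(list.files(file.path(dir1, "cyc01")), 1)
})

test_that("written acquisitions are byte-identical under a fixed seed", {
  desc <- small_descriptor(n_cycles = 2, tile = 32L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_acquisition(generate_phantom(desc, n_nuclei = 10L, seed = 4), d1)
  write_acquisition(generate_phantom(desc, n_nuclei = 10L, seed = 4), d2)
  f1 <- list.files(d1, recursive = TRUE, pattern = "\\.tif$")
  expect_gt(length(f1), 0)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), raw(), 1e6),
                     readBin(file.path(d2, f), raw(), 1e6))
})
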