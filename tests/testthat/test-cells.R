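# Segmentation, boundary polygons and per-cell measurement.

test_that("well-separated bright disks are counted exactly", {
  img <- paint_disks(100, 100, list(c(15, 15), c(15, 80), c(50, 50),
                                    c(85, 20), c(80, 80)), 7, 800)
  lab <- segment_nuclei(img)
  expect_equal(attr(lab, "n_labels"), 5)
  ids <- sort(unique(lab[lab > 0]))
  expect_equal(ids, 1:5)
})

test_that("blank and constant images yield zero labels", {
  lab <- segment_nuclei(matrix(0, 30, 30))
  expect_equal(attr(lab, "n_labels"), 0)
  expect_true(all(lab == 0))
  expect_equal(attr(segment_nuclei(matrix(5, 30, 30)), "n_labels"), 0)
})

test_that("touching disks are split by the seeded watershed", {
  # centres 1.8 r apart: overlap of 20% of the radius
  img <- paint_disks(70, 70, list(c(28, 35), c(28 + round(1.8 * 8), 35)), 8,
                     1000)
  lab <- segment_nuclei(img)
  expect_equal(attr(lab, "n_labels"), 2)
  sizes <- table(lab[lab > 0])
  expect_gt(min(sizes) / max(sizes), 0.6)  # roughly even split
})

test_that("plugin segmenters slot in behind the same contract", {
  img <- paint_disks(40, 40, list(c(20, 20)), 6, 500)
  plug <- function(x) matrix(as.integer(x > 100) * 7L, nrow(x), ncol(x))
  lab <- segment_nuclei(img, method = "plugin", plugin = plug)
  expect_equal(attr(lab, "n_labels"), 1)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
})

test_that("boundary polygons rasterise back to their labels", {
  lab <- matrix(0L, 30, 30)
  lab[10:19, 5:14] <- 1L   # 10x10 square
  rois <- labels_to_rois(lab)
  expect_length(rois, 1)
  poly <- rois[[1]]$coords
  mask <- rasterize_polygon(poly, 30, 30)
  expect_equal(sum(mask), 100)
  expect_true(all(mask == (lab == 1L)))

  expect_length(labels_to_rois(matrix(0L, 5, 5)), 0)

  img <- paint_disks(80, 80, list(c(20, 20), c(20, 60), c(60, 40)), 7, 900)
  lab2 <- segment_nuclei(img)
  rois2 <- labels_to_rois(lab2)
  expect_length(rois2, attr(lab2, "n_labels"))
  expect_equal(vapply(rois2, `[[`, character(1), "name"),
               as.character(seq_along(rois2)))
  for (roi in rois2) {
    id <- as.integer(roi$name)
    mask <- rasterize_polygon(roi$coords, 80, 80)
    region <- lab2 == id
    # agreement up to a 1-px boundary band
    core <- region & !label_boundaries(lab2)
    expect_true(all(mask[core]))
    outside <- !region
    grown <- label_boundaries(lab2)
    expect_lt(mean(mask[outside]), 0.02)
  }
})

test_that("measurements report exact means, centroids and invariances", {
  lab <- matrix(0L, 80, 80)
  for (r in 1:80) for (c in 1:80) {
    if ((r - 41)^2 + (c - 51)^2 <= 100) lab[r, c] <- 1L
    if ((r - 15)^2 + (c - 15)^2 <= 25) lab[r, c] <- 2L
  }
  intens <- matrix(100, 80, 80)
  cells <- measure_cells(lab, list(cyc02_ch2_CD3e = intens))
  expect_equal(nrow(cells), 2)
  expect_equal(cells$mean_cyc02_ch2_CD3e, c(100, 100))
  # symmetric disk centred at (x=50, y=40) in 0-based coordinates
  expect_lt(abs(cells$centroid_x[1] - 50), 0.5)
  expect_lt(abs(cells$centroid_y[1] - 40), 0.5)
  expect_true(all(cells$circularity > 0.7 & cells$circularity <= 1 + 1e-6))
  expect_equal(cells$area, c(sum(lab == 1L), sum(lab == 2L)))

  # permutation invariance of the measured quantities
  perm <- lab
  perm[lab == 1L] <- 2L; perm[lab == 2L] <- 1L
  cells_p <- measure_cells(perm, list(cyc02_ch2_CD3e = intens))
  expect_equal(cells_p$area, rev(cells$area))
  expect_equal(cells_p$centroid_x, rev(cells$centroid_x))

  expect_error(measure_cells(lab, list(a = matrix(0, 4, 4))), "shape")
  empty <- measure_cells(matrix(0L, 10, 10), list())
  expect_equal(nrow(empty), 0)
})

test_that("simulator nuclei are recovered with centroid accuracy", {
  desc <- small_descriptor(n_cols = 1, n_rows = 1, n_cycles = 2, tile = 160L)
  truth <- generate_phantom(desc, n_nuclei = 12L, seed = 13,
                            drift_max = 0, defocus_slope = 0,
                            shading_amplitude = 0, af_variation = 0,
                            radius_range = c(5, 7), min_separation = 24)
  tile <- render_tile(truth, tile_key(1, 1, 1, 1))
  # SNR: nuclear level 3000 over AF 300 with noise sd ~sqrt(3300) = 57
  lab <- segment_nuclei(tile)
  gt <- nuclei_in_tile(truth, 1)
  expect_equal(attr(lab, "n_labels"), nrow(gt))
  cells <- measure_cells(lab)
  # match each ground-truth nucleus to the nearest centroid (1-based -> 0-based)
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((cells$centroid_x - (gt$x[i] - 1))^2 +
                (cells$centroid_y - (gt$y[i] - 1))^2)
    expect_lt(min(d), 2)
  }
})
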