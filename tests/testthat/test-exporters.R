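# Measurement table, CSV/FCS writers, ImageJ ROI archive, overlay image
# and the output tree.

make_table <- function(n = 3) {
  cells <- data.frame(label = seq_len(n),
                      centroid_x = seq_len(n) * 10.5,
                      centroid_y = seq_len(n) * 3.25,
                      area = seq_len(n) * 7,
                      perimeter = rep(12, n), circularity = rep(0.9, n),
                      orientation = rep(5, n),
                      mean_cyc02_ch2_CD3e = seq_len(n) + 0.125,
                      mean_cyc02_ch3_CD20 = seq_len(n) * 2 + 0.5)
  measurement_table(cells)
}

test_that("measurement table uses the fixed column contract", {
  tab <- make_table(3)
  expect_equal(dim(tab), c(3L, 6L))
  expect_equal(names(tab), c("cell_id", "x", "y", "size",
                             "cyc02_ch2_CD3e", "cyc02_ch3_CD20"))
  cells <- data.frame(label = 1:2, centroid_x = 1, centroid_y = 2, area = 3,
                      perimeter = 4, circularity = 0.5, orientation = 0,
                      mean_cyc02_ch2_X = 9)
  shaped <- measurement_table(cells, include_shape = TRUE)
  expect_equal(names(shaped), c("cell_id", "x", "y", "size", "cyc02_ch2_X",
                                "perimeter", "circularity", "orientation"))
})

test_that("CSV writer round-trips, including the empty table", {
  dir <- withr::local_tempdir()
  tab <- make_table(3)
  f <- file.path(dir, "m.csv")
  write_measurements_csv(tab, f)
  back <- read_measurements_csv(f)
  expect_equal(names(back), names(tab))
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12,
               ignore_attr = TRUE)

  empty <- make_table(0)
  f0 <- file.path(dir, "empty.csv")
  write_measurements_csv(empty, f0)
  expect_length(readLines(f0), 1)  # header only
  expect_equal(nrow(read_measurements_csv(f0)), 0)
})

test_that("FCS files round-trip through the independent reader", {
  dir <- withr::local_tempdir()
  set.seed(51)
  tab <- data.frame(a = rnorm(100) * 1000, b = runif(100, 0, 65535),
                    c = rpois(100, 40), d = rnorm(100), e = rnorm(100),
                    f = seq_len(100))
  f <- file.path(dir, "t.fcs")
  write_fcs(tab, f)
  back <- read_fcs(f)
  expect_equal(back$keywords[["$PAR"]], "6")
  expect_equal(back$keywords[["$TOT"]], "100")
  expect_equal(names(back$data), names(tab))
  for (nm in names(tab)) {
    scale <- pmax(abs(tab[[nm]]), 1)
    expect_lt(max(abs(back$data[[nm]] - tab[[nm]]) / scale), 1e-5)
  }

  f0 <- file.path(dir, "empty.fcs")
  write_fcs(make_table(0), f0)
  b0 <- read_fcs(f0)
  expect_equal(b0$keywords[["$TOT"]], "0")
  expect_equal(nrow(b0$data), 0)
  expect_error(write_fcs(data.frame(), file.path(dir, "bad.fcs")),
               "zero parameters")
})

test_that("CSV and FCS encode identical numbers", {
  dir <- withr::local_tempdir()
  tab <- make_table(25)
  fc <- file.path(dir, "m.csv"); ff <- file.path(dir, "m.fcs")
  write_measurements_csv(tab, fc)
  write_fcs(tab, ff)
  csv <- read_measurements_csv(fc)
  fcs <- read_fcs(ff)$data
  for (j in seq_along(csv))
    expect_lt(max(abs(csv[[j]] - fcs[[j]]) / pmax(abs(csv[[j]]), 1)), 1e-5)
})

test_that("ImageJ ROI archives round-trip through the independent reader", {
  dir <- withr::local_tempdir()
  sq <- list(name = "1", coords = cbind(x = c(5L, 14L, 14L, 5L),
                                        y = c(7L, 7L, 16L, 16L)))
  f <- file.path(dir, "r.zip")
  write_roi_zip(list(sq), f)
  back <- read_roi_zip(f)
  expect_length(back, 1)
  expect_equal(unname(back[["1"]]), unname(sq$coords))

  # many ROIs, names preserved
  many <- lapply(1:500, function(i)
    list(name = as.character(i),
         coords = cbind(x = c(0L, 3L, 3L, 0L) + i %% 7,
                        y = c(0L, 0L, 3L, 3L) + i %% 5)))
  fm <- file.path(dir, "many.zip")
  write_roi_zip(many, fm)
  bm <- read_roi_zip(fm)
  expect_length(bm, 500)
  expect_equal(names(bm), as.character(1:500))

  f0 <- file.path(dir, "none.zip")
  write_roi_zip(list(), f0)
  expect_true(file.exists(f0))
  expect_length(read_roi_zip(f0), 0)

  bad <- list(name = "x", coords = cbind(x = c(1L, 2L), y = c(1L, 2L)))
  expect_error(write_roi_zip(list(bad), file.path(dir, "bad.zip")),
               "3 vertices")
})

test_that("segmentation-derived ROIs survive the archive round-trip", {
  img <- paint_disks(60, 60, list(c(20, 20), c(40, 45)), 7, 700)
  lab <- segment_nuclei(img)
  rois <- labels_to_rois(lab)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cells.zip")
  write_roi_zip(rois, f)
  back <- read_roi_zip(f)
  expect_length(back, length(rois))
  for (i in seq_along(rois))
    expect_equal(unname(back[[rois[[i]]$name]]),
                 unname(rois[[i]]$coords))
})

test_that("outline overlays draw exactly the label boundaries", {
  dir <- withr::local_tempdir()
  lab <- matrix(0L, 20, 20)
  lab[5:12, 6:13] <- 1L
  f <- file.path(dir, "o.tif")
  write_outline_overlay(lab, f, color = c(0, 255, 0))
  img <- read_tiff(f)
  drawn <- img[, , 2] > 0
  expect_equal(drawn, label_boundaries(lab))
  expect_true(all(img[, , c(1, 3)] == 0))
  interior <- lab == 1L & !label_boundaries(lab)
  expect_true(all(!drawn[interior]))

  f0 <- file.path(dir, "black.tif")
  write_outline_overlay(matrix(0L, 10, 10), f0)
  expect_true(all(read_tiff(f0) == 0))
})

test_that("the output tree is deterministic and guarded", {
  mosaics <- list(cyc01_CH1 = matrix(100, 16, 16),
                  cyc02_CH2 = matrix(200, 16, 16))
  lab <- matrix(0L, 16, 16); lab[4:9, 4:9] <- 1L
  tab <- make_table(2)
  rois <- labels_to_rois(lab)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- export_output_layout(mosaics, tab, rois, lab, d1, logs = "run")
  m2 <- export_output_layout(mosaics, tab, rois, lab, d2, logs = "run")
  j1 <- jsonlite::fromJSON(m1); j2 <- jsonlite::fromJSON(m2)
  expect_equal(j1$files$md5, j2$files$md5)
  expect_setequal(dirname(j1$files$path),
                  c("mosaics", "segmentation", "segmentation", "measurements",
                    "measurements", "rois", "logs"))
  # checksums in the manifest match the files on disk
  expect_equal(unname(tools::md5sum(file.path(d1, j1$files$path))),
               j1$files$md5)
  expect_error(export_output_layout(mosaics, tab, rois, lab, d1), "overwrite")
  expect_error(export_output_layout(list(), tab, rois, lab,
                                    withr::local_tempdir()), "no mosaics")
})
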