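# Nuclei segmentation on the stitched reference-cycle nuclear mosaic,
# label handling, boundary polygons and per-cell measurements. The
# classical segmenter (normalisation, smoothing, Otsu, distance-transform
# watershed with h-maxima seeds) carries core correctness; `method =
# "plugin"` accepts any external callable returning a label image, so a
# learned model can be dropped in without touching the pipeline.

#' Otsu threshold of a numeric image
#'
#' Maximises between-class variance over a fixed-bin histogram.
#'
#' @param img numeric matrix.
#' @param n_bins histogram bins.
#' @return threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(pmax(findInterval(
    v, seq(rng[1], rng[2], length.out = n_bins + 1L),
    rightmost.closed = TRUE), 1L), n_bins), n_bins)
  p <- h / sum(h)
  centers <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] -
    diff(rng) / (2 * n_bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  centers[which.max(between)]
}

#' Segment nuclei in a 2D image
#'
#' Classical pipeline: percentile normalisation (1st-99th), Gaussian
#' smoothing, Otsu threshold, exact Euclidean distance transform, h-maxima
#' seed detection, seeded watershed split of touching nuclei, and a
#' minimum-area filter. Labels are relabelled to the contiguous range
#' `1..N`. A blank image yields zero labels.
#'
#' @param img numeric matrix (nuclear-stain mosaic).
#' @param method `"classical"` or `"plugin"`.
#' @param smooth_sigma Gaussian smoothing sigma, px.
#' @param h h-maxima depth on the distance transform, px.
#' @param min_area minimum object area, px^2.
#' @param plugin for `method = "plugin"`: a `function(img) -> integer
#'   label matrix`.
#' @return integer label matrix with attribute `n_labels`; background 0.
#' @export
segment_nuclei <- function(img, method = c("classical", "plugin"),
                           smooth_sigma = 1.5, h = 0.5, min_area = 20L,
                           plugin = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), length(img) > 0)
  if (method == "plugin") {
    if (!is.function(plugin)) stop("method='plugin' needs a plugin function")
    lab <- plugin(img)
    stopifnot(is.matrix(lab), identical(dim(lab), dim(img)))
    return(relabel_sequential(matrix(as.integer(lab), nrow(lab), ncol(lab))))
  }
  rng <- quantile(img, c(0.01, 0.99), names = FALSE)
  if (rng[2] <= rng[1]) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  norm <- pmin(pmax((img - rng[1]) / (rng[2] - rng[1]), 0), 1)
  sm <- if (smooth_sigma > 0) gaussian_blur(norm, smooth_sigma) else norm
  thr <- otsu_threshold(sm)
  mask <- matrix(as.integer(sm > thr), nrow(sm), ncol(sm))
  if (!any(mask == 1L)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "n_labels") <- 0L
    return(out)
  }
  dist <- cp_distance_transform(mask)
  # h-maxima seeds: regional maxima of the h-reconstruction of the EDT
  hm <- cp_reconstruct(dist - h, dist)
  delta <- min(h, 0.5)
  rm <- cp_reconstruct(hm - delta, hm)
  seeds_mask <- matrix(as.integer(hm - rm >= delta / 2 & mask == 1L),
                       nrow(mask), ncol(mask))
  seeds <- cp_label_components(seeds_mask)
  if (attr(seeds, "n_labels") == 0L) seeds <- cp_label_components(mask)
  lab <- cp_watershed(dist, seeds, mask)
  # minimum-area filter, then make labels contiguous
  if (min_area > 0) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  relabel_sequential(lab)
}

#' Relabel a label image to the contiguous range 1..N
#'
#' @param lab integer matrix, 0 = background.
#' @return relabelled matrix with attribute `n_labels`.
#' @export
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  out <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  out[lab == 0L] <- 0L
  attr(out, "n_labels") <- length(ids)
  out
}

#' Boundary polygons of all labels
#'
#' Traces the outer boundary of every label (Moore neighbourhood,
#' clockwise) and returns one polygon per label in 0-based mosaic pixel
#' coordinates. Rasterising a polygon recovers its label region up to a
#' 1-px boundary band.
#'
#' @param lab integer label matrix.
#' @return list of ROIs; each has `name` (the label id as text) and
#'   `coords` (n x 2 matrix of 0-based x, y vertices).
#' @export
labels_to_rois <- function(lab) {
  n <- length(unique(lab[lab > 0L]))
  ids <- sort(unique(lab[lab > 0L]))
  lapply(ids, function(id) {
    coords <- cp_trace_boundary(lab, as.integer(id))
    list(name = as.character(id), coords = coords)
  })
}

#' Rasterise a polygon ROI back to a pixel mask
#'
#' Even-odd fill of pixel centres plus the boundary vertices themselves;
#' used to verify the polygon round-trip.
#'
#' @param coords n x 2 matrix of 0-based x, y vertices.
#' @param nrow,ncol output mask size.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(coords, nrow, ncol) {
  mask <- matrix(FALSE, nrow, ncol)
  if (nrow(coords) == 0) return(mask)
  xs <- coords[, 1]; ys <- coords[, 2]
  n <- length(xs)
  for (r in seq_len(nrow)) {
    py <- r - 1L
    j <- n
    crossings <- numeric(0)
    for (i in seq_len(n)) {
      yi <- ys[i]; yj <- ys[j]
      if ((yi > py) != (yj > py)) {
        crossings <- c(crossings, xs[i] + (py - yi) / (yj - yi) * (xs[j] - xs[i]))
      }
      j <- i
    }
    crossings <- sort(crossings)
    k <- 1
    while (k + 1 <= length(crossings)) {
      c0 <- ceiling(crossings[k]); c1 <- floor(crossings[k + 1])
      if (c1 >= c0) {
        cc <- pmin(pmax(c0:c1 + 1L, 1L), ncol)
        mask[r, cc] <- TRUE
      }
      k <- k + 2
    }
  }
  mask[cbind(pmin(pmax(ys + 1L, 1L), nrow), pmin(pmax(xs + 1L, 1L), ncol))] <- TRUE
  mask
}

#' Measure every cell across all channel mosaics
#'
#' One record per label: unweighted pixel centroid (0-based mosaic frame),
#' area, perimeter (length of the traced boundary polygon, diagonal steps
#' weighted sqrt(2)), circularity `4 pi area / perimeter^2`, orientation
#' from second central moments (degrees in (-90, 90]), and the mean
#' intensity over the label's pixels in every supplied mosaic.
#'
#' @param lab integer label matrix.
#' @param mosaics named list of mosaics sharing `lab`'s shape; names
#'   become intensity column suffixes (e.g. `"cyc02_ch2_CD3e"`).
#' @return data.frame with one row per label: `label`, `centroid_x`,
#'   `centroid_y`, `area`, `perimeter`, `circularity`, `orientation`, and
#'   one `mean_<name>` column per mosaic.
#' @export
measure_cells <- function(lab, mosaics = list()) {
  stopifnot(is.matrix(lab))
  for (m in mosaics)
    if (!identical(dim(m), dim(lab)))
      stop("mosaic shape does not match the label image")
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    out <- data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      orientation = numeric(0))
    for (nm in names(mosaics)) out[[paste0("mean_", nm)]] <- numeric(0)
    return(out)
  }
  px <- which(lab > 0L)
  lbl <- lab[px]
  rowi <- (px - 1L) %% nrow(lab) + 1L
  coli <- (px - 1L) %/% nrow(lab) + 1L
  f <- factor(lbl, levels = ids)
  area <- as.numeric(table(f))
  cx <- tapply(coli - 1L, f, mean)   # 0-based x
  cy <- tapply(rowi - 1L, f, mean)
  # second central moments -> orientation
  orientation <- vapply(seq_along(ids), function(k) {
    sel <- lbl == ids[k]
    x <- coli[sel] - 1 - cx[k]; y <- rowi[sel] - 1 - cy[k]
    mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
    ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (ang <= -90) ang + 180 else if (ang > 90) ang - 180 else ang
  }, numeric(1))
  perimeter <- vapply(ids, function(id) {
    b <- cp_trace_boundary(lab, as.integer(id))
    if (nrow(b) < 2) return(4)  # isolated pixel: unit square
    d <- sqrt(diff(c(b[, 1], b[1, 1]))^2 + diff(c(b[, 2], b[1, 2]))^2)
    sum(d)
  }, numeric(1))
  circ <- pmin(4 * pi * area / pmax(perimeter, 1e-9)^2, 1 + 1e-6)
  out <- data.frame(label = ids, centroid_x = as.numeric(cx),
                    centroid_y = as.numeric(cy), area = area,
                    perimeter = perimeter, circularity = circ,
                    orientation = orientation)
  for (nm in names(mosaics)) {
    v <- mosaics[[nm]][px]
    out[[paste0("mean_", nm)]] <- as.numeric(tapply(v, f, mean))
  }
  rownames(out) <- NULL
  out
}
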