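# Synthetic acquisition simulator. Generates a phantom tissue plane plus
# the physical nuisances the pipeline corrects — camera-frame vignetting,
# tissue autofluorescence drifting linearly across cycles, per-cycle stage
# drift, Z defocus, Poisson/Gaussian noise — and writes raw tiles in the
# exact on-disk layout of a real acquisition, with ground truth kept for
# verification.

#' Generate a phantom acquisition ground truth
#'
#' Builds the full-mosaic-plane ground truth for a synthetic cycle
#' acquisition: randomly placed nuclei (soft-edged disks) visible in the
#' nuclear channel of every cycle, per-nucleus reporter levels in every
#' non-blank (cycle, channel), smooth autofluorescence fields at the two
#' blank anchor cycles (interpolated linearly in between, which is exactly
#' the model the correction stages assume), a camera-frame polynomial
#' vignette per channel and anchor cycle, integer (optionally subpixel)
#' stage drift per cycle, and Z defocus growing linearly away from the
#' focal plane.
#'
#' @param desc an [experiment_descriptor()].
#' @param n_nuclei number of nuclei to scatter over the plane.
#' @param seed integer seed; the phantom and every rendered tile are
#'   reproducible functions of it.
#' @param nuclear_level peak nuclear-stain intensity (counts).
#' @param marker_level_range range of per-nucleus reporter levels (counts),
#'   sampled log-uniformly.
#' @param af_level mean autofluorescence level (counts).
#' @param af_variation relative spatial/anchor variation of
#'   autofluorescence (0..1).
#' @param shading_amplitude corner falloff of the vignette (0..1).
#' @param drift_max maximum per-cycle stage drift magnitude, px.
#' @param subpixel_drift if `TRUE` drifts are continuous, else integer.
#' @param noise_gain Poisson gain (counts per photon); 0 disables shot noise.
#' @param noise_sigma Gaussian read-noise sigma (counts); 0 disables.
#' @param defocus_sigma0 blur sigma at the focal plane, px (0 = sharp).
#' @param defocus_slope blur sigma increase per Z plane away from focus.
#' @param radius_range nucleus radius range, px.
#' @param min_separation minimum centre-to-centre distance between nuclei,
#'   px (0 = unconstrained; positions are rejection-sampled, and fewer
#'   than `n_nuclei` may be placed if the plane is crowded).
#' @param margin guard margin around the mosaic plane, px (absorbs drift).
#' @return an object of class `phantom_truth`.
#' @export
generate_phantom <- function(desc, n_nuclei = 150L, seed = 1L,
                             nuclear_level = 3000,
                             marker_level_range = c(500, 4000),
                             af_level = 300, af_variation = 0.2,
                             shading_amplitude = 0.3,
                             drift_max = 8, subpixel_drift = FALSE,
                             noise_gain = 1, noise_sigma = 2,
                             defocus_sigma0 = 0, defocus_slope = 1.5,
                             radius_range = c(4, 7), min_separation = 0,
                             margin = 16L) {
  stopifnot(inherits(desc, "experiment_descriptor"), n_nuclei >= 0)
  set.seed(as.integer(seed))
  g <- desc$grid
  W <- desc$tile_width; H <- desc$tile_height
  step_x <- as.integer(round(W * (1 - g$overlap_fraction)))
  step_y <- as.integer(round(H * (1 - g$overlap_fraction)))
  plane_w <- 2L * margin + step_x * (g$n_cols - 1L) + W
  plane_h <- 2L * margin + step_y * (g$n_rows - 1L) + H
  nC <- n_cycles(desc); nch <- n_channels(desc)
  blank <- blank_matrix(desc)

  # nuclei inside the imaged area (margin excluded); optionally
  # rejection-sampled to keep a minimum separation
  xs <- ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n_nuclei && attempts < 50L * max(n_nuclei, 1L)) {
    attempts <- attempts + 1L
    x <- runif(1, margin + radius_range[2], plane_w - margin - radius_range[2])
    y <- runif(1, margin + radius_range[2], plane_h - margin - radius_range[2])
    if (min_separation > 0 && length(xs) &&
        min((xs - x)^2 + (ys - y)^2) < min_separation^2) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  nuclei <- data.frame(x = xs, y = ys,
                       radius = runif(length(xs), radius_range[1],
                                      radius_range[2]))
  n_nuclei <- length(xs)

  paint_disks <- function(levels) {
    field <- matrix(0, plane_h, plane_w)
    for (i in seq_len(nrow(nuclei))) {
      cx <- nuclei$x[i]; cy <- nuclei$y[i]; rad <- nuclei$radius[i]
      xr <- max(1, floor(cx - rad - 2)):min(plane_w, ceiling(cx + rad + 2))
      yr <- max(1, floor(cy - rad - 2)):min(plane_h, ceiling(cy + rad + 2))
      dx <- outer(rep(1, length(yr)), xr - cx)
      dy <- outer(yr - cy, rep(1, length(xr)))
      d <- sqrt(dx^2 + dy^2)
      w <- pmin(pmax(rad + 0.5 - d, 0), 1)  # 1-px soft edge
      field[yr, xr] <- pmax(field[yr, xr], levels[i] * w)
    }
    field
  }

  nuclear_map <- paint_disks(rep(nuclear_level, max(n_nuclei, 0)))

  # per-nucleus reporter level for every non-blank, non-nuclear slot
  lr <- log(marker_level_range)
  marker_levels <- list(); marker_maps <- list()
  for (cyc in seq_len(nC)) {
    marker_levels[[cyc]] <- vector("list", nch)
    marker_maps[[cyc]] <- vector("list", nch)
    for (ch in seq_len(nch)) {
      if (ch == desc$reference_channel) {
        marker_maps[[cyc]][[ch]] <- nuclear_map
        marker_levels[[cyc]][[ch]] <- rep(nuclear_level, n_nuclei)
      } else if (!blank[cyc, ch]) {
        lv <- exp(runif(n_nuclei, lr[1], lr[2]))
        marker_levels[[cyc]][[ch]] <- lv
        marker_maps[[cyc]][[ch]] <- paint_disks(lv)
      }
    }
  }

  smooth_field <- function(base, rel) {
    # low-order polynomial modulation, values in base*(1 +/- rel)
    cf <- runif(3, -1, 1)
    X <- matrix(seq(-1, 1, length.out = plane_w), plane_h, plane_w, byrow = TRUE)
    Y <- matrix(seq(-1, 1, length.out = plane_h), plane_h, plane_w)
    mod <- cf[1] * X + cf[2] * Y + cf[3] * X * Y
    mod <- mod / max(abs(mod), 1e-9)
    base * (1 + rel * mod)
  }
  af <- lapply(seq_len(nch), function(ch)
    list(first = smooth_field(af_level, af_variation),
         last = smooth_field(af_level, af_variation)))

  vignette <- function(amp) {
    X <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
    Y <- matrix(seq(-1, 1, length.out = H), H, W)
    v <- 1 - amp * (X^2 + Y^2) / 2
    v / mean(v)
  }
  shading <- lapply(seq_len(nch), function(ch)
    list(first = vignette(shading_amplitude * runif(1, 0.8, 1.2)),
         last = vignette(shading_amplitude * runif(1, 0.8, 1.2))))

  drifts <- matrix(0, nC, 2, dimnames = list(NULL, c("dx", "dy")))
  for (cyc in seq_len(nC)) {
    if (cyc == desc$reference_cycle) next
    d <- runif(2, -drift_max, drift_max)
    if (!subpixel_drift) d <- round(d)
    drifts[cyc, ] <- d
  }

  # nominal 0-based top-left plane coordinates per snake position
  rc <- index_to_grid(seq_len(n_positions(desc)), g)
  origins <- data.frame(position = seq_len(n_positions(desc)),
                        x0 = margin + (rc$col - 1L) * step_x,
                        y0 = margin + (rc$row - 1L) * step_y)

  structure(list(
    descriptor = desc, nuclei = nuclei,
    marker_maps = marker_maps, marker_levels = marker_levels,
    autofluorescence = af, shading = shading, drifts = drifts,
    origins = origins, plane_w = plane_w, plane_h = plane_h,
    margin = as.integer(margin), step_x = step_x, step_y = step_y,
    noise_gain = noise_gain, noise_sigma = noise_sigma,
    defocus_sigma0 = defocus_sigma0, defocus_slope = defocus_slope,
    seed = as.integer(seed)),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("phantom_truth: %d nuclei on a %dx%d px plane, ",
                     "%d cycles, drift <= %.1f px, seed %d\n"),
              nrow(x$nuclei), x$plane_w, x$plane_h,
              nrow(x$drifts), max(abs(x$drifts)), x$seed))
  invisible(x)
}

# linear anchor interpolation used throughout: weight of the last anchor
cycle_weight <- function(cycle, n_cycles) {
  if (n_cycles <= 1L) 0 else (cycle - 1) / (n_cycles - 1)
}

# noiseless full-resolution field seen by (cycle, channel): marker + AF
phantom_field <- function(truth, cycle, channel) {
  desc <- truth$descriptor
  w <- cycle_weight(cycle, n_cycles(desc))
  afc <- truth$autofluorescence[[channel]]
  field <- (1 - w) * afc$first + w * afc$last
  mm <- truth$marker_maps[[cycle]][[channel]]
  if (!is.null(mm)) field <- field + mm
  field
}

# tile-frame vignette for (cycle, channel)
phantom_shading <- function(truth, cycle, channel) {
  w <- cycle_weight(cycle, n_cycles(truth$descriptor))
  sc <- truth$shading[[channel]]
  (1 - w) * sc$first + w * sc$last
}

# crop the plane at a position with the cycle's stage drift applied:
# content appears displaced by +drift relative to the reference cycle
phantom_window <- function(truth, position, cycle, field) {
  o <- truth$origins[position, ]
  d <- truth$drifts[cycle, ]
  dxi <- floor(d[["dx"]]); dyi <- floor(d[["dy"]])
  fx <- d[["dx"]] - dxi; fy <- d[["dy"]] - dyi
  W <- truth$descriptor$tile_width; H <- truth$descriptor$tile_height
  crop <- function(ddx, ddy) {
    x0 <- o$x0 - ddx; y0 <- o$y0 - ddy     # window moves opposite to content
    field[y0 + seq_len(H), x0 + seq_len(W), drop = FALSE]
  }
  if (fx == 0 && fy == 0) return(crop(dxi, dyi))
  # bilinear blend of the four integer-shift crops for subpixel drift
  (1 - fx) * (1 - fy) * crop(dxi, dyi) +
    fx * (1 - fy) * crop(dxi + 1L, dyi) +
    (1 - fx) * fy * crop(dxi, dyi + 1L) +
    fx * fy * crop(dxi + 1L, dyi + 1L)
}

#' Render one raw tile plane of the phantom
#'
#' Applies the forward model the pipeline inverts: the (marker +
#' autofluorescence) field is windowed at the tile's nominal position
#' displaced by the cycle's stage drift, defocus-blurred according to the
#' Z plane, multiplied by the cycle-interpolated camera vignette, and
#' corrupted with Poisson shot noise and Gaussian read noise. Values are
#' clipped to the unsigned 16-bit range.
#'
#' @param truth a [generate_phantom()] result.
#' @param key a [tile_key()].
#' @return numeric tile matrix (counts, still floating point).
#' @export
render_tile <- function(truth, key) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(key, "tile_key"))
  desc <- truth$descriptor
  stopifnot(key$cycle <= n_cycles(desc), key$position <= n_positions(desc),
            key$z <= desc$n_z, key$channel <= n_channels(desc))
  field <- phantom_field(truth, key$cycle, key$channel)
  tile <- phantom_window(truth, key$position, key$cycle, field)
  z_focus <- (desc$n_z + 1) / 2
  sigma_z <- truth$defocus_sigma0 + truth$defocus_slope * abs(key$z - z_focus)
  if (sigma_z > 0) tile <- gaussian_blur(tile, sigma_z)
  tile <- tile * phantom_shading(truth, key$cycle, key$channel)
  if (truth$noise_gain > 0 || truth$noise_sigma > 0) {
    # per-tile seed: reproducible regardless of rendering order
    idx <- ((key$cycle * 131071 + key$position) * 8191 +
              key$z * 127 + key$channel)
    set.seed(as.integer((as.numeric(truth$seed) * 2654435 + idx) %% 2147483647))
    if (truth$noise_gain > 0)
      tile <- matrix(rpois(length(tile), pmax(tile, 0) / truth$noise_gain) *
                       truth$noise_gain, nrow(tile), ncol(tile))
    if (truth$noise_sigma > 0)
      tile <- tile + matrix(rnorm(length(tile), 0, truth$noise_sigma),
                            nrow(tile), ncol(tile))
  }
  pmin(pmax(tile, 0), 65535)
}

#' Ground-truth nuclei visible in one tile
#'
#' Nuclei of the global list whose centre falls inside the tile's nominal
#' (reference-cycle) window; coordinates are returned in the tile frame,
#' 1-based.
#'
#' @param truth a [generate_phantom()] result.
#' @param position 1-based snake position.
#' @return data.frame with `x`, `y`, `radius` (tile frame).
#' @export
nuclei_in_tile <- function(truth, position) {
  o <- truth$origins[position, ]
  desc <- truth$descriptor
  inside <- truth$nuclei$x > o$x0 & truth$nuclei$x <= o$x0 + desc$tile_width &
    truth$nuclei$y > o$y0 & truth$nuclei$y <= o$y0 + desc$tile_height
  out <- truth$nuclei[inside, , drop = FALSE]
  out$x <- out$x - o$x0
  out$y <- out$y - o$y0
  out
}

#' Write a synthetic acquisition to disk in the raw instrument layout
#'
#' Creates one folder per cycle (named via [cycle_folder_name()]), each
#' holding `positions x n_z x channels` single-plane uint16 TIFFs named by
#' [tile_filename()], plus `Experiment.json`, `channelNames.txt` and a
#' `ground_truth/` sidecar (JSON manifest + float32 TIFF fields) for
#' verification.
#'
#' @param truth a [generate_phantom()] result.
#' @param out_dir output directory (created if needed).
#' @param write_ground_truth write the sidecar (default `TRUE`).
#' @return `out_dir`, invisibly.
#' @export
write_acquisition <- function(truth, out_dir, write_ground_truth = TRUE) {
  desc <- truth$descriptor
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (cyc in seq_len(n_cycles(desc))) {
    cdir <- file.path(out_dir, cycle_folder_name(cyc))
    dir.create(cdir, showWarnings = FALSE)
    for (pos in seq_len(n_positions(desc)))
      for (z in seq_len(desc$n_z))
        for (ch in seq_len(n_channels(desc))) {
          key <- tile_key(cyc, pos, z, ch)
          write_tiff(render_tile(truth, key),
                     file.path(cdir, tile_filename(key, desc$name)),
                     type = "uint16")
        }
  }
  write_experiment_json(desc, file.path(out_dir, "Experiment.json"))
  write_channel_names(desc, file.path(out_dir, "channelNames.txt"))
  if (write_ground_truth) {
    gdir <- file.path(out_dir, "ground_truth")
    dir.create(gdir, showWarnings = FALSE)
    manifest <- list(
      seed = truth$seed, plane_w = truth$plane_w, plane_h = truth$plane_h,
      margin = truth$margin, step_x = truth$step_x, step_y = truth$step_y,
      nuclei = truth$nuclei,
      drifts = as.data.frame(truth$drifts),
      origins = truth$origins,
      noise_gain = truth$noise_gain, noise_sigma = truth$noise_sigma,
      defocus_sigma0 = truth$defocus_sigma0,
      defocus_slope = truth$defocus_slope)
    jsonlite::write_json(manifest, file.path(gdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (ch in seq_len(n_channels(desc))) {
      write_tiff(truth$shading[[ch]]$first,
                 file.path(gdir, sprintf("shading_first_CH%d.tif", ch)),
                 "float32")
      write_tiff(truth$shading[[ch]]$last,
                 file.path(gdir, sprintf("shading_last_CH%d.tif", ch)),
                 "float32")
      write_tiff(truth$autofluorescence[[ch]]$first,
                 file.path(gdir, sprintf("af_first_CH%d.tif", ch)), "float32")
      write_tiff(truth$autofluorescence[[ch]]$last,
                 file.path(gdir, sprintf("af_last_CH%d.tif", ch)), "float32")
    }
  }
  invisible(out_dir)
}
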