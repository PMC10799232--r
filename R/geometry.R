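# Geometry: translation-only inter-cycle registration by phase
# correlation, crop-to-common-frame, and MIST-style grid stitching
# (pairwise phase correlation of overlap strips + maximum-quality spanning
# tree) shared by all channels and cycles.

translation <- function(dx, dy, quality = NA_real_) {
  structure(list(dx = dx, dy = dy, quality = quality), class = "translation")
}

#' @export
print.translation <- function(x, ...) {
  cat(sprintf("translation: dx %+0.3f, dy %+0.3f (quality %.3f)\n",
              x$dx, x$dy, x$quality))
  invisible(x)
}

# wrap 0-based circular peak coordinates into signed shifts
.wrap_shift <- function(i, n) ifelse(i > n / 2, i - n, i)

#' Estimate the translation between two images
#'
#' Phase correlation: the peak of the inverse-transformed normalised
#' cross-power spectrum gives the integer displacement `(dx, dy)` of the
#' moving image's content relative to the reference (`moving ==
#' shift(reference, dx, dy)` for a pure shift). Optional subpixel
#' refinement fits a 1-d parabola through the peak and its neighbours on
#' each axis. `quality` is the normalised cross-correlation of the two
#' images over their overlap after undoing the integer shift.
#'
#' @param reference,moving numeric matrices of one shape, non-constant.
#' @param subpixel logical; refine the peak to subpixel precision.
#' @param window apply a Hann window before the transform (reduces edge
#'   leakage for non-periodic content; off by default).
#' @return a `translation` (fields `dx`, `dy`, `quality`).
#' @export
estimate_translation <- function(reference, moving, subpixel = FALSE,
                                 window = FALSE) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (sd(reference) == 0 || sd(moving) == 0)
    stop("phase correlation is undefined for a constant image")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  if (window) {
    hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(a)) - 1) / (nrow(a) - 1))
    hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(a)) - 1) / (ncol(a) - 1))
    h <- outer(hr, hc)
    a <- a * h; b <- b * h
  }
  Fa <- fft(a); Fb <- fft(b)
  cross <- Fa * Conj(Fb)
  mag <- Mod(cross)
  r <- Re(fft(cross / pmax(mag, 1e-12), inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r))
  nr <- nrow(r); nc <- ncol(r)
  # peak at index p means moving = reference shifted by -(p - 1) circularly
  dy <- -.wrap_shift(pk[1] - 1L, nr)
  dx <- -.wrap_shift(pk[2] - 1L, nc)
  if (subpixel) {
    at <- function(i, j) r[((i - 1) %% nr) + 1, ((j - 1) %% nc) + 1]
    para <- function(m1, c0, p1) {
      den <- m1 - 2 * c0 + p1
      if (abs(den) < 1e-12) 0 else 0.5 * (m1 - p1) / den
    }
    dy <- dy - para(at(pk[1] - 1L, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1L, pk[2]))
    dx <- dx - para(at(pk[1], pk[2] - 1L), at(pk[1], pk[2]), at(pk[1], pk[2] + 1L))
  }
  q <- .overlap_ncc(reference, moving, round(dx), round(dy))
  translation(dx, dy, q)
}

# normalised cross-correlation of ref vs moving shifted back by (-dx, -dy),
# over the common valid region
.overlap_ncc <- function(reference, moving, dx, dy) {
  nr <- nrow(reference); nc <- ncol(reference)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(rs) < 4 || length(cs) < 4) return(NA_real_)
  a <- reference[rs - dy, cs - dx, drop = FALSE]
  b <- moving[rs, cs, drop = FALSE]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) *
    length(a) / (length(a) - 1)
}

#' Register all cycles of one position to the reference cycle
#'
#' Runs [estimate_translation()] of every cycle's nuclear-channel tile
#' against the reference cycle's. The reference cycle's translation is
#' identically `(0, 0)`; by contract the same per-cycle translation is
#' applied to every channel of that cycle.
#'
#' @param tiles list of nuclear-channel tiles, one per cycle, same shape.
#' @param reference_cycle 1-based index into `tiles`.
#' @param subpixel passed to [estimate_translation()].
#' @return list of `translation`s, one per cycle.
#' @export
register_cycles <- function(tiles, reference_cycle = 1L, subpixel = FALSE) {
  stopifnot(is.list(tiles), length(tiles) >= 1)
  if (reference_cycle < 1 || reference_cycle > length(tiles))
    stop("reference cycle ", reference_cycle, " not among the ",
         length(tiles), " provided cycles")
  if (any(vapply(tiles, is.null, logical(1))))
    stop("missing nuclear tile for cycle ",
         which(vapply(tiles, is.null, logical(1)))[1])
  ref <- tiles[[reference_cycle]]
  lapply(seq_along(tiles), function(cyc) {
    if (cyc == reference_cycle) translation(0, 0, 1)
    else estimate_translation(ref, tiles[[cyc]], subpixel = subpixel)
  })
}

#' Align and crop all tiles of a position to a common frame
#'
#' Each cycle's tiles are shifted by minus the cycle's translation
#' (rounded to integers) so all cycles overlay the reference, then every
#' tile is cropped by symmetric margins of `ceil(max |dy|)` rows and
#' `ceil(max |dx|)` columns on each side, so all outputs share one shape
#' and identical physical framing.
#'
#' @param tiles nested list `tiles[[cycle]][[channel]]` of same-shaped
#'   matrices.
#' @param translations per-cycle `translation` list ([register_cycles()]).
#' @param margin_x,margin_y override the crop margins (px), e.g. with the
#'   maximum over all positions so every position keeps one shape.
#' @return nested list of cropped tiles, plus attributes `margin_x`,
#'   `margin_y`.
#' @export
crop_to_common <- function(tiles, translations, margin_x = NULL,
                           margin_y = NULL) {
  stopifnot(length(tiles) == length(translations))
  dxs <- vapply(translations, `[[`, numeric(1), "dx")
  dys <- vapply(translations, `[[`, numeric(1), "dy")
  mx <- as.integer(margin_x %||% ceiling(max(abs(dxs))))
  my <- as.integer(margin_y %||% ceiling(max(abs(dys))))
  d <- dim(tiles[[1]][[which(!vapply(tiles[[1]], is.null, logical(1)))[1]]])
  if (2 * mx >= d[2] || 2 * my >= d[1])
    stop("registration drift too large: crop of ", mx, "x", my,
         " px exceeds the tile size")
  out <- lapply(seq_along(tiles), function(cyc) {
    lapply(tiles[[cyc]], function(tile) {
      if (is.null(tile)) return(NULL)
      shifted <- translate_pad(tile, -round(dxs[cyc]), -round(dys[cyc]))
      shifted[(my + 1):(d[1] - my), (mx + 1):(d[2] - mx), drop = FALSE]
    })
  })
  attr(out, "margin_x") <- mx
  attr(out, "margin_y") <- my
  out
}

#' Estimate offsets between adjacent grid tiles
#'
#' For every horizontally and vertically adjacent tile pair of the grid,
#' phase-correlates the nominal overlap strips and reports the measured
#' displacement of the second tile relative to the first, together with
#' the nominal displacement implied by `overlap_fraction` and a quality
#' score. Featureless or low-quality seams fall back to the nominal
#' offset (flagged in the `fallback` column).
#'
#' @param tiles list of tiles indexed by snake position (reference channel
#'   of the reference cycle).
#' @param grid the [grid_spec()].
#' @param min_quality seams below this NCC use the nominal offset.
#' @param step nominal tile spacing `c(step_x, step_y)` in px. Defaults to
#'   `tile size * (1 - overlap_fraction)`; pass the spacing of the
#'   *acquired* tiles when the supplied tiles have been drift-cropped (the
#'   stage spacing does not shrink with the crop).
#' @return data.frame with one row per adjacent pair: `from`, `to` (snake
#'   indices), `direction` (`"h"`/`"v"`), `offset_x`, `offset_y`,
#'   `nominal_x`, `nominal_y`, `quality`, `fallback`. Seams whose overlap
#'   is under 4 px are reported as nominal with `quality` `NA`.
#' @export
estimate_pairwise_offsets <- function(tiles, grid, min_quality = 0.3,
                                      step = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- grid$n_cols * grid$n_rows
  if (length(tiles) < n) stop("need all ", n, " grid tiles")
  if (n == 1) return(data.frame(from = integer(0), to = integer(0),
                                direction = character(0),
                                offset_x = numeric(0), offset_y = numeric(0),
                                nominal_x = numeric(0), nominal_y = numeric(0),
                                quality = numeric(0), fallback = logical(0)))
  d <- dim(tiles[[1]])
  H <- d[1]; W <- d[2]
  if (is.null(step)) step <- c(round(W * (1 - grid$overlap_fraction)),
                               round(H * (1 - grid$overlap_fraction)))
  step_x <- step[1]; step_y <- step[2]
  ov_x <- W - step_x; ov_y <- H - step_y
  rows <- list()
  measure <- function(strip_a, strip_b, nominal) {
    est <- tryCatch(estimate_translation(strip_a, strip_b, subpixel = FALSE),
                    error = function(e) translation(0, 0, NA_real_))
    fallback <- is.na(est$quality) || est$quality < min_quality
    if (fallback) list(off = nominal, q = est$quality, fb = TRUE)
    else list(off = c(nominal[1] - est$dx, nominal[2] - est$dy),
              q = est$quality, fb = FALSE)
  }
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      i <- grid_to_index(r, cc, grid)
      if (cc < grid$n_cols) {  # horizontal neighbour
        j <- grid_to_index(r, cc + 1L, grid)
        m <- if (ov_x >= 4)
          measure(tiles[[i]][, (W - ov_x + 1):W, drop = FALSE],
                  tiles[[j]][, 1:ov_x, drop = FALSE], c(step_x, 0))
        else list(off = c(step_x, 0), q = NA_real_, fb = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          from = i, to = j, direction = "h",
          offset_x = m$off[1], offset_y = m$off[2],
          nominal_x = step_x, nominal_y = 0,
          quality = m$q, fallback = m$fb)
      }
      if (r < grid$n_rows) {  # vertical neighbour
        j <- grid_to_index(r + 1L, cc, grid)
        m <- if (ov_y >= 4)
          measure(tiles[[i]][(H - ov_y + 1):H, , drop = FALSE],
                  tiles[[j]][1:ov_y, , drop = FALSE], c(0, step_y))
        else list(off = c(0, step_y), q = NA_real_, fb = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          from = i, to = j, direction = "v",
          offset_x = m$off[1], offset_y = m$off[2],
          nominal_x = 0, nominal_y = step_y,
          quality = m$q, fallback = m$fb)
      }
    }
  }
  do.call(rbind, rows)
}

#' Solve global tile positions from pairwise offsets
#'
#' Builds the 4-neighbour tile graph weighted by seam quality and anchors
#' positions along its maximum-quality spanning tree (Prim), starting from
#' tile 1; coordinates are then shifted so the minimum is 0. This is the
#' MIST-style translation model without the stage-model refinement.
#'
#' @param offsets data.frame from [estimate_pairwise_offsets()].
#' @param grid the [grid_spec()].
#' @param tile_width,tile_height tile size in px (sets the mosaic bounds).
#' @return an object of class `mosaic_layout`: `positions` data.frame
#'   (`index`, `x`, `y`; 0-based px of each tile's top-left corner),
#'   `mosaic_width`, `mosaic_height`, `tile_width`, `tile_height`.
#' @export
solve_global_positions <- function(offsets, grid, tile_width, tile_height) {
  n <- grid$n_cols * grid$n_rows
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  x[1] <- 0; y[1] <- 0
  if (n > 1) {
    if (nrow(offsets) == 0) stop("tile graph is disconnected: no offsets")
    q <- ifelse(is.na(offsets$quality), 0, offsets$quality)
    done <- c(1L)
    while (length(done) < n) {
      cand <- which((offsets$from %in% done) != (offsets$to %in% done))
      if (!length(cand)) stop("tile graph is disconnected")
      e <- cand[which.max(q[cand])]
      fr <- offsets$from[e]; to <- offsets$to[e]
      if (fr %in% done) {
        x[to] <- x[fr] + offsets$offset_x[e]
        y[to] <- y[fr] + offsets$offset_y[e]
        done <- c(done, to)
      } else {
        x[fr] <- x[to] - offsets$offset_x[e]
        y[fr] <- y[to] - offsets$offset_y[e]
        done <- c(done, fr)
      }
    }
  }
  x <- round(x - min(x)); y <- round(y - min(y))
  structure(list(
    positions = data.frame(index = seq_len(n), x = x, y = y),
    mosaic_width = as.integer(max(x) + tile_width),
    mosaic_height = as.integer(max(y) + tile_height),
    tile_width = as.integer(tile_width),
    tile_height = as.integer(tile_height)),
    class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("mosaic_layout: %d tiles (%dx%d px each) in a %dx%d px mosaic\n",
              nrow(x$positions), x$tile_width, x$tile_height,
              x$mosaic_width, x$mosaic_height))
  invisible(x)
}

#' Compose one mosaic from tiles and a shared layout
#'
#' Places every tile at its layout position. In `"feather"` mode overlap
#' pixels are blended with weights growing linearly with the distance to
#' each tile's edge (average-preserving; two identical strips blend to the
#' same content); pixels covered by a single tile are copied verbatim. In
#' `"reference"` mode the lowest tile index wins outright.
#'
#' @param tiles list of tiles indexed by snake position (one channel of
#'   one cycle).
#' @param layout a [solve_global_positions()] result, computed once on the
#'   reference channel/cycle and reused for every channel and cycle.
#' @param blend `"feather"` (default) or `"reference"`.
#' @return numeric mosaic matrix of size `mosaic_height x mosaic_width`.
#' @export
compose_mosaic <- function(tiles, layout, blend = c("feather", "reference")) {
  blend <- match.arg(blend)
  stopifnot(inherits(layout, "mosaic_layout"))
  H <- layout$tile_height; W <- layout$tile_width
  acc <- matrix(0, layout$mosaic_height, layout$mosaic_width)
  wacc <- matrix(0, layout$mosaic_height, layout$mosaic_width)
  fw <- outer(pmin(seq_len(H), H + 1 - seq_len(H)),
              pmin(seq_len(W), W + 1 - seq_len(W)), pmin)
  for (i in layout$positions$index) {
    tile <- tiles[[i]]
    if (!identical(dim(tile), c(H, W)))
      stop("tile ", i, " does not match the layout tile size")
    x0 <- layout$positions$x[i]; y0 <- layout$positions$y[i]
    if (x0 < 0 || y0 < 0 || x0 + W > layout$mosaic_width ||
        y0 + H > layout$mosaic_height)
      stop("tile ", i, " falls outside the mosaic bounds")
    rs <- y0 + seq_len(H); cs <- x0 + seq_len(W)
    if (blend == "feather") {
      acc[rs, cs] <- acc[rs, cs] + tile * fw
      wacc[rs, cs] <- wacc[rs, cs] + fw
    } else {
      unset <- wacc[rs, cs] == 0
      block <- acc[rs, cs]
      block[unset] <- tile[unset]
      acc[rs, cs] <- block
      wacc[rs, cs][unset] <- 1
    }
  }
  if (blend == "feather") acc / pmax(wacc, 1) else acc
}
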