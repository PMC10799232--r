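# Intensity correction: shading-profile estimation at the two blank anchor
# cycles with linear inter-cycle interpolation, blank-cycle
# autofluorescence subtraction, and the negative-value cleanup that
# precedes casting back to unsigned integers. All intermediates are kept
# in floating point.

#' Estimate a shading (vignetting) profile from one anchor cycle
#'
#' The default `"ratio"` mode implements the estimator literally: the
#' pixelwise median `M` across all positions of the channel is divided by
#' its Gaussian blur, `profile = M / (G_sigma * M)`, then mean-normalised
#' to 1. With `sigma = 64` px the blur removes everything slower than the
#' vignette so the ratio isolates the fixed illumination pattern. The
#' `"smooth"` mode returns the conventional smooth flat-field estimate
#' `(G_sigma * M) / mean(G_sigma * M)` instead.
#'
#' @param tiles list of same-shaped numeric matrices: all positions of one
#'   channel in one anchor cycle.
#' @param sigma Gaussian blur sigma, px.
#' @param mode `"ratio"` (default) or `"smooth"`.
#' @param eps floor applied to the blurred median before division; pixels
#'   at the floor are reported via a warning.
#' @return an object of class `shading_profile` (matrix `field`, mean 1).
#' @export
compute_shading_profile <- function(tiles, sigma = 64, mode = c("ratio", "smooth"),
                                    eps = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is.list(tiles), length(tiles) >= 1)
  dims <- unique(lapply(tiles, dim))
  if (length(dims) != 1) stop("all tiles must share one shape")
  M <- if (length(tiles) == 1) tiles[[1]]
    else apply(simplify2array(tiles), c(1, 2), median)
  B <- gaussian_blur(M, sigma)
  if (mode == "ratio") {
    n_floor <- sum(B < eps)
    if (n_floor > 0)
      warning("blurred median hit the epsilon floor on ", n_floor, " pixel(s)")
    field <- M / pmax(B, eps)
  } else {
    field <- B
  }
  field <- field / mean(field)
  structure(list(field = field, sigma = sigma, mode = mode),
            class = "shading_profile")
}

#' Linearly interpolate anchor profiles to a cycle
#'
#' `field = first + (cycle - 1) / (n_cycles - 1) * (last - first)`; exact
#' at both endpoints. With a single cycle the first profile is returned.
#'
#' @param first,last [compute_shading_profile()] results or plain matrices
#'   of one shape.
#' @param cycle 1-based target cycle.
#' @param n_cycles total number of cycles.
#' @return interpolated field (plain matrix).
#' @export
interpolate_profile <- function(first, last, cycle, n_cycles) {
  f <- if (inherits(first, "shading_profile")) first$field else first
  l <- if (inherits(last, "shading_profile")) last$field else last
  stopifnot(identical(dim(f), dim(l)), cycle >= 1, cycle <= n_cycles)
  if (n_cycles == 1L) return(f)
  w <- cycle_weight(cycle, n_cycles)
  f + w * (l - f)
}

#' Divide a tile by a shading field
#'
#' @param tile numeric matrix.
#' @param profile interpolated shading field (strictly positive matrix or
#'   a `shading_profile`).
#' @return corrected tile (floating point).
#' @export
apply_shading <- function(tile, profile) {
  p <- if (inherits(profile, "shading_profile")) profile$field else profile
  if (!identical(dim(tile), dim(p)))
    stop("tile and shading profile shapes differ")
  if (any(p <= 0)) stop("shading profile must be strictly positive")
  tile / p
}

#' Autofluorescence background field from a blank tile
#'
#' A Gaussian blur (sigma 10 px by default) of the shading-corrected blank
#' anchor-cycle tile; the blurred blank is taken as the tissue
#' autofluorescence of that channel at that anchor.
#'
#' @param blank_tile shading-corrected blank tile, numeric matrix.
#' @param sigma blur sigma, px.
#' @return nonnegative background field matrix.
#' @export
compute_background <- function(blank_tile, sigma = 10) {
  out <- gaussian_blur(blank_tile, sigma)
  out[out < 0] <- 0
  out
}

#' Subtract the cycle-interpolated autofluorescence background
#'
#' The background at the target cycle is the linear interpolation of the
#' first and last anchor fields; the result may be negative (resolved
#' later by [remove_negative_values()]).
#'
#' @param tile shading-corrected tile.
#' @param first_bg,last_bg anchor background fields ([compute_background()]).
#' @param cycle 1-based target cycle.
#' @param n_cycles total number of cycles.
#' @return signed tile matrix.
#' @export
subtract_background <- function(tile, first_bg, last_bg, cycle, n_cycles) {
  if (!identical(dim(tile), dim(first_bg)) ||
      !identical(dim(tile), dim(last_bg)))
    stop("tile and background field shapes differ")
  tile - interpolate_profile(first_bg, last_bg, cycle, n_cycles)
}

#' Clip negatives and rebase positive intensities
#'
#' Negative values are replaced by 0; then the minimum over the strictly
#' positive values is subtracted from every positive value (zeros stay
#' zero), so the output minimum is 0 whenever any positive value existed.
#'
#' @param img signed numeric matrix.
#' @return nonnegative matrix of the same shape.
#' @export
remove_negative_values <- function(img) {
  img[img < 0] <- 0
  pos <- img > 0
  if (!any(pos)) return(img)
  m <- min(img[pos])
  img[pos] <- img[pos] - m
  img
}
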