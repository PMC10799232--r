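# Restoration: PSF synthesis, Richardson-Lucy deconvolution of per-tile
# Z-stacks, and extended-depth-of-field projection to a single in-focus 2D
# image. Stacks are 3-d arrays [y, x, z].

#' Generate a widefield point spread function
#'
#' Scalar Gaussian approximation of the widefield PSF: lateral sigma
#' `0.21 * lambda / NA`, axial sigma `0.66 * lambda * n / NA^2` (both in
#' physical units, converted to voxels). The kernel is normalised to sum 1,
#' peaks at the centre voxel and is centrosymmetric; lateral width grows
#' with wavelength and shrinks with NA. The model sits behind a `psf_model`
#' seam so a vectorial/Born-Wolf kernel can be substituted.
#'
#' @param wavelength emission wavelength, nm.
#' @param na numerical aperture.
#' @param voxel voxel size `c(dx, dy, dz)` in micrometres.
#' @param size odd kernel size `c(nx, ny, nz)` in voxels; defaults to
#'   about 6 sigma per axis.
#' @param refractive_index immersion refractive index.
#' @return an object of class `psf_model` with the normalised `kernel`.
#' @export
generate_psf <- function(wavelength, na, voxel, size = NULL,
                         refractive_index = 1.0) {
  if (wavelength <= 0 || na <= 0 || any(voxel <= 0))
    stop("wavelength, numerical aperture and voxel sizes must be positive")
  lambda_um <- wavelength / 1000
  sigma_xy_um <- 0.21 * lambda_um / na
  sigma_z_um <- 0.66 * lambda_um * refractive_index / na^2
  sig <- c(sigma_xy_um / voxel[1], sigma_xy_um / voxel[2],
           sigma_z_um / voxel[3])  # voxels: x, y, z
  if (is.null(size)) {
    size <- pmax(2 * ceiling(3 * sig) + 1, 3)
  }
  size <- as.integer(size)
  if (any(size %% 2L == 0L)) stop("PSF kernel size must be odd on every axis")
  ax <- function(n, s) {
    x <- seq_len(n) - (n + 1) / 2
    if (n == 1) return(1)
    exp(-x^2 / (2 * max(s, 1e-6)^2))
  }
  gx <- ax(size[1], sig[1]); gy <- ax(size[2], sig[2]); gz <- ax(size[3], sig[3])
  kernel <- outer(outer(gy, gx), gz)  # [y, x, z]
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, wavelength = wavelength, na = na,
                 voxel = voxel, sigma_voxels = sig),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  d <- dim(x$kernel)
  cat(sprintf("psf_model: %dx%dx%d kernel, lambda %g nm, NA %g, sigma_xy %.2f px\n",
              d[2], d[1], d[3], x$wavelength, x$na, x$sigma_voxels[1]))
  invisible(x)
}

#' Richardson-Lucy deconvolution of a Z-stack
#'
#' Standard multiplicative Richardson-Lucy update with reflective boundary
#' handling; 10 iterations by default. `iterations = 0` returns the input.
#' Nonnegativity of the estimate is preserved at every iteration.
#'
#' @param stack 3-d array `[y, x, z]`, nonnegative. A matrix is treated as
#'   a single-plane stack.
#' @param psf a [generate_psf()] result (its mirrored kernel is used for
#'   the adjoint; the Gaussian kernel is symmetric).
#' @param iterations number of RL iterations.
#' @return deconvolved stack, same shape as the input.
#' @export
richardson_lucy <- function(stack, psf, iterations = 10L) {
  two_d <- is.matrix(stack)
  if (two_d) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L, inherits(psf, "psf_model"),
            iterations >= 0)
  if (any(stack < 0))
    stop("richardson_lucy: input stack contains negative values")
  kernel <- psf$kernel
  kd <- dim(kernel)
  if (any(kd > 2 * dim(stack)))  # crop an oversized kernel to the data
    kernel <- crop_kernel(kernel, pmin(kd, 2 * (dim(stack) %/% 2) + 1))
  kflip <- kernel[rev(seq_len(dim(kernel)[1])), rev(seq_len(dim(kernel)[2])),
                  rev(seq_len(dim(kernel)[3])), drop = FALSE]
  est <- stack
  eps <- 1e-12
  for (i in seq_len(iterations)) {
    blurred <- convolve3_reflect(est, kernel)
    ratio <- stack / pmax(blurred, eps)
    est <- est * convolve3_reflect(ratio, kflip)
    est[est < 0] <- 0
  }
  if (two_d) est[, , 1] else est
}

crop_kernel <- function(kernel, size) {
  d <- dim(kernel)
  off <- (d - size) %/% 2
  k <- kernel[off[1] + seq_len(size[1]), off[2] + seq_len(size[2]),
              off[3] + seq_len(size[3]), drop = FALSE]
  k / sum(k)
}

#' Extended depth of field projection
#'
#' Collapses a Z-stack to a 2D image by selecting, per pixel, the slice
#' with the strongest local focus. The focus measure is the local variance
#' of the discrete Laplacian in a square window; the winning-slice index
#' map is median-filtered to suppress isolated slice switches. `"hard"`
#' mode copies the winning slice's pixel; `"soft"` mode blends slices with
#' weights proportional to their focus response.
#'
#' @param stack 3-d array `[y, x, z]` (a matrix is returned unchanged).
#' @param window odd focus-window size, px.
#' @param median_radius radius of the median filter on the slice map, px
#'   (2 gives the 5 x 5 window).
#' @param mode `"hard"` (default) or `"soft"`.
#' @return list with `image` (2D projection) and `slice_map` (1-based
#'   selected slice per pixel; hard mode).
#' @export
extended_depth_of_field <- function(stack, window = 9L, median_radius = 2L,
                                    mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (is.matrix(stack)) return(list(image = stack,
                                    slice_map = matrix(1L, nrow(stack), ncol(stack))))
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 1L) stop("EDF expects a non-empty Z-stack")
  nz <- d[3]
  if (nz == 1L) return(list(image = stack[, , 1],
                            slice_map = matrix(1L, d[1], d[2])))
  focus <- array(0, d)
  for (z in seq_len(nz)) {
    L <- laplacian(stack[, , z])
    m <- box_filter(L, window)
    focus[, , z] <- box_filter(L^2, window) - m^2   # local variance
  }
  if (mode == "soft") {
    w <- focus - min(focus)
    wsum <- apply(w, c(1, 2), sum)
    wsum[wsum == 0] <- 1
    img <- matrix(0, d[1], d[2])
    for (z in seq_len(nz)) img <- img + stack[, , z] * w[, , z]
    img <- img / wsum
    smap <- apply(focus, c(1, 2), which.max)
    return(list(image = img, slice_map = smap))
  }
  smap <- apply(focus, c(1, 2), which.max)
  smap <- cp_median_filter(matrix(as.integer(smap), d[1], d[2]), median_radius)
  smap[smap < 1L] <- 1L; smap[smap > nz] <- nz
  idx <- cbind(as.vector(row(smap)), as.vector(col(smap)), as.vector(smap))
  img <- matrix(stack[idx], d[1], d[2])
  list(image = img, slice_map = smap)
}
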