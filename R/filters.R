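# Shared numeric image helpers. Images are numeric matrices [row=y, col=x];
# stacks are 3-d arrays [y, x, z]. All convolutions use reflective
# boundaries with Gaussian kernels truncated at 4 sigma.

#' Discrete 1-d Gaussian kernel
#'
#' Normalised to sum 1, truncated at `truncate * sigma`.
#'
#' @param sigma standard deviation in pixels (>= 0; 0 gives the identity).
#' @param truncate truncation radius in sigmas.
#' @return numeric vector of odd length.
#' @export
gaussian_kernel <- function(sigma, truncate = 4) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a 2-d image
#'
#' Separable convolution with reflective boundary handling.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @param truncate kernel truncation radius in sigmas.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma, truncate = 4) {
  stopifnot(is.matrix(img))
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma, truncate)
  cp_convolve_sep(img, k, k)
}

# circular shift of a matrix by integer (dx, dy); positive dx moves content
# right (+x), positive dy moves content down (+y)
circshift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1L - as.integer(dy)) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - as.integer(dx)) %% nc) + 1L
  img[ri, ci, drop = FALSE]
}

# integer translation with zero padding at exposed borders
translate_pad <- function(img, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# reflective padding of a 3-d array along all axes by (py, px, pz)
pad_reflect3 <- function(vol, py, px, pz) {
  d <- dim(vol)
  idx <- function(n, p) {
    if (p == 0) return(seq_len(n))
    if (n == 1) return(rep(1L, n + 2 * p))
    base <- c(rev(seq_len(min(p, n - 1)) + 1L), seq_len(n),
              rev(seq_len(n))[seq_len(min(p, n - 1)) + 1L])
    # if p exceeds n-1, clamp by edge replication of the reflected pattern
    while (length(base) < n + 2 * p)
      base <- c(base[1], base, base[length(base)])
    base
  }
  vol[idx(d[1], py), idx(d[2], px), idx(d[3], pz), drop = FALSE]
}

# FFT-based 3-d convolution with a centred kernel and reflective padding.
# kernel dims must be odd and not exceed vol dims after padding.
convolve3_reflect <- function(vol, kernel) {
  kd <- dim(kernel)
  stopifnot(all(kd %% 2 == 1))
  half <- (kd - 1L) %/% 2L
  p <- half
  vp <- pad_reflect3(vol, p[1], p[2], p[3])
  d <- dim(vp)
  kbig <- array(0, d)
  kbig[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  # centre the kernel at the origin (circular convolution)
  kbig <- kbig[((seq_len(d[1]) - 1L + half[1]) %% d[1]) + 1L,
               ((seq_len(d[2]) - 1L + half[2]) %% d[2]) + 1L,
               ((seq_len(d[3]) - 1L + half[3]) %% d[3]) + 1L, drop = FALSE]
  out <- Re(fft(fft(vp) * fft(kbig), inverse = TRUE)) / prod(d)
  out[p[1] + seq_len(dim(vol)[1]), p[2] + seq_len(dim(vol)[2]),
      p[3] + seq_len(dim(vol)[3]), drop = FALSE]
}

# local mean via box filter (odd window), reflective boundaries
box_filter <- function(img, window) {
  stopifnot(window %% 2 == 1)
  k <- rep(1 / window, window)
  cp_convolve_sep(img, k, k)
}

# 4-neighbour discrete Laplacian, reflective boundaries
laplacian <- function(img) {
  up <- rbind(img[1, , drop = FALSE], img[-nrow(img), , drop = FALSE])
  dn <- rbind(img[-1, , drop = FALSE], img[nrow(img), , drop = FALSE])
  lf <- cbind(img[, 1, drop = FALSE], img[, -ncol(img), drop = FALSE])
  rt <- cbind(img[, -1, drop = FALSE], img[, ncol(img), drop = FALSE])
  up + dn + lf + rt - 4 * img
}
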