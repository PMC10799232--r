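#' @useDynLib cycleproc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile rnorm rpois runif sd setNames
#' @importFrom utils unzip head tail
NULL

# Minimal baseline TIFF 6.0 codec (little-endian, uncompressed, one image
# per file). No TIFF package ships with this toolchain, and raw microscope
# tiles are plain single-plane grayscale, so a small strict codec is used:
# grayscale uint16 / int32 / float32 and interleaved RGB uint8.

.le16 <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, x %/% 256L))
}

.le32 <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}

.ifd_entry <- function(tag, type, count, value_raw4) {
  c(.le16(tag), .le16(type), .le32(count), value_raw4)
}

#' Write a single-plane TIFF image
#'
#' Writes an uncompressed, little-endian, single-strip baseline TIFF.
#' Grayscale matrices are written row-major with `img[row, col]` = (y, x);
#' RGB input is a `h x w x 3` array of values in 0..255.
#'
#' @param img numeric/integer matrix (grayscale) or `h x w x 3` array (rgb8).
#' @param path output file path.
#' @param type one of `"uint16"`, `"float32"`, `"int32"`, `"rgb8"`.
#'   `uint16` input is clipped to `[0, 65535]` and rounded.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(img, path, type = c("uint16", "float32", "int32", "rgb8")) {
  type <- match.arg(type)
  if (type == "rgb8") {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    h <- dim(img)[1]; w <- dim(img)[2]
    v <- pmin(pmax(round(img), 0), 255)
    # interleave samples per pixel, row-major
    px <- aperm(v, c(3L, 2L, 1L))  # sample, x, y
    data <- as.raw(as.vector(px))
    bps <- c(8L, 8L, 8L); spp <- 3L; photometric <- 2L; fmt <- 1L
  } else {
    stopifnot(is.matrix(img))
    h <- nrow(img); w <- ncol(img)
    vals <- as.vector(t(img))  # row-major
    spp <- 1L; photometric <- 1L
    if (type == "uint16") {
      v <- as.integer(pmin(pmax(round(vals), 0), 65535))
      data <- as.raw(rbind(v %% 256L, v %/% 256L))
      bps <- 16L; fmt <- 1L
    } else if (type == "int32") {
      data <- writeBin(as.integer(round(vals)), raw(), size = 4L,
                       endian = "little")
      bps <- 32L; fmt <- 2L
    } else {
      data <- writeBin(as.numeric(vals), raw(), size = 4L, endian = "little")
      bps <- 32L; fmt <- 3L
    }
  }
  data_offset <- 8L
  n_data <- length(data)
  ifd_offset <- data_offset + n_data
  if (ifd_offset %% 2L == 1L) {  # IFD must be word-aligned
    data <- c(data, as.raw(0L))
    ifd_offset <- ifd_offset + 1L
  }

  short_val <- function(x) c(.le16(x), as.raw(c(0L, 0L)))
  entries <- list(
    .ifd_entry(256L, 3L, 1L, short_val(w)),            # ImageWidth
    .ifd_entry(257L, 3L, 1L, short_val(h)),            # ImageLength
    NULL,                                              # BitsPerSample (below)
    .ifd_entry(259L, 3L, 1L, short_val(1L)),           # Compression = none
    .ifd_entry(262L, 3L, 1L, short_val(photometric)),  # Photometric
    .ifd_entry(273L, 4L, 1L, .le32(data_offset)),      # StripOffsets
    .ifd_entry(277L, 3L, 1L, short_val(spp)),          # SamplesPerPixel
    .ifd_entry(278L, 3L, 1L, short_val(h)),            # RowsPerStrip
    .ifd_entry(279L, 4L, 1L, .le32(n_data)),           # StripByteCounts
    NULL                                               # SampleFormat (below)
  )
  n_entries <- 10L
  extra <- raw(0)
  if (spp == 3L) {
    # 3 shorts do not fit in the 4-byte value slot; store after the IFD
    bps_offset <- ifd_offset + 2L + n_entries * 12L + 4L
    entries[[3]] <- .ifd_entry(258L, 3L, 3L, .le32(bps_offset))
    entries[[10]] <- .ifd_entry(339L, 3L, 3L, .le32(bps_offset + 6L))
    extra <- c(.le16(bps), .le16(rep(fmt, 3L)))
  } else {
    entries[[3]] <- .ifd_entry(258L, 3L, 1L, short_val(bps))
    entries[[10]] <- .ifd_entry(339L, 3L, 1L, short_val(fmt))
  }
  ifd <- c(.le16(n_entries), do.call(c, entries), .le32(0L), extra)
  header <- c(charToRaw("II"), .le16(42L), .le32(ifd_offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, data, ifd), con)
  invisible(path)
}

.rd16 <- function(bytes, off) {  # 0-based offset
  as.integer(bytes[off + 1L]) + 256L * as.integer(bytes[off + 2L])
}
.rd32 <- function(bytes, off) {
  as.numeric(as.integer(bytes[off + 1L])) +
    256 * as.integer(bytes[off + 2L]) +
    65536 * as.integer(bytes[off + 3L]) +
    16777216 * as.integer(bytes[off + 4L])
}

.tiff_tag_value <- function(bytes, entry_off) {
  type <- .rd16(bytes, entry_off + 2L)
  count <- .rd32(bytes, entry_off + 4L)
  sz <- c(1L, 1L, 2L, 4L, 8L)[type]  # BYTE ASCII SHORT LONG RATIONAL
  if (is.na(sz)) return(NULL)
  nbytes <- sz * count
  voff <- if (nbytes <= 4) entry_off + 8L else .rd32(bytes, entry_off + 8L)
  if (type == 3L) vapply(seq_len(count) - 1L, function(i)
    .rd16(bytes, voff + 2L * i), numeric(1))
  else if (type == 4L) vapply(seq_len(count) - 1L, function(i)
    .rd32(bytes, voff + 4L * i), numeric(1))
  else NULL
}

#' Read a single-plane TIFF image
#'
#' Reads uncompressed little-endian baseline TIFF as written by
#' [write_tiff()] (and by common writers when using no compression).
#' Returns a numeric matrix for grayscale images or a `h x w x 3` array for
#' RGB. Unsigned 16-bit data come back as integers in 0..65535.
#'
#' @param path file path.
#' @return numeric matrix or 3-d array, with attribute `tiff_type`.
#' @export
read_tiff <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (rawToChar(bytes[1:2]) != "II")
    stop("only little-endian ('II') TIFF is supported: ", path)
  if (.rd16(bytes, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd <- .rd32(bytes, 4L)
  n <- .rd16(bytes, ifd)
  tags <- list()
  for (i in seq_len(n) - 1L) {
    off <- ifd + 2L + 12L * i
    tags[[as.character(.rd16(bytes, off))]] <- .tiff_tag_value(bytes, off)
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("TIFF tag ", tag, " missing in ", path)
    v
  }
  w <- need(256L); h <- need(257L)
  bps <- need(258L)
  comp <- tags[["259"]]
  if (!is.null(comp) && comp != 1) stop("compressed TIFF not supported: ", path)
  spp <- if (is.null(tags[["277"]])) 1L else as.integer(tags[["277"]])
  fmt <- if (is.null(tags[["339"]])) 1L else as.integer(tags[["339"]][1])
  offs <- need(273L); counts <- need(279L)
  data <- do.call(c, lapply(seq_along(offs), function(i)
    bytes[(offs[i] + 1):(offs[i] + counts[i])]))
  if (spp == 3L) {
    v <- as.integer(data)
    px <- array(v, dim = c(3L, w, h))
    out <- aperm(px, c(3L, 2L, 1L))
    attr(out, "tiff_type") <- "rgb8"
    return(out)
  }
  npx <- as.integer(w * h)
  vals <- if (bps[1] == 16L && fmt == 1L) {
    readBin(data, integer(), n = npx, size = 2L, signed = FALSE,
            endian = "little")
  } else if (bps[1] == 32L && fmt == 2L) {
    readBin(data, integer(), n = npx, size = 4L, endian = "little")
  } else if (bps[1] == 32L && fmt == 3L) {
    readBin(data, numeric(), n = npx, size = 4L, endian = "little")
  } else if (bps[1] == 8L && fmt == 1L) {
    as.integer(data[seq_len(npx)])
  } else stop("unsupported TIFF pixel type (bits=", bps[1], ", format=", fmt,
              ") in ", path)
  out <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  attr(out, "tiff_type") <- if (bps[1] == 16L) "uint16"
    else if (fmt == 2L) "int32" else if (fmt == 3L) "float32" else "uint8"
  out
}
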