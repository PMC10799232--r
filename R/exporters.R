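# Export stage: measurement table (CSV + FCS 3.1), ImageJ-compatible ROI
# archive, RGB outline overlay and the analysis-ready output tree. All
# writers are deterministic: no timestamps, fixed byte layouts.

#' Build the measurement table from per-cell records
#'
#' Fixed column order: `cell_id`, `x`, `y`, `size`, then one mean-intensity
#' column per non-blank (cycle, channel) named `cyc{NN}_ch{C}_{reporter}`,
#' followed by the shape descriptors.
#'
#' @param cells data.frame from [measure_cells()] whose intensity columns
#'   are named `mean_cyc{NN}_ch{C}_{reporter}`.
#' @param include_shape append the shape descriptor columns (perimeter,
#'   circularity, orientation) after the intensity block.
#' @return data.frame (class `measurement_table`).
#' @export
measurement_table <- function(cells, include_shape = FALSE) {
  icol <- grep("^mean_cyc", names(cells), value = TRUE)
  out <- data.frame(cell_id = cells$label,
                    x = cells$centroid_x, y = cells$centroid_y,
                    size = cells$area)
  for (nm in icol) out[[sub("^mean_", "", nm)]] <- cells[[nm]]
  if (include_shape)
    for (nm in c("perimeter", "circularity", "orientation"))
      if (nm %in% names(cells)) out[[nm]] <- cells[[nm]]
  if (anyDuplicated(names(out))) stop("duplicate measurement column names")
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Write the measurement table as RFC 4180 CSV
#'
#' Plain decimal numbers, header row, no quoting (column names contain no
#' separators); reading the file back reproduces the table.
#'
#' @param table a [measurement_table()] (any data.frame works).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV
#' @param path file path.
#' @return data.frame.
#' @export
read_measurements_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write the measurement table as FCS 3.1
#'
#' List-mode FCS 3.1: one event per cell, one parameter per column,
#' `$DATATYPE=F` (32-bit IEEE floats), little-endian (`$BYTEORD=1,2,3,4`),
#' with correct HEADER byte offsets and `$PnN`/`$PnR` keywords. The file
#' is readable by standard cytometry software.
#'
#' @param table data.frame of numeric columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  df <- as.data.frame(table)
  if (ncol(df) == 0) stop("cannot write an FCS file with zero parameters")
  n_par <- ncol(df); n_tot <- nrow(df)
  vals <- as.numeric(t(as.matrix(df)))  # event-major interleaving
  data_bytes <- writeBin(vals, raw(), size = 4L, endian = "little")
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (p in seq_len(n_par)) {
    rng <- if (n_tot > 0) max(abs(df[[p]]), 1) else 1
    kw <- c(kw,
            sprintf("$P%dN", p), names(df)[p],
            sprintf("$P%dB", p), "32",
            sprintf("$P%dE", p), "0,0",
            sprintf("$P%dR", p), sprintf("%.0f", ceiling(rng) + 1))
  }
  # TEXT segment must embed its own BEGIN/ENDDATA offsets: the keyword
  # values are fixed-width so the segment length does not depend on them
  build_text <- function(begin_data, end_data) {
    all_kw <- c("$BEGINDATA", sprintf("%012d", begin_data),
                "$ENDDATA", sprintf("%012d", end_data), kw)
    paste0(delim, paste(all_kw, collapse = delim), delim)
  }
  text_start <- 58L  # HEADER is 58 bytes: version + 6 offset fields
  probe <- build_text(0, 0)
  text_end <- text_start + nchar(probe, type = "bytes") - 1L
  begin_data <- text_end + 1L
  end_data <- if (length(data_bytes)) begin_data + length(data_bytes) - 1L
    else 0L
  text <- build_text(begin_data, if (length(data_bytes)) end_data else 0L)
  pad8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   pad8(text_start), pad8(text_end),
                   pad8(if (end_data <= 99999999) begin_data else 0),
                   pad8(if (end_data <= 99999999) end_data else 0),
                   pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (length(data_bytes)) writeBin(data_bytes, con)
  invisible(path)
}

#' Read an FCS file written with `$DATATYPE=F`
#'
#' Independent parser used as the round-trip oracle: interprets the
#' HEADER offsets, the delimited TEXT segment and the float DATA segment
#' from raw bytes.
#'
#' @param path file path.
#' @return list with `keywords` (named character) and `data` (data.frame,
#'   one column per parameter named from `$PnN`).
#' @export
read_fcs <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  version <- rawToChar(bytes[1:6])
  if (!startsWith(version, "FCS3")) stop("not an FCS 3.x file: ", path)
  off <- function(i) as.numeric(trimws(rawToChar(bytes[(10 + 8 * (i - 1) + 1):(10 + 8 * i)])))
  text_start <- off(1); text_end <- off(2)
  txt <- rawToChar(bytes[(text_start + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 toupper(parts[seq(1, length(parts), 2)]))
  n_par <- as.integer(kw[["$PAR"]]); n_tot <- as.integer(kw[["$TOT"]])
  begin_data <- as.numeric(kw[["$BEGINDATA"]])
  stopifnot(identical(kw[["$DATATYPE"]], "F"))
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  nms <- vapply(seq_len(n_par), function(p) kw[[sprintf("$P%dN", p)]],
                character(1))
  if (n_tot == 0)
    return(list(keywords = kw,
                data = setNames(as.data.frame(matrix(numeric(0), 0, n_par)), nms)))
  vals <- readBin(bytes[(begin_data + 1):length(bytes)], numeric(),
                  n = n_par * n_tot, size = 4L, endian = endian)
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  list(keywords = kw, data = setNames(as.data.frame(m), nms))
}

# --- ImageJ ROI binary format ------------------------------------------

.roi_bytes <- function(roi) {
  coords <- roi$coords
  if (nrow(coords) < 3) stop("polygon ROI needs at least 3 vertices")
  xs <- as.integer(coords[, 1]); ys <- as.integer(coords[, 2])
  left <- min(xs); top <- min(ys)
  right <- max(xs) + 1L; bottom <- max(ys) + 1L
  n <- length(xs)
  be16 <- function(v) {
    v <- as.integer(v); v <- ifelse(v < 0, v + 65536L, v)
    as.raw(rbind(v %/% 256L, v %% 256L))
  }
  header <- c(charToRaw("Iout"),        # magic
              be16(228L),               # version
              as.raw(c(0L, 0L)),        # type 0 = polygon, + pad byte
              be16(top), be16(left), be16(bottom), be16(right),
              be16(n),
              raw(64 - 18))             # unused header fields zeroed
  c(header, be16(xs - left), be16(ys - top))
}

.parse_roi_bytes <- function(bytes) {
  if (rawToChar(bytes[1:4]) != "Iout") stop("not an ImageJ ROI entry")
  rd16 <- function(off) as.integer(bytes[off + 1L]) * 256L +
    as.integer(bytes[off + 2L])
  top <- rd16(8L); left <- rd16(10L)
  n <- rd16(16L)
  xs <- vapply(seq_len(n) - 1L, function(i) rd16(64L + 2L * i), integer(1))
  ys <- vapply(seq_len(n) - 1L, function(i) rd16(64L + 2L * n + 2L * i),
               integer(1))
  cbind(x = xs + left, y = ys + top)
}

#' Write polygon ROIs as an ImageJ-compatible ZIP archive
#'
#' Each ROI becomes one binary entry (`<name>.roi`, magic `"Iout"`,
#' polygon type) inside an uncompressed ZIP readable by ImageJ's ROI
#' Manager and by [read_roi_zip()]. The archive is written natively
#' (STORE method, CRC-32) so no external `zip` binary is needed.
#'
#' @param rois list from [labels_to_rois()].
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
write_roi_zip <- function(rois, path) {
  entries <- lapply(rois, function(roi)
    list(name = paste0(roi$name, ".roi"), bytes = .roi_bytes(roi)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  pos <- 0L
  dosdate <- .le16(c(33L))   # fixed date (1980-01-01 would be 0x21)
  central <- raw(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    nm <- charToRaw(e$name)
    crc <- cp_crc32(e$bytes)
    sz <- length(e$bytes)
    local_hdr <- c(.le32(0x04034b50), .le16(20L), .le16(0L), .le16(0L),
                   .le16(0L), .le16(0L), .le32(crc), .le32(sz), .le32(sz),
                   .le16(length(nm)), .le16(0L), nm)
    offsets[i] <- pos
    writeBin(c(local_hdr, e$bytes), con)
    pos <- pos + length(local_hdr) + sz
    central <- c(central,
                 .le32(0x02014b50), .le16(20L), .le16(20L), .le16(0L),
                 .le16(0L), .le16(0L), .le16(0L), .le32(crc), .le32(sz),
                 .le32(sz), .le16(length(nm)), .le16(0L), .le16(0L),
                 .le16(0L), .le16(0L), .le32(0L), .le32(offsets[i]), nm)
  }
  writeBin(central, con)
  eocd <- c(.le32(0x06054b50), .le16(0L), .le16(0L),
            .le16(length(entries)), .le16(length(entries)),
            .le32(length(central)), .le32(pos), .le16(0L))
  writeBin(eocd, con)
  invisible(path)
}

#' Read an ImageJ ROI ZIP archive
#'
#' Independent reader used as the round-trip oracle: entries are unpacked
#' with `utils::unzip` and each ROI's polygon is decoded from its bytes.
#'
#' @param path `.zip` path.
#' @return named list of `n x 2` vertex matrices (0-based x, y).
#' @export
read_roi_zip <- function(path) {
  tmp <- tempfile("rois")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- suppressWarnings(utils::unzip(path, exdir = tmp))
  if (!length(files)) return(setNames(list(), character(0)))
  out <- lapply(files, function(f)
    .parse_roi_bytes(readBin(f, raw(), n = file.info(f)$size)))
  names(out) <- sub("\\.roi$", "", basename(files))
  out[order(suppressWarnings(as.numeric(names(out))), names(out))]
}

#' Write an RGB outline overlay of a label image
#'
#' Boundary pixels of every label (pixels 4-adjacent to a different value)
#' are drawn in a fixed colour on black; interiors stay black.
#'
#' @param lab integer label matrix.
#' @param path output TIFF path.
#' @param color RGB triplet 0..255.
#' @return `path`, invisibly.
#' @export
write_outline_overlay <- function(lab, path, color = c(255, 0, 0)) {
  b <- label_boundaries(lab)
  img <- array(0, c(nrow(lab), ncol(lab), 3))
  for (k in 1:3) img[, , k][b] <- color[k]
  write_tiff(img, path, type = "rgb8")
  invisible(path)
}

#' Boundary mask of a label image
#'
#' @param lab integer label matrix.
#' @return logical matrix, `TRUE` on label pixels that touch (4-adjacency)
#'   the background or another label.
#' @export
label_boundaries <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  b <- lab > 0L & (lab != pad(lab, -1L, 0L) | lab != pad(lab, 1L, 0L) |
                     lab != pad(lab, 0L, -1L) | lab != pad(lab, 0L, 1L))
  # tiles on the image border are boundary too
  b[1, ] <- b[1, ] | lab[1, ] > 0L
  b[nr, ] <- b[nr, ] | lab[nr, ] > 0L
  b[, 1] <- b[, 1] | lab[, 1] > 0L
  b[, nc] <- b[, nc] | lab[, nc] > 0L
  b
}

#' Export the analysis-ready output tree
#'
#' Deterministic layout: `mosaics/` (uint16 TIFF per cycle x channel),
#' `segmentation/` (int32 label TIFF + RGB overlay), `measurements/`
#' (CSV + FCS), `rois/` (ImageJ ZIP), `logs/`, plus `manifest.json`
#' listing every emitted file with its MD5 checksum. Re-running on
#' identical inputs reproduces an identical manifest. An existing
#' non-empty target is refused unless `overwrite = TRUE`.
#'
#' @param mosaics named list of numeric mosaics (`cyc{NN}_CH{C}` names).
#' @param table a [measurement_table()].
#' @param rois list from [labels_to_rois()].
#' @param labels integer label matrix.
#' @param out_dir target directory.
#' @param overwrite replace a previous run.
#' @param logs optional character vector written to `logs/run.log`.
#' @return path of the manifest, invisibly.
#' @export
export_output_layout <- function(mosaics, table, rois, labels, out_dir,
                                 overwrite = FALSE, logs = character(0)) {
  if (is.null(mosaics) || !length(mosaics))
    stop("no mosaics to export")
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory ", out_dir, " is not empty; use overwrite = TRUE")
  for (d in c("", "mosaics", "segmentation", "measurements", "rois", "logs"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(mosaics)) {
    f <- file.path(out_dir, "mosaics", paste0(nm, ".tif"))
    write_tiff(mosaics[[nm]], f, type = "uint16")
    files <- c(files, f)
  }
  f <- file.path(out_dir, "segmentation", "labels.tif")
  write_tiff(labels, f, type = "int32"); files <- c(files, f)
  f <- file.path(out_dir, "segmentation", "outlines.tif")
  write_outline_overlay(labels, f); files <- c(files, f)
  f <- file.path(out_dir, "measurements", "measurements.csv")
  write_measurements_csv(table, f); files <- c(files, f)
  f <- file.path(out_dir, "measurements", "measurements.fcs")
  write_fcs(table, f); files <- c(files, f)
  f <- file.path(out_dir, "rois", "rois.zip")
  write_roi_zip(rois, f); files <- c(files, f)
  f <- file.path(out_dir, "logs", "run.log")
  writeLines(logs, f); files <- c(files, f)
  norm_out <- normalizePath(out_dir)
  rel <- substring(normalizePath(files), nchar(norm_out) + 2L)
  manifest <- list(files = data.frame(path = rel,
                                      md5 = unname(tools::md5sum(files)),
                                      bytes = unname(file.info(files)$size)))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}
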