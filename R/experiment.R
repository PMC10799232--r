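# Acquisition data model: snake-ordered mosaic grid, cycles/channels,
# tile file naming, and the experiment descriptor JSON + channelNames.txt.
# All user-facing indices (cycle, position, z, channel, row, col) are
# 1-based, matching the instrument's file names; array coordinates are
# 0-based only inside low-level image code.

#' Mosaic grid specification
#'
#' Describes the tile grid of one acquisition: number of columns and rows,
#' fractional overlap between adjacent tiles, and the snake enumeration
#' order (row-major, first row left-to-right, alternating direction on
#' successive rows — the instrument's default reading order).
#'
#' @param n_cols,n_rows positive integers.
#' @param overlap_fraction overlap between adjacent tiles as a fraction of
#'   tile size, in `[0, 1)`. Default 0.1 (10 percent).
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(13, 9)
#' grid_to_index(6, 4, g)  # 75
#' @export
grid_spec <- function(n_cols, n_rows, overlap_fraction = 0.1) {
  stopifnot(length(n_cols) == 1, length(n_rows) == 1,
            n_cols >= 1, n_rows >= 1,
            n_cols == round(n_cols), n_rows == round(n_rows),
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 overlap_fraction = as.numeric(overlap_fraction),
                 ordering = "snake-by-rows",
                 first_row_direction = "left-to-right"),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows (%d tiles), overlap %.1f%%, %s\n",
              x$n_cols, x$n_rows, x$n_cols * x$n_rows,
              100 * x$overlap_fraction, x$ordering))
  invisible(x)
}

#' Snake-order tile index from grid coordinates
#'
#' Odd rows are counted left-to-right, even rows right-to-left, starting at
#' index 1 in the top-left corner.
#'
#' @param row,col 1-based grid coordinates (vectorised).
#' @param grid a [grid_spec()].
#' @return 1-based snake tile index.
#' @export
grid_to_index <- function(row, col, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols))
    stop("row/col outside the ", grid$n_rows, "x", grid$n_cols, " grid")
  within_row <- ifelse(row %% 2L == 1L, col, grid$n_cols - col + 1L)
  (row - 1L) * grid$n_cols + within_row
}

#' Grid coordinates from a snake-order tile index
#'
#' Inverse of [grid_to_index()].
#'
#' @param index 1-based snake index (vectorised).
#' @param grid a [grid_spec()].
#' @return data.frame with columns `row`, `col`.
#' @export
index_to_grid <- function(index, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  index <- as.integer(index)
  if (any(index < 1L | index > grid$n_cols * grid$n_rows))
    stop("index outside 1..", grid$n_cols * grid$n_rows)
  row <- (index - 1L) %/% grid$n_cols + 1L
  within <- (index - 1L) %% grid$n_cols + 1L
  col <- ifelse(row %% 2L == 1L, within, grid$n_cols - within + 1L)
  data.frame(row = row, col = col)
}

#' Address of one acquired image plane
#'
#' @param cycle,position,z,channel 1-based indices: acquisition cycle,
#'   snake tile position, Z plane, fluorescence channel.
#' @return an object of class `tile_key`.
#' @export
tile_key <- function(cycle, position, z, channel) {
  k <- list(cycle = as.integer(cycle), position = as.integer(position),
            z = as.integer(z), channel = as.integer(channel))
  if (any(vapply(k, function(v) length(v) != 1 || is.na(v) || v < 1, logical(1))))
    stop("tile_key indices must be single positive integers")
  structure(k, class = "tile_key")
}

#' @export
print.tile_key <- function(x, ...) {
  cat(sprintf("tile_key: cycle %d, position %d, Z %d, channel %d\n",
              x$cycle, x$position, x$z, x$channel))
  invisible(x)
}

#' Raw tile file name for a tile key
#'
#' Produces `<experiment_name>-position{P}_Z{ZZ}_CH{C}.tif` with the Z index
#' zero-padded to two digits, the flat per-cycle naming used by the
#' instrument (the cycle is encoded by the containing folder, see
#' [cycle_folder_name()]).
#'
#' @param key a [tile_key()].
#' @param experiment_name experiment/image base name.
#' @return file name string.
#' @export
tile_filename <- function(key, experiment_name) {
  stopifnot(inherits(key, "tile_key"))
  sprintf("%s-position%d_Z%02d_CH%d.tif", experiment_name,
          key$position, key$z, key$channel)
}

#' Parse a raw tile file name
#'
#' Inverse of [tile_filename()]. The cycle index is not encoded in the file
#' name; pass it explicitly (e.g. from the folder name).
#'
#' @param filename a base file name.
#' @param cycle 1-based cycle the file belongs to (default 1).
#' @return list with `experiment_name` and the [tile_key()].
#' @export
parse_tile_filename <- function(filename, cycle = 1L) {
  m <- regmatches(filename,
    regexec("^(.*)-position([0-9]+)_Z([0-9]+)_CH([0-9]+)\\.tif$", filename))[[1]]
  if (length(m) != 5L)
    stop("cannot parse tile file name: ", filename)
  list(experiment_name = m[2],
       key = tile_key(cycle, as.integer(m[3]), as.integer(m[4]),
                      as.integer(m[5])))
}

#' Cycle folder name
#'
#' @param cycle 1-based cycle index.
#' @param pattern `sprintf` pattern with one integer slot.
#' @return folder name, `"cyc01"` style by default.
#' @export
cycle_folder_name <- function(cycle, pattern = "cyc%02d") {
  sprintf(pattern, as.integer(cycle))
}

#' Experiment descriptor
#'
#' The single source of truth for an acquisition: grid geometry, optics,
#' channels and per-cycle reporter assignments. Defaults mirror a typical
#' PhenoCycler-style run: 2048 x 2048 px tiles at 0.325 um/px, 11-plane
#' Z-stacks with 1.5 um steps, NA 0.8, four channels with the nuclear stain
#' in channel 1, and a 13 x 9 snake grid at 10 percent overlap.
#'
#' @param name experiment name (used in tile file names).
#' @param grid a [grid_spec()].
#' @param channels data.frame with columns `index`, `name`,
#'   `emission_wavelength` (nm) and optionally `exposure` (ms).
#' @param cycles list, one character vector of reporter names per cycle
#'   (length = number of channels; `"Blank"` marks no reporter). The first
#'   and last cycles are expected blank in all non-nuclear channels.
#' @param n_z number of Z planes.
#' @param z_step Z step, micrometres.
#' @param pixel_size_xy lateral pixel size, micrometres.
#' @param numerical_aperture objective NA.
#' @param refractive_index immersion refractive index.
#' @param tile_width,tile_height tile size in pixels.
#' @param reference_channel nuclear-stain channel (present in every cycle).
#' @param reference_cycle anchor cycle for registration/stitching.
#' @return an object of class `experiment_descriptor`.
#' @export
experiment_descriptor <- function(name = "experiment",
                                  grid = grid_spec(13, 9),
                                  channels = default_channels(),
                                  cycles = default_cycles(nrow(channels), 6L),
                                  n_z = 11L, z_step = 1.5,
                                  pixel_size_xy = 0.325,
                                  numerical_aperture = 0.8,
                                  refractive_index = 1.0,
                                  tile_width = 2048L, tile_height = 2048L,
                                  reference_channel = 1L,
                                  reference_cycle = 1L) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(channels),
            is.list(cycles))
  desc <- structure(list(
    name = name, grid = grid, channels = channels, cycles = cycles,
    n_z = as.integer(n_z), z_step = as.numeric(z_step),
    pixel_size_xy = as.numeric(pixel_size_xy),
    numerical_aperture = as.numeric(numerical_aperture),
    refractive_index = as.numeric(refractive_index),
    tile_width = as.integer(tile_width), tile_height = as.integer(tile_height),
    reference_channel = as.integer(reference_channel),
    reference_cycle = as.integer(reference_cycle)),
    class = "experiment_descriptor")
  validate_descriptor(desc)
  desc
}

#' Default four-channel table (DAPI + three reporter channels)
#' @param exposure optional exposures in ms.
#' @return data.frame usable as `channels` in [experiment_descriptor()].
#' @export
default_channels <- function(exposure = c(5, 400, 500, 500)) {
  data.frame(index = 1:4,
             name = c("DAPI", "ATTO550", "Cy5", "AF750"),
             emission_wavelength = c(461, 580, 670, 776),
             exposure = exposure)
}

#' Default cycle table: blank anchor cycles first and last
#'
#' Channel 1 carries the nuclear stain in every cycle; the first and the
#' last cycle carry no reporters in the remaining channels (blank cycles
#' used for autofluorescence estimation).
#'
#' @param n_channels channels per cycle.
#' @param n_cycles total cycles (>= 2).
#' @return list of per-cycle reporter character vectors.
#' @export
default_cycles <- function(n_channels = 4L, n_cycles = 6L) {
  stopifnot(n_cycles >= 2L)
  lapply(seq_len(n_cycles), function(cyc) {
    rep_names <- if (cyc == 1L || cyc == n_cycles) rep("Blank", n_channels - 1L)
      else paste0("marker_c", cyc, "_ch", seq_len(n_channels - 1L) + 1L)
    c("DAPI", rep_names)
  })
}

validate_descriptor <- function(desc) {
  nch <- nrow(desc$channels)
  if (!identical(desc$channels$index, seq_len(nch)))
    stop("channel indices must be contiguous from 1")
  if (any(desc$channels$emission_wavelength <= 0))
    stop("emission wavelengths must be positive")
  if (desc$n_z < 1L) stop("n_z must be >= 1")
  if (desc$tile_width < 1L || desc$tile_height < 1L)
    stop("tile dimensions must be positive")
  if (desc$reference_channel > nch)
    stop("reference_channel exceeds channel count")
  if (desc$reference_cycle > length(desc$cycles))
    stop("reference_cycle exceeds cycle count")
  bad <- which(vapply(desc$cycles, length, integer(1)) != nch)
  if (length(bad))
    stop("cycle ", bad[1], " has a reporter list of the wrong length")
  nuclear <- vapply(desc$cycles, function(r)
    r[desc$reference_channel] != "Blank", logical(1))
  if (!all(nuclear))
    stop("every cycle must carry the nuclear stain in the reference channel")
  invisible(desc)
}

#' @export
print.experiment_descriptor <- function(x, ...) {
  cat(sprintf(paste0("experiment_descriptor '%s': %d cycles x %d positions x ",
                     "%d Z x %d channels, tiles %dx%d px\n"),
              x$name, n_cycles(x), n_positions(x), x$n_z,
              n_channels(x), x$tile_width, x$tile_height))
  invisible(x)
}

#' @rdname descriptor-counts
#' @param desc an [experiment_descriptor()].
#' @export
n_positions <- function(desc) desc$grid$n_cols * desc$grid$n_rows

#' Descriptor cardinalities
#'
#' Convenience accessors for the number of positions, cycles and channels
#' of an experiment.
#' @name descriptor-counts
#' @export
n_cycles <- function(desc) length(desc$cycles)

#' @rdname descriptor-counts
#' @export
n_channels <- function(desc) nrow(desc$channels)

#' Blank flags per cycle and channel
#'
#' @param desc an [experiment_descriptor()].
#' @return logical matrix `[cycle, channel]`, `TRUE` where the reporter is
#'   `"Blank"` (no reporter; pure autofluorescence).
#' @export
blank_matrix <- function(desc) {
  t(vapply(desc$cycles, function(r) r == "Blank", logical(n_channels(desc))))
}

required_keys <- c("name", "grid", "channels", "n_cycles", "n_z", "z_step",
                   "pixel_size_xy", "numerical_aperture", "tile_width",
                   "tile_height")

#' Parse an experiment descriptor JSON
#'
#' Reads the documented descriptor schema (see [write_experiment_json()]).
#' Unknown keys are preserved under attribute `"extra_keys"` but otherwise
#' ignored. Missing optional keys take the documented defaults
#' (`refractive_index` 1.0, `reference_channel` 1, `reference_cycle` 1,
#' snake ordering left-to-right on row 1).
#'
#' @param path_or_text file path, or a JSON string.
#' @param cycles optional per-cycle reporter lists (e.g. from
#'   [parse_channel_names()]); if absent they are taken from the JSON
#'   `"cycles"` key or default to blank-anchored placeholders.
#' @return an [experiment_descriptor()].
#' @export
parse_experiment <- function(path_or_text, cycles = NULL) {
  txt <- if (length(path_or_text) == 1 && file.exists(path_or_text))
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  else paste(path_or_text, collapse = "\n")
  j <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  missing <- setdiff(required_keys, names(j))
  if (length(missing))
    stop("experiment descriptor is missing required key(s): ",
         paste(missing, collapse = ", "))
  gmiss <- setdiff(c("n_cols", "n_rows", "overlap_fraction"), names(j$grid))
  if (length(gmiss))
    stop("experiment descriptor is missing required key(s): ",
         paste(paste0("grid.", gmiss), collapse = ", "))
  grid <- grid_spec(j$grid$n_cols, j$grid$n_rows, j$grid$overlap_fraction)
  channels <- as.data.frame(j$channels)
  if (is.null(cycles)) {
    cycles <- if (!is.null(j$cycles)) lapply(seq_len(nrow(j$cycles) %||% 0),
                                             function(i) unlist(j$cycles[i, ]))
      else NULL
    if (is.null(cycles) || !length(cycles)) {
      if (is.list(j$cycles) && !is.data.frame(j$cycles) && length(j$cycles))
        cycles <- lapply(j$cycles, unlist)
      else
        cycles <- default_cycles(nrow(channels), j$n_cycles)
    }
  }
  desc <- experiment_descriptor(
    name = j$name, grid = grid, channels = channels, cycles = cycles,
    n_z = j$n_z, z_step = j$z_step, pixel_size_xy = j$pixel_size_xy,
    numerical_aperture = j$numerical_aperture,
    refractive_index = j$refractive_index %||% 1.0,
    tile_width = j$tile_width, tile_height = j$tile_height,
    reference_channel = j$reference_channel %||% 1L,
    reference_cycle = j$reference_cycle %||% 1L)
  extra <- setdiff(names(j), c(required_keys, "cycles", "refractive_index",
                               "reference_channel", "reference_cycle"))
  if (length(extra)) attr(desc, "extra_keys") <- j[extra]
  desc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the experiment descriptor JSON
#'
#' @param desc an [experiment_descriptor()].
#' @param path output path (conventionally `Experiment.json`).
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(desc, path) {
  j <- list(name = desc$name,
            grid = list(n_cols = desc$grid$n_cols, n_rows = desc$grid$n_rows,
                        overlap_fraction = desc$grid$overlap_fraction,
                        ordering = desc$grid$ordering,
                        first_row_direction = desc$grid$first_row_direction),
            channels = desc$channels,
            cycles = desc$cycles,
            n_cycles = n_cycles(desc),
            n_z = desc$n_z, z_step = desc$z_step,
            pixel_size_xy = desc$pixel_size_xy,
            numerical_aperture = desc$numerical_aperture,
            refractive_index = desc$refractive_index,
            tile_width = desc$tile_width, tile_height = desc$tile_height,
            reference_channel = desc$reference_channel,
            reference_cycle = desc$reference_cycle)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse channelNames.txt
#'
#' One reporter name per line in cycle-major order (all channels of cycle 1,
#' then all channels of cycle 2, ...). The literal `"Blank"` marks a
#' channel acquired without reporter.
#'
#' @param path_or_lines file path or character vector of lines.
#' @param desc an [experiment_descriptor()] giving the expected
#'   cycle/channel counts.
#' @return list with `cycles` (per-cycle reporter vectors) and `blank`
#'   (logical matrix `[cycle, channel]`).
#' @export
parse_channel_names <- function(path_or_lines, desc) {
  lines <- if (length(path_or_lines) == 1 && file.exists(path_or_lines))
    readLines(path_or_lines, warn = FALSE) else path_or_lines
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  nc <- n_cycles(desc); nch <- n_channels(desc)
  if (length(lines) != nc * nch)
    stop("channelNames.txt has ", length(lines), " entries but the ",
         "descriptor implies ", nc, " cycles x ", nch, " channels = ",
         nc * nch)
  cyc <- split(lines, rep(seq_len(nc), each = nch))
  cyc <- unname(lapply(cyc, unname))
  blank <- t(vapply(cyc, function(r) r == "Blank", logical(nch)))
  list(cycles = cyc, blank = blank)
}

#' Write channelNames.txt
#'
#' @param desc an [experiment_descriptor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_names <- function(desc, path) {
  writeLines(unlist(desc$cycles), path)
  invisible(path)
}
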