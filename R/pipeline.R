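# Pipeline driver: runs the canonical stage order over an on-disk
# acquisition, staging every intermediate in a work directory so any
# suffix of the pipeline can resume from disk, and collecting a run
# report. Stage parameters default to the instrument-tuned values
# (RL 10 iterations, shading sigma 64 px, background sigma 10 px,
# reference cycle 1, reference channel 1).

PIPELINE_STEPS <- c("deconvolve", "edf", "shading", "background", "register",
                    "clip_negatives", "stitch", "segment", "overlay",
                    "measure", "export")

#' Pipeline configuration
#'
#' @param input_dir raw acquisition directory (cycle folders +
#'   `Experiment.json` + `channelNames.txt`).
#' @param work_dir stage intermediates directory.
#' @param output_dir final analysis-ready tree.
#' @param steps ordered subset of the canonical steps; defaults to all of
#'   `deconvolve, edf, shading, background, register, clip_negatives,
#'   stitch, segment, overlay, measure, export`.
#' @param rl_iterations Richardson-Lucy iterations (Step 0).
#' @param deconvolve run deconvolution (it is optional; any external
#'   deconvolution can be substituted by pre-staging its output).
#' @param shading_sigma shading-profile blur sigma, px.
#' @param shading_mode `"ratio"` or `"smooth"` (see
#'   [compute_shading_profile()]).
#' @param background_sigma blank-cycle blur sigma, px.
#' @param subpixel subpixel registration refinement.
#' @param blend mosaic blending mode (see [compose_mosaic()]).
#' @param segment_params list passed on to [segment_nuclei()].
#' @param seed integer seed (for reproducibility bookkeeping).
#' @param overwrite allow writing into a non-empty output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, work_dir, output_dir,
                            steps = PIPELINE_STEPS,
                            rl_iterations = 10L, deconvolve = TRUE,
                            shading_sigma = 64, shading_mode = "ratio",
                            background_sigma = 10, subpixel = FALSE,
                            blend = "feather",
                            segment_params = list(), seed = 1L,
                            overwrite = FALSE) {
  steps <- match.arg(steps, PIPELINE_STEPS, several.ok = TRUE)
  if (!deconvolve) steps <- setdiff(steps, "deconvolve")
  bad <- which(diff(match(steps, PIPELINE_STEPS)) <= 0)
  if (length(bad)) stop("steps must follow the canonical order: ",
                        paste(PIPELINE_STEPS, collapse = ", "))
  stopifnot(rl_iterations >= 0, shading_sigma > 0, background_sigma > 0)
  structure(list(input_dir = input_dir, work_dir = work_dir,
                 output_dir = output_dir, steps = steps,
                 rl_iterations = as.integer(rl_iterations),
                 shading_sigma = shading_sigma, shading_mode = shading_mode,
                 background_sigma = background_sigma,
                 subpixel = isTRUE(subpixel), blend = blend,
                 segment_params = segment_params,
                 seed = as.integer(seed), overwrite = isTRUE(overwrite)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- j[intersect(names(j), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Validate a raw acquisition directory
#'
#' Checks the folder-per-cycle layout, the per-folder file count
#' (positions x n_z x channels), that every file name parses, and that
#' all image shapes agree with the descriptor. Violations are reported,
#' not thrown.
#'
#' @param input_dir acquisition directory.
#' @param desc an [experiment_descriptor()]; read from
#'   `Experiment.json`/`channelNames.txt` in `input_dir` when omitted.
#' @param check_shapes read every TIFF and verify its shape (slower).
#' @return list with `violations` (character vector) and `n_files_per_cycle`.
#' @export
validate_inputs <- function(input_dir, desc = NULL, check_shapes = FALSE) {
  violations <- character(0)
  if (is.null(desc)) {
    ej <- file.path(input_dir, "Experiment.json")
    if (!file.exists(ej))
      return(list(violations = paste0("missing Experiment.json in ", input_dir),
                  n_files_per_cycle = NA_integer_))
    cn <- file.path(input_dir, "channelNames.txt")
    desc <- parse_experiment(ej)
    if (file.exists(cn))
      desc$cycles <- parse_channel_names(cn, desc)$cycles
  }
  expected <- n_positions(desc) * desc$n_z * n_channels(desc)
  for (cyc in seq_len(n_cycles(desc))) {
    cdir <- file.path(input_dir, cycle_folder_name(cyc))
    if (!dir.exists(cdir)) {
      violations <- c(violations, paste0("missing cycle folder: ",
                                         cycle_folder_name(cyc)))
      next
    }
    files <- list.files(cdir, pattern = "\\.tif$")
    if (length(files) != expected)
      violations <- c(violations, sprintf(
        "cycle %d: %d files, expected %d", cyc, length(files), expected))
    for (pos in seq_len(n_positions(desc)))
      for (z in seq_len(desc$n_z))
        for (ch in seq_len(n_channels(desc))) {
          key <- tile_key(cyc, pos, z, ch)
          f <- file.path(cdir, tile_filename(key, desc$name))
          if (!file.exists(f)) {
            violations <- c(violations, sprintf(
              "missing tile: cycle %d position %d Z %d channel %d", cyc, pos,
              z, ch))
          } else if (check_shapes) {
            img <- tryCatch(read_tiff(f), error = function(e) NULL)
            if (is.null(img) || nrow(img) != desc$tile_height ||
                ncol(img) != desc$tile_width)
              violations <- c(violations, sprintf(
                "bad shape: cycle %d position %d Z %d channel %d", cyc, pos,
                z, ch))
          }
        }
  }
  list(violations = violations, n_files_per_cycle = expected,
       descriptor = desc)
}

.edf_name <- function(cyc, pos, ch)
  sprintf("cyc%02d_pos%d_CH%d.tif", cyc, pos, ch)

.read_stack <- function(dir, desc, cyc, pos, ch) {
  planes <- lapply(seq_len(desc$n_z), function(z)
    read_tiff(file.path(dir, cycle_folder_name(cyc),
                        tile_filename(tile_key(cyc, pos, z, ch), desc$name))))
  array(unlist(planes), c(dim(planes[[1]]), desc$n_z))
}

#' Run the preprocessing pipeline
#'
#' Executes the requested steps in canonical order. Every step writes its
#' outputs under `work_dir` (float32 intermediates) so the pipeline can be
#' resumed from any step whose inputs are already on disk; the final
#' `export` step builds the analysis-ready tree in `output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return run report: per-step status and timing, collected warnings, and
#'   the validated descriptor.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- Sys.time()
  report <- list(steps = list(), warnings = character(0))
  note <- function(...) {
    report$warnings <<- c(report$warnings, sprintf(...))
  }
  wd <- config$work_dir
  dir.create(wd, recursive = TRUE, showWarnings = FALSE)

  val <- validate_inputs(config$input_dir)
  desc <- val$descriptor
  if (is.null(desc) || (length(val$violations) &&
      any(grepl("missing Experiment.json|missing cycle folder", val$violations))))
    stop("invalid input layout: ", paste(val$violations, collapse = "; "))
  if (length(val$violations))
    stop("input validation failed: ", paste(head(val$violations, 5),
                                            collapse = "; "))
  report$descriptor <- desc
  nC <- n_cycles(desc); nch <- n_channels(desc); nP <- n_positions(desc)
  blank <- blank_matrix(desc)

  stage_dir <- function(s) file.path(wd, s)
  need_stage <- function(s, what) {
    if (!dir.exists(stage_dir(s)))
      stop("step '", what, "' needs outputs of stage '", s,
           "' which are not in ", wd)
  }
  run_step <- function(name, fun) {
    if (!(name %in% config$steps)) return(invisible(NULL))
    t0 <- Sys.time()
    fun()
    report$steps[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  ## Step 0: deconvolution (optional)
  run_step("deconvolve", function() {
    ddir <- stage_dir("deconvolved")
    dir.create(ddir, showWarnings = FALSE)
    for (cyc in seq_len(nC)) {
      cdir <- file.path(ddir, cycle_folder_name(cyc))
      dir.create(cdir, showWarnings = FALSE)
      for (ch in seq_len(nch)) {
        psf <- generate_psf(desc$channels$emission_wavelength[ch],
                            desc$numerical_aperture,
                            c(desc$pixel_size_xy, desc$pixel_size_xy,
                              desc$z_step),
                            refractive_index = desc$refractive_index)
        for (pos in seq_len(nP)) {
          stack <- .read_stack(config$input_dir, desc, cyc, pos, ch)
          out <- richardson_lucy(stack, psf, config$rl_iterations)
          for (z in seq_len(desc$n_z))
            write_tiff(out[, , z],
                       file.path(cdir, tile_filename(
                         tile_key(cyc, pos, z, ch), desc$name)), "float32")
        }
      }
    }
  })

  ## Step 1: extended depth of field -> 2D tiles
  run_step("edf", function() {
    src <- if (dir.exists(stage_dir("deconvolved"))) stage_dir("deconvolved")
      else config$input_dir
    edir <- stage_dir("edf")
    dir.create(edir, showWarnings = FALSE)
    for (cyc in seq_len(nC))
      for (pos in seq_len(nP))
        for (ch in seq_len(nch)) {
          stack <- .read_stack(src, desc, cyc, pos, ch)
          e <- extended_depth_of_field(stack)
          write_tiff(e$image, file.path(edir, .edf_name(cyc, pos, ch)),
                     "float32")
        }
  })

  read_stage <- function(s, cyc, pos, ch)
    read_tiff(file.path(stage_dir(s), .edf_name(cyc, pos, ch)))

  ## Step 2: shading correction with cycle interpolation
  run_step("shading", function() {
    need_stage("edf", "shading")
    sdir <- stage_dir("shaded")
    dir.create(sdir, showWarnings = FALSE)
    for (ch in seq_len(nch)) {
      prof <- lapply(c(1L, nC), function(cyc) {
        tiles <- lapply(seq_len(nP), function(pos) read_stage("edf", cyc, pos, ch))
        withCallingHandlers(
          compute_shading_profile(tiles, sigma = config$shading_sigma,
                                  mode = config$shading_mode),
          warning = function(w) {
            note("shading CH%d cycle %d: %s", ch, cyc, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      })
      write_tiff(prof[[1]]$field, file.path(sdir, sprintf("profile_first_CH%d.tif", ch)),
                 "float32")
      write_tiff(prof[[2]]$field, file.path(sdir, sprintf("profile_last_CH%d.tif", ch)),
                 "float32")
      for (cyc in seq_len(nC)) {
        field <- interpolate_profile(prof[[1]], prof[[2]], cyc, nC)
        field <- pmax(field, 1e-6)
        for (pos in seq_len(nP))
          write_tiff(apply_shading(read_stage("edf", cyc, pos, ch), field),
                     file.path(sdir, .edf_name(cyc, pos, ch)), "float32")
      }
    }
  })

  ## Step 3: blank-cycle autofluorescence subtraction
  run_step("background", function() {
    need_stage("shaded", "background")
    bdir <- stage_dir("bg_subtracted")
    dir.create(bdir, showWarnings = FALSE)
    for (ch in seq_len(nch))
      for (pos in seq_len(nP)) {
        if (ch == desc$reference_channel || !blank[1, ch] || !blank[nC, ch]) {
          # nuclear (or never-blank) channel: no blank anchors to subtract
          for (cyc in seq_len(nC))
            write_tiff(read_stage("shaded", cyc, pos, ch),
                       file.path(bdir, .edf_name(cyc, pos, ch)), "float32")
          next
        }
        first_bg <- compute_background(read_stage("shaded", 1L, pos, ch),
                                       config$background_sigma)
        last_bg <- compute_background(read_stage("shaded", nC, pos, ch),
                                      config$background_sigma)
        for (cyc in seq_len(nC))
          write_tiff(subtract_background(read_stage("shaded", cyc, pos, ch),
                                         first_bg, last_bg, cyc, nC),
                     file.path(bdir, .edf_name(cyc, pos, ch)), "float32")
      }
  })

  ## Step 4: inter-cycle registration + crop to common frame
  run_step("register", function() {
    need_stage("bg_subtracted", "register")
    rdir <- stage_dir("registered")
    dir.create(rdir, showWarnings = FALSE)
    # estimate all positions first so one global crop keeps every
    # position's tiles the same shape for stitching
    trans_by_pos <- lapply(seq_len(nP), function(pos) {
      nuclear <- lapply(seq_len(nC), function(cyc)
        read_stage("bg_subtracted", cyc, pos, desc$reference_channel))
      register_cycles(nuclear, desc$reference_cycle,
                      subpixel = config$subpixel)
    })
    all_dx <- unlist(lapply(trans_by_pos, function(trs)
      vapply(trs, `[[`, numeric(1), "dx")))
    all_dy <- unlist(lapply(trans_by_pos, function(trs)
      vapply(trs, `[[`, numeric(1), "dy")))
    gmx <- ceiling(max(abs(all_dx))); gmy <- ceiling(max(abs(all_dy)))
    trans_all <- list()
    for (pos in seq_len(nP)) {
      tiles <- lapply(seq_len(nC), function(cyc)
        lapply(seq_len(nch), function(ch)
          read_stage("bg_subtracted", cyc, pos, ch)))
      cropped <- crop_to_common(tiles, trans_by_pos[[pos]],
                                margin_x = gmx, margin_y = gmy)
      for (cyc in seq_len(nC))
        for (ch in seq_len(nch))
          write_tiff(cropped[[cyc]][[ch]],
                     file.path(rdir, .edf_name(cyc, pos, ch)), "float32")
      trans_all[[pos]] <- lapply(trans_by_pos[[pos]], function(tr)
        list(dx = tr$dx, dy = tr$dy, quality = tr$quality))
    }
    jsonlite::write_json(trans_all, file.path(rdir, "translations.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  ## Step 5: clip negatives and rebase positives
  run_step("clip_negatives", function() {
    need_stage("registered", "clip_negatives")
    cdir <- stage_dir("clipped")
    dir.create(cdir, showWarnings = FALSE)
    for (cyc in seq_len(nC))
      for (pos in seq_len(nP))
        for (ch in seq_len(nch))
          write_tiff(remove_negative_values(read_stage("registered", cyc, pos, ch)),
                     file.path(cdir, .edf_name(cyc, pos, ch)), "float32")
  })

  ## Step 6: stitching (layout from reference cycle/channel, reused)
  run_step("stitch", function() {
    need_stage("clipped", "stitch")
    mdir <- stage_dir("mosaics")
    dir.create(mdir, showWarnings = FALSE)
    ref_tiles <- lapply(seq_len(nP), function(pos)
      read_stage("clipped", desc$reference_cycle, pos, desc$reference_channel))
    d <- dim(ref_tiles[[1]])
    # nominal stage spacing comes from the acquired tile size: the
    # drift crop shrinks tiles around their centres, not the grid pitch
    step <- c(round(desc$tile_width * (1 - desc$grid$overlap_fraction)),
              round(desc$tile_height * (1 - desc$grid$overlap_fraction)))
    offsets <- estimate_pairwise_offsets(ref_tiles, desc$grid, step = step)
    if (any(offsets$fallback))
      note("stitching: %d seam(s) fell back to the nominal offset",
           sum(offsets$fallback))
    layout <- solve_global_positions(offsets, desc$grid, d[2], d[1])
    jsonlite::write_json(list(positions = layout$positions,
                              mosaic_width = layout$mosaic_width,
                              mosaic_height = layout$mosaic_height,
                              tile_width = layout$tile_width,
                              tile_height = layout$tile_height),
                         file.path(mdir, "layout.json"),
                         auto_unbox = TRUE, digits = NA)
    for (cyc in seq_len(nC))
      for (ch in seq_len(nch)) {
        tiles <- lapply(seq_len(nP), function(pos)
          read_stage("clipped", cyc, pos, ch))
        mosaic <- compose_mosaic(tiles, layout, blend = config$blend)
        write_tiff(mosaic,
                   file.path(mdir, sprintf("cyc%02d_CH%d.tif", cyc, ch)),
                   "uint16")
      }
  })

  read_mosaic <- function(cyc, ch)
    read_tiff(file.path(stage_dir("mosaics"),
                        sprintf("cyc%02d_CH%d.tif", cyc, ch)))

  ## Step 7: nuclei segmentation on the reference nuclear mosaic
  run_step("segment", function() {
    need_stage("mosaics", "segment")
    gdir <- stage_dir("cells")
    dir.create(gdir, showWarnings = FALSE)
    nuclear <- read_mosaic(desc$reference_cycle, desc$reference_channel)
    lab <- do.call(segment_nuclei,
                   c(list(img = nuclear), config$segment_params))
    write_tiff(lab, file.path(gdir, "labels.tif"), "int32")
    rois <- labels_to_rois(lab)
    write_roi_zip(rois, file.path(gdir, "rois.zip"))
  })

  ## Step 8: outline overlay
  run_step("overlay", function() {
    need_stage("cells", "overlay")
    lab <- read_tiff(file.path(stage_dir("cells"), "labels.tif"))
    write_outline_overlay(lab, file.path(stage_dir("cells"), "outlines.tif"))
  })

  ## Step 9: per-cell measurements over non-blank channels
  run_step("measure", function() {
    need_stage("cells", "measure")
    need_stage("mosaics", "measure")
    lab <- read_tiff(file.path(stage_dir("cells"), "labels.tif"))
    mosaics <- list()
    for (cyc in seq_len(nC))
      for (ch in seq_len(nch)) {
        if (blank[cyc, ch]) next
        nm <- sprintf("cyc%02d_ch%d_%s", cyc, ch, desc$cycles[[cyc]][ch])
        mosaics[[nm]] <- read_mosaic(cyc, ch)
      }
    cells <- measure_cells(lab, mosaics)
    table <- measurement_table(cells)
    write_measurements_csv(table, file.path(stage_dir("cells"),
                                            "measurements.csv"))
  })

  ## Step 10: analysis-ready output tree
  run_step("export", function() {
    need_stage("mosaics", "export")
    need_stage("cells", "export")
    lab <- read_tiff(file.path(stage_dir("cells"), "labels.tif"))
    table <- read_measurements_csv(file.path(stage_dir("cells"),
                                             "measurements.csv"))
    mosaics <- list()
    for (cyc in seq_len(nC))
      for (ch in seq_len(nch)) {
        nm <- sprintf("cyc%02d_CH%d", cyc, ch)
        mosaics[[nm]] <- read_mosaic(cyc, ch)
      }
    export_output_layout(mosaics, table, labels_to_rois(lab), lab,
                         config$output_dir, overwrite = config$overwrite,
                         logs = c(sprintf("seed: %d", config$seed),
                                  report$warnings))
  })

  report$seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  report$config <- config
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline run:", length(x$steps), "step(s) in",
      sprintf("%.1f s", x$seconds), "\n")
  for (nm in names(x$steps))
    cat(sprintf("  %-15s %s (%.1f s)\n", nm, x$steps[[nm]]$status,
                x$steps[[nm]]$seconds))
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
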