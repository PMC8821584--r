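#' Image and table I/O helpers
#'
#' Grayscale images travel as TIFF: 16-bit integer-quantized channels
#' (interferograms, fluorescence), 32-bit float for phase (normalized to
#' `[0, 1]` with offset/scale recorded in a JSON sidecar carrying pixel size
#' and wavelength), 8-bit for \{0,1,2\} label maps. Tables are CSV, reports
#' and manifests JSON.
#'
#' @name io-helpers
NULL

#' @rdname io-helpers
#' @param x Numeric matrix with values in `[0, 1]`.
#' @param path Output file path.
#' @param bits 8, 16 or 32 bits per sample.
#' @export
write_tiff_image <- function(x, path, bits = 16L) {
  stopifnot(is.matrix(x))
  if (bits != 32L && (min(x) < 0 || max(x) > 1)) {
    abort("Integer TIFF images must lie in [0, 1].",
          class = "phaseviab_format_error")
  }
  tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname io-helpers
#' @export
read_tiff_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("TIFF file not found: %s", path),
          class = "phaseviab_io_error")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname io-helpers
#' @param pm A [phase_map()]. Written as a normalized 32-bit float TIFF plus
#'   a `<path>.json` sidecar holding offset, scale, pixel size and
#'   wavelength.
#' @export
write_phase_tiff <- function(pm, path) {
  stopifnot(inherits(pm, "phase_map"))
  lo <- min(pm$phase)
  hi <- max(pm$phase)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (pm$phase - lo) / scale
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  meta <- list(offset = lo, scale = scale,
               pixel_size_um = pm$pixel_size_um,
               wavelength_um = pm$wavelength_um)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname io-helpers
#' @export
read_phase_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    abort(sprintf("Phase TIFF or its JSON sidecar missing: %s", path),
          class = "phaseviab_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  norm <- read_tiff_image(path)
  phase_map(norm * meta$scale + meta$offset,
            pixel_size_um = meta$pixel_size_um,
            wavelength_um = meta$wavelength_um)
}

#' @rdname io-helpers
#' @param map A [semantic_map()]; stored as an 8-bit indexed TIFF with the
#'   raw values \{0,1,2\}.
#' @export
write_label_tiff <- function(map, path) {
  lab <- as_label_matrix(map)
  tiff::writeTIFF(lab / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname io-helpers
#' @export
read_label_tiff <- function(path) {
  img <- read_tiff_image(path)
  lab <- round(img * 255)
  if (!all(lab %in% 0:2)) {
    abort(sprintf("Label TIFF %s contains values outside {0, 1, 2}.", path),
          class = "phaseviab_format_error")
  }
  semantic_map(matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

#' @rdname io-helpers
#' @param tracks Measured tracks tibble (see [measure_track()]).
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname io-helpers
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Track CSV not found: %s", path),
          class = "phaseviab_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname io-helpers
#' @param report Named list of results.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname io-helpers
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Report JSON not found: %s", path),
          class = "phaseviab_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---- experiment directory layout -------------------------------------------

#' Write a simulated experiment to a dataset directory
#'
#' Directory layout: `manifest.json` (configuration, seed, optics),
#' `truth_records.csv` (per-frame per-nucleus truth),
#' `frame_XXX/interf_k.tif` (four 16-bit interferograms),
#' `frame_XXX/phase.tif` (+ JSON sidecar), `frame_XXX/blue.tif`,
#' `frame_XXX/green.tif`, `frame_XXX/truth.tif`. All downstream stages (and
#' the command-line interface) consume this layout.
#'
#' @param ex A `sim_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(ex, dir) {
  stopifnot(inherits(ex, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_len(ex$cfg$n_frames)) {
    fd <- file.path(dir, sprintf("frame_%03d", f))
    dir.create(fd, showWarnings = FALSE)
    for (k in 1:4) {
      write_tiff_image(ex$stacks[[f]]$frames[[k]],
                       file.path(fd, sprintf("interf_%d.tif", k)), bits = 16L)
    }
    write_phase_tiff(ex$phases[[f]], file.path(fd, "phase.tif"))
    write_tiff_image(ex$fluors[[f]]$blue, file.path(fd, "blue.tif"), bits = 16L)
    write_tiff_image(ex$fluors[[f]]$green, file.path(fd, "green.tif"), bits = 16L)
    write_label_tiff(ex$truths[[f]], file.path(fd, "truth.tif"))
  }
  readr::write_csv(ex$records, file.path(dir, "truth_records.csv"))
  readr::write_csv(ex$cells, file.path(dir, "truth_cells.csv"))
  manifest <- list(
    config = unclass(ex$cfg),
    optics = unclass(ex$optics),
    n_frames = ex$cfg$n_frames,
    seed = ex$cfg$seed
  )
  write_report_json(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a dataset directory written by [write_experiment()]
#'
#' @param dir Dataset directory.
#' @return A `sim_experiment`-shaped list (configuration, per-frame stacks,
#'   phases, fluorescence pairs, truth maps, truth records).
#' @export
read_experiment <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    abort(sprintf("Not a dataset directory (no manifest.json): %s", dir),
          class = "phaseviab_io_error")
  }
  mf <- read_report_json(mf_path)
  cfg <- do.call(sim_config, mf$config[names(mf$config) %in%
                                         names(formals(sim_config))])
  opt <- do.call(optics_config, mf$optics[names(mf$optics) %in%
                                            names(formals(optics_config))])
  n <- mf$n_frames
  phases <- stacks <- fluors <- truths <- vector("list", n)
  for (f in seq_len(n)) {
    fd <- file.path(dir, sprintf("frame_%03d", f))
    frames <- lapply(1:4, function(k)
      read_tiff_image(file.path(fd, sprintf("interf_%d.tif", k))))
    stacks[[f]] <- intensity_stack(frames, pixel_size_um = opt$pixel_size_um)
    phases[[f]] <- read_phase_tiff(file.path(fd, "phase.tif"))
    fluors[[f]] <- fluor_pair(read_tiff_image(file.path(fd, "blue.tif")),
                              read_tiff_image(file.path(fd, "green.tif")))
    truths[[f]] <- read_label_tiff(file.path(fd, "truth.tif"))
  }
  records <- readr::read_csv(file.path(dir, "truth_records.csv"),
                             show_col_types = FALSE)
  cells <- readr::read_csv(file.path(dir, "truth_cells.csv"),
                           show_col_types = FALSE)
  structure(
    list(cfg = cfg, optics = opt, cells = cells, phases = phases,
         stacks = stacks, fluors = fluors, truths = truths,
         records = records),
    class = "sim_experiment"
  )
}
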