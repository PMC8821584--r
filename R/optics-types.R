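#' Optics configuration for SLIM phase reconstruction and dry mass
#'
#' Bundles the physical constants used by [reconstruct_phase()] and
#' [compute_dry_mass()].
#'
#' @param b_ratio Scattered-to-incident field amplitude ratio (dimensionless,
#'   >= 0), or the string `"identity"` (default) in which case
#'   [reconstruct_phase()] returns the raw four-frame phase difference without
#'   the amplitude-ratio composition step.
#' @param wavelength_um Central illumination wavelength in micrometres. The
#'   default 0.55 is representative of a broadband white-light LED source.
#' @param pixel_size_um Effective object-plane pixel pitch in micrometres.
#'   The default 0.1625 corresponds to a 6.5 um camera pixel behind a 40x
#'   objective.
#' @param alpha_ri_um3_per_pg Refractive increment of cellular dry matter in
#'   um^3/pg (numerically equal to the conventional 0.2 mL/g).
#' @return An object of class `optics_config`.
#' @export
#' @examples
#' cfg <- optics_config()
#' cfg$pixel_size_um
optics_config <- function(b_ratio = "identity",
                          wavelength_um = 0.55,
                          pixel_size_um = 0.1625,
                          alpha_ri_um3_per_pg = 0.2) {
  if (!identical(b_ratio, "identity")) {
    stopifnot(is.numeric(b_ratio), length(b_ratio) == 1L, b_ratio >= 0)
  }
  stopifnot(wavelength_um > 0, pixel_size_um > 0, alpha_ri_um3_per_pg > 0)
  structure(
    list(
      b_ratio = b_ratio,
      wavelength_um = wavelength_um,
      pixel_size_um = pixel_size_um,
      alpha_ri_um3_per_pg = alpha_ri_um3_per_pg
    ),
    class = "optics_config"
  )
}

#' Quantitative phase map
#'
#' A 2-D quantitative phase image in radians together with the acquisition
#' metadata needed to convert phase to physical units (dry mass, areas).
#'
#' @param phase Numeric matrix of per-pixel optical phase delay (radians).
#' @param pixel_size_um Object-plane pixel pitch (micrometres per pixel).
#' @param wavelength_um Central illumination wavelength (micrometres).
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase, pixel_size_um = 0.1625, wavelength_um = 0.55) {
  if (!is.matrix(phase) || !is.numeric(phase)) {
    abort("`phase` must be a numeric matrix.", class = "phaseviab_arg_error")
  }
  if (!all(is.finite(phase))) {
    abort("`phase` must be finite everywhere.", class = "phaseviab_arg_error")
  }
  stopifnot(pixel_size_um > 0, wavelength_um > 0)
  structure(
    list(
      phase = phase,
      pixel_size_um = pixel_size_um,
      wavelength_um = wavelength_um
    ),
    class = "phase_map"
  )
}

#' @export
print.phase_map <- function(x, ...) {
  cat(
    sprintf(
      "<phase_map> %d x %d px, %.4f um/px, lambda %.3f um, range [%.3f, %.3f] rad\n",
      nrow(x$phase), ncol(x$phase), x$pixel_size_um, x$wavelength_um,
      min(x$phase), max(x$phase)
    )
  )
  invisible(x)
}

#' Four-frame phase-shifted intensity stack
#'
#' The raw SLIM acquisition: four co-registered intensity images recorded at
#' modulator phase shifts of 0, pi/2, pi and 3*pi/2.
#'
#' @param frames A list of four numeric matrices with identical dimensions and
#'   non-negative values, ordered by modulator shift.
#' @param pixel_size_um Object-plane pixel pitch (micrometres per pixel).
#' @return An object of class `intensity_stack`.
#' @export
intensity_stack <- function(frames, pixel_size_um = 0.1625) {
  if (!is.list(frames) || length(frames) != 4L) {
    abort("`frames` must be a list of exactly 4 matrices.",
          class = "phaseviab_arg_error")
  }
  dims <- lapply(frames, dim)
  if (!all(vapply(frames, is.matrix, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All 4 frames must be matrices with identical dimensions.",
          class = "phaseviab_arg_error")
  }
  if (any(vapply(frames, function(f) any(f < 0), logical(1)))) {
    abort("Intensity frames must be non-negative.",
          class = "phaseviab_arg_error")
  }
  stopifnot(pixel_size_um > 0)
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um),
    class = "intensity_stack"
  )
}
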