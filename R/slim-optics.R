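#' Reconstruct a quantitative phase map from four phase-shifted interferograms
#'
#' Standard four-step phase-shifting estimator. With frames \eqn{I_k} recorded
#' at modulator shifts \eqn{0, \pi/2, \pi, 3\pi/2}, the per-pixel phase
#' difference between scattered and incident fields is
#' \deqn{\Delta\phi = \mathrm{atan2}(I_{3\pi/2} - I_{\pi/2},\; I_0 - I_\pi).}
#' When `cfg$b_ratio` is a number \eqn{b}, the total object phase is composed
#' as \eqn{\phi = \mathrm{atan}\,[b\sin\Delta\phi / (1 + b\cos\Delta\phi)]};
#' when it is `"identity"` (the default) \eqn{\Delta\phi} is returned
#' directly.
#'
#' Pixels where both numerator and denominator fall below `contrast_floor`
#' carry no fringe contrast; they are set to 0 and counted. If more than half
#' of all pixels are degenerate the reconstruction aborts.
#'
#' @param stack An [intensity_stack()].
#' @param cfg An [optics_config()].
#' @param contrast_floor Contrast magnitude (normalized intensity units) below
#'   which a pixel is treated as degenerate.
#' @return A [phase_map()]; attribute `n_degenerate` carries the count of
#'   zeroed pixels.
#' @seealso [forward_slim()] for the matching forward model.
#' @export
#' @examples
#' pm <- phase_map(matrix(0.5, 8, 8))
#' st <- forward_slim(pm, b_ratio = 0.3)
#' rec <- reconstruct_phase(st, optics_config())
#' max(abs(rec$phase - pm$phase))
reconstruct_phase <- function(stack, cfg = optics_config(),
                              contrast_floor = 1e-12) {
  if (!inherits(stack, "intensity_stack")) {
    abort("`stack` must be an intensity_stack.", class = "phaseviab_arg_error")
  }
  f <- stack$frames
  num <- f[[4]] - f[[2]]
  den <- f[[1]] - f[[3]]
  degen <- abs(num) < contrast_floor & abs(den) < contrast_floor
  n_degen <- sum(degen)
  if (n_degen > 0.5 * length(num)) {
    abort(
      sprintf(
        "Phase reconstruction failed: %d of %d pixels (%.1f%%) have no fringe contrast.",
        n_degen, length(num), 100 * n_degen / length(num)
      ),
      class = "phaseviab_reconstruction_error"
    )
  }
  dphi <- atan2(num, den)
  dphi[degen] <- 0
  if (identical(cfg$b_ratio, "identity")) {
    phi <- dphi
  } else {
    b <- cfg$b_ratio
    phi <- atan(b * sin(dphi) / (1 + b * cos(dphi)))
    phi[degen] <- 0
  }
  out <- phase_map(phi, pixel_size_um = stack$pixel_size_um,
                   wavelength_um = cfg$wavelength_um)
  attr(out, "n_degenerate") <- n_degen
  out
}

#' Downsample a phase map by block averaging
#'
#' Each `factor` x `factor` block of pixels is replaced by its mean and the
#' pixel pitch is multiplied by `factor`. Trailing rows/columns that do not
#' fill a complete block are cropped.
#'
#' @param pm A [phase_map()].
#' @param factor Positive integer downsampling factor.
#' @return A [phase_map()] with reduced dimensions.
#' @export
downsample_phase <- function(pm, factor = 2L) {
  stopifnot(inherits(pm, "phase_map"))
  if (length(factor) != 1L || factor < 1 || factor != round(factor)) {
    abort("`factor` must be a positive integer.", class = "phaseviab_arg_error")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(pm)
  p <- pm$phase
  h <- (nrow(p) %/% factor) * factor
  w <- (ncol(p) %/% factor) * factor
  p <- p[seq_len(h), seq_len(w), drop = FALSE]
  # block mean via two aggregation passes
  rows <- rowsum(p, rep(seq_len(h %/% factor), each = factor)) / factor
  cols <- t(rowsum(t(rows), rep(seq_len(w %/% factor), each = factor)) / factor)
  dimnames(cols) <- NULL
  phase_map(cols, pixel_size_um = pm$pixel_size_um * factor,
            wavelength_um = pm$wavelength_um)
}

#' Compute cellular dry mass from a phase map
#'
#' Optical phase delay is linearly related to the non-aqueous (dry) content of
#' the cell. Integrating phase over a segmented region gives the region's dry
#' mass:
#' \deqn{m = \frac{\lambda}{2\pi\,\alpha} \sum_{x \in \mathrm{mask}} \phi(x)\,
#'   \Delta^2}
#' with \eqn{\lambda} the wavelength, \eqn{\alpha} the refractive increment
#' (um^3/pg) and \eqn{\Delta} the pixel pitch (um).
#'
#' @param pm A [phase_map()].
#' @param mask Logical (or 0/1) matrix of the same dimensions selecting the
#'   region to integrate.
#' @param cfg An [optics_config()] supplying the refractive increment; the
#'   wavelength and pixel size are taken from `pm`.
#' @return Dry mass in picograms (0 for an empty mask).
#' @export
#' @examples
#' pm <- phase_map(matrix(1, 10, 10), pixel_size_um = 0.325)
#' compute_dry_mass(pm, matrix(TRUE, 10, 10))
compute_dry_mass <- function(pm, mask, cfg = optics_config()) {
  stopifnot(inherits(pm, "phase_map"))
  if (!identical(dim(mask), dim(pm$phase))) {
    abort("`mask` must have the same dimensions as the phase image.",
          class = "phaseviab_arg_error")
  }
  mask <- as.logical(mask)
  if (!any(mask)) return(0)
  (pm$wavelength_um / (2 * pi * cfg$alpha_ri_um3_per_pg)) *
    sum(pm$phase[mask]) * pm$pixel_size_um^2
}
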