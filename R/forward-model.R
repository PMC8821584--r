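#' Forward SLIM model: synthesize four phase-shifted interferograms
#'
#' Common-path two-beam interference with uniform incident intensity
#' \eqn{I_0}: at modulator shift \eqn{\theta_k \in \{0, \pi/2, \pi, 3\pi/2\}}
#' the recorded frame is
#' \deqn{I_k = I_0 \left(1 + b^2 + 2 b \cos(\phi + \theta_k)\right)}
#' where \eqn{b} is the scattered-to-incident amplitude ratio. This is the
#' exact forward counterpart of [reconstruct_phase()]: in noise-free
#' conditions the round trip is the identity (in `"identity"` b-ratio mode).
#'
#' @param pm A [phase_map()].
#' @param b_ratio Scattered-to-incident amplitude ratio (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian camera noise, as a
#'   fraction of the full-scale intensity 1. 0 disables noise.
#' @param i0 Incident intensity in normalized camera units; the default keeps
#'   all four frames within [0, 1] for 16-bit storage.
#' @return An [intensity_stack()] (negative noisy values are clipped at 0).
#' @export
forward_slim <- function(pm, b_ratio = 0.3, noise_sd = 0, i0 = 0.25) {
  stopifnot(inherits(pm, "phase_map"))
  if (!is.numeric(b_ratio) || b_ratio < 0) {
    abort("`b_ratio` must be a non-negative number.",
          class = "phaseviab_arg_error")
  }
  phi <- pm$phase
  shifts <- c(0, pi / 2, pi, 3 * pi / 2)
  frames <- lapply(shifts, function(th) {
    f <- i0 * (1 + b_ratio^2 + 2 * b_ratio * cos(phi + th))
    if (noise_sd > 0) {
      f <- f + matrix(rnorm(length(f), sd = noise_sd), nrow(f), ncol(f))
      f[f < 0] <- 0
    }
    f
  })
  intensity_stack(frames, pixel_size_um = pm$pixel_size_um)
}
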