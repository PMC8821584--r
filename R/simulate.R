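#' Configuration for the synthetic time-lapse simulator
#'
#' The simulator emulates the structure of a SLIM viability experiment:
#' adherent cells rendered as smooth elliptical nuclei (flat-top
#' super-Gaussian phase profiles) with fainter surrounding cytoplasm, imaged
#' as four phase-shifted interferograms plus two co-registered fluorescence
#' channels, with per-nucleus viability truth. Each live cell dies
#' independently with a fixed per-frame hazard; a dying cell swells to
#' `swell_factor` relative area, then shrinks to `shrink_factor` while its
#' nuclear phase density rises (condensation), over `fluor_dead_ramp_frames`
#' frames. The "dead" fluorescence channel ramps up over the same window.
#'
#' @param image_px Square image side in pixels.
#' @param n_cells Number of cells placed (non-overlapping nuclei).
#' @param frame_interval_min Minutes between frames (metadata only).
#' @param n_frames Number of timepoints.
#' @param death_hazard_per_frame Per-frame probability that a live cell dies.
#' @param swell_factor Peak relative nuclear area during death.
#' @param shrink_factor Late-dead relative nuclear area.
#' @param phase_amplitude_rad Peak nuclear phase of a live cell (radians);
#'   per-cell amplitudes vary by +/- 5%.
#' @param b_ratio Scattered-to-incident amplitude ratio of the forward
#'   interferometric model.
#' @param noise_sd Gaussian camera noise (fraction of full scale) added to
#'   interferograms and fluorescence; 0 for noise-free data.
#' @param fluor_dead_ramp_frames Frames over which death morphology and the
#'   dead-reagent signal develop; 1 makes both switch fully at the death
#'   frame.
#' @param seed Integer seed; equal configurations produce byte-identical
#'   datasets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(image_px = 256L,
                       n_cells = 12L,
                       frame_interval_min = 30,
                       n_frames = 10L,
                       death_hazard_per_frame = 0.1,
                       swell_factor = 1.3,
                       shrink_factor = 0.7,
                       phase_amplitude_rad = 1.5,
                       b_ratio = 0.3,
                       noise_sd = 0.005,
                       fluor_dead_ramp_frames = 3L,
                       seed = 1L) {
  stopifnot(
    image_px >= 32, n_cells >= 0, n_frames >= 1,
    death_hazard_per_frame >= 0, death_hazard_per_frame <= 1,
    swell_factor > 0, shrink_factor > 0, phase_amplitude_rad > 0,
    b_ratio >= 0, noise_sd >= 0, fluor_dead_ramp_frames >= 1
  )
  structure(
    list(
      image_px = as.integer(image_px), n_cells = as.integer(n_cells),
      frame_interval_min = frame_interval_min, n_frames = as.integer(n_frames),
      death_hazard_per_frame = death_hazard_per_frame,
      swell_factor = swell_factor, shrink_factor = shrink_factor,
      phase_amplitude_rad = phase_amplitude_rad, b_ratio = b_ratio,
      noise_sd = noise_sd,
      fluor_dead_ramp_frames = as.integer(fluor_dead_ramp_frames),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# fixed rendering constants (documented in the methods vignette)
.sim_const <- list(
  semi_axis_range = c(6, 9),    # nucleus semi-axes, px
  amp_jitter = 0.05,            # per-cell live amplitude spread (+/-)
  cyto_scale = 1.8,             # cytoplasm semi-axes / nucleus semi-axes
  cyto_amp_frac = 0.12,         # cytoplasm phase / nucleus amplitude
  amp_peak = 1.3,               # nuclear phase factor at peak swelling
  amp_dead = 1.2,               # nuclear phase factor late dead
  blue_level = 0.8,             # NucBlue peak intensity (full scale 1)
  i0 = 0.25,                    # incident intensity of the forward model
  camera_levels = 65535         # 16-bit quantization of stored channels
)

# morphology of a dying cell as a function of ramp progress u in [0, 1]:
# relative area (linear swell-then-shrink) and phase amplitude factor
death_area_factor <- function(u, swell, shrink) {
  ifelse(u <= 0.5, 1 + (swell - 1) * 2 * u, swell + (shrink - swell) * (2 * u - 1))
}

death_amp_factor <- function(u) {
  pk <- .sim_const$amp_peak
  dd <- .sim_const$amp_dead
  ifelse(u <= 0.5, 1 + (pk - 1) * 2 * u, pk + (dd - pk) * (2 * u - 1))
}

quantize16 <- function(x) {
  lv <- .sim_const$camera_levels
  pmin(pmax(round(x * lv) / lv, 0), 1)
}

#' Simulate a synthetic SLIM viability time-lapse experiment
#'
#' Generates, for every frame: the four-frame interferogram stack (from the
#' forward interferometric model, with camera noise and 16-bit
#' quantization), the underlying quantitative phase map, the NucBlue-like
#' and NucGreen-like fluorescence pair, the true semantic map, and
#' per-nucleus truth records (class, footprint area, analytic dry mass).
#'
#' @param cfg A [sim_config()].
#' @param opt An [optics_config()] supplying pixel size, wavelength and
#'   refractive increment for the truth dry-mass bookkeeping.
#' @return An object of class `sim_experiment`: a list with elements `cfg`,
#'   `cells` (per-cell geometry and death frame), `phases`, `stacks`,
#'   `fluors`, `truths` (per-frame lists) and `records` (tibble of
#'   per-frame per-nucleus truth).
#' @export
simulate_experiment <- function(cfg = sim_config(), opt = optics_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- .sim_const
  n <- cfg$n_cells
  sw <- sqrt(cfg$swell_factor)

  # ---- cell placement (rejection sampling, nuclei never overlap) ----------
  amax_hi <- k$semi_axis_range[2]
  margin <- ceiling(amax_hi * sw) + 3
  if (2 * margin >= cfg$image_px && n > 0) {
    abort("Image too small for the configured cell size.",
          class = "phaseviab_sim_error")
  }
  cells <- NULL
  if (n > 0) {
    rows <- cols <- aa <- bb <- th <- numeric(0)
    attempts <- 0L
    while (length(rows) < n) {
      attempts <- attempts + 1L
      if (attempts > 300L * n) {
        abort(sprintf("Could not place %d non-overlapping cells in a %d px image.",
                      n, cfg$image_px),
              class = "phaseviab_sim_error")
      }
      r <- runif(1, margin, cfg$image_px - margin)
      c <- runif(1, margin, cfg$image_px - margin)
      a <- runif(1, k$semi_axis_range[1], k$semi_axis_range[2])
      b <- runif(1, k$semi_axis_range[1], k$semi_axis_range[2])
      t <- runif(1, 0, pi)
      am <- max(a, b)
      ok <- TRUE
      for (j in seq_along(rows)) {
        amj <- max(aa[j], bb[j])
        need <- sw * (k$cyto_scale * max(am, amj) + min(am, amj)) + 4
        if ((r - rows[j])^2 + (c - cols[j])^2 < need^2) { ok <- FALSE; break }
      }
      if (ok) {
        rows <- c(rows, r); cols <- c(cols, c)
        aa <- c(aa, a); bb <- c(bb, b); th <- c(th, t)
      }
    }
    amp <- cfg$phase_amplitude_rad *
      runif(n, 1 - k$amp_jitter, 1 + k$amp_jitter)
    h <- cfg$death_hazard_per_frame
    death <- if (h == 0) rep(NA_integer_, n)
             else if (h == 1) rep(1L, n)
             else as.integer(stats::rgeom(n, h) + 1L)
    death[!is.na(death) & death > cfg$n_frames] <- NA_integer_
    cells <- tibble::tibble(
      id = seq_len(n), row = rows, col = cols, a = aa, b = bb, theta = th,
      amp = amp, death_frame = death
    )
  } else {
    cells <- tibble::tibble(
      id = integer(), row = numeric(), col = numeric(), a = numeric(),
      b = numeric(), theta = numeric(), amp = numeric(),
      death_frame = integer()
    )
  }

  # ---- per-frame rendering -------------------------------------------------
  phases <- stacks <- fluors <- truths <- vector("list", cfg$n_frames)
  recs <- list()
  mass_scale <- opt$wavelength_um / (2 * pi * opt$alpha_ri_um3_per_pg) *
    opt$pixel_size_um^2

  for (f in seq_len(cfg$n_frames)) {
    phase <- matrix(0, cfg$image_px, cfg$image_px)
    blue <- matrix(0, cfg$image_px, cfg$image_px)
    green <- matrix(0, cfg$image_px, cfg$image_px)
    truth <- matrix(2L, cfg$image_px, cfg$image_px)
    frame_rows <- list()
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      dead <- !is.na(cl$death_frame) && f >= cl$death_frame
      u <- if (dead) min((f - cl$death_frame + 1) / cfg$fluor_dead_ramp_frames, 1) else 0
      s <- sqrt(death_area_factor(u, cfg$swell_factor, cfg$shrink_factor))
      m <- death_amp_factor(u)
      if (!dead) { s <- 1; m <- 1 }
      a_s <- cl$a * s; b_s <- cl$b * s
      a_c <- k$cyto_scale * a_s; b_c <- k$cyto_scale * b_s
      ext <- ceiling(max(a_c, b_c)) + 3L
      r0 <- max(1L, floor(cl$row) - ext); r1 <- min(cfg$image_px, ceiling(cl$row) + ext)
      c0 <- max(1L, floor(cl$col) - ext); c1 <- min(cfg$image_px, ceiling(cl$col) + ext)
      rr <- r0:r1; cc <- c0:c1
      dy <- outer(rr - cl$row, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cl$col)
      xr <- dx * cos(cl$theta) + dy * sin(cl$theta)
      yr <- -dx * sin(cl$theta) + dy * cos(cl$theta)
      rho2_n <- (xr / a_s)^2 + (yr / b_s)^2
      rho2_c <- (xr / a_c)^2 + (yr / b_c)^2
      prof_n <- exp(-rho2_n^2)
      prof_c <- exp(-rho2_c^2)
      amp_n <- cl$amp * m
      amp_c <- k$cyto_amp_frac * cl$amp
      phase[rr, cc] <- phase[rr, cc] + amp_n * prof_n + amp_c * prof_c
      blue[rr, cc] <- blue[rr, cc] + k$blue_level * prof_n
      green[rr, cc] <- green[rr, cc] + u * k$blue_level * prof_n
      foot <- rho2_n <= 1
      sub <- truth[rr, cc]
      sub[foot] <- if (dead) 1L else 0L
      truth[rr, cc] <- sub
      # truth dry mass: this cell's own rendered phase summed over its
      # footprint (the rendered object's mass by definition; independent of
      # neighbouring cytoplasm tails)
      own_phase <- amp_n * prof_n + amp_c * prof_c
      frame_rows[[i]] <- tibble::tibble(
        frame = f, id = cl$id, class = if (dead) "dead" else "live",
        centroid_row = cl$row, centroid_col = cl$col,
        area_px = sum(foot), mass_pg = mass_scale * sum(own_phase[foot]),
        ramp = u
      )
    }
    pm <- phase_map(phase, pixel_size_um = opt$pixel_size_um,
                    wavelength_um = opt$wavelength_um)
    st <- forward_slim(pm, b_ratio = cfg$b_ratio, noise_sd = cfg$noise_sd,
                       i0 = k$i0)
    st$frames <- lapply(st$frames, quantize16)
    if (cfg$noise_sd > 0) {
      blue <- blue + matrix(rnorm(length(blue), sd = cfg$noise_sd),
                            nrow(blue), ncol(blue))
      green <- green + matrix(rnorm(length(green), sd = cfg$noise_sd),
                              nrow(green), ncol(green))
      blue[blue < 0] <- 0
      green[green < 0] <- 0
    }
    blue <- quantize16(blue)
    green <- quantize16(green)
    phases[[f]] <- pm
    stacks[[f]] <- st
    fluors[[f]] <- fluor_pair(blue, green)
    truths[[f]] <- semantic_map(truth)
    recs[[f]] <- dplyr::bind_rows(frame_rows)
  }
  structure(
    list(cfg = cfg, optics = opt, cells = cells, phases = phases,
         stacks = stacks, fluors = fluors, truths = truths,
         records = dplyr::bind_rows(recs)),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "<sim_experiment> %d frames of %d px, %d cells (%d die), seed %d\n",
    x$cfg$n_frames, x$cfg$image_px, nrow(x$cells),
    sum(!is.na(x$cells$death_frame)), x$cfg$seed
  ))
  invisible(x)
}

#' Collect simulated experiments into a training frame table
#'
#' Flattens one or more simulated experiments into the tidy frame table
#' consumed by [train_segmenter()]: one row per frame with the phase image
#' and the true semantic map, each experiment forming one sequence.
#'
#' @param experiments A `sim_experiment` or list of them.
#' @param use_reconstruction If `TRUE`, images are phase maps reconstructed
#'   from the simulated interferograms via [reconstruct_phase()] (the
#'   realistic pipeline); if `FALSE`, the noise-free ground-truth phase is
#'   used directly.
#' @param cfg Optics configuration for the reconstruction.
#' @return A tibble with columns `sequence_id`, `frame`, `image`, `labels`.
#' @export
sim_frames <- function(experiments, use_reconstruction = TRUE,
                       cfg = optics_config()) {
  if (inherits(experiments, "sim_experiment")) experiments <- list(experiments)
  rows <- purrr::imap(experiments, function(ex, nm) {
    sid <- if (is.character(nm) && nzchar(nm)) nm else paste0("seq", nm)
    tibble::tibble(
      sequence_id = sid,
      frame = seq_len(ex$cfg$n_frames),
      image = lapply(seq_len(ex$cfg$n_frames), function(f) {
        if (use_reconstruction) {
          reconstruct_phase(ex$stacks[[f]], cfg)$phase
        } else {
          ex$phases[[f]]$phase
        }
      }),
      labels = ex$truths
    )
  })
  dplyr::bind_rows(rows)
}
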