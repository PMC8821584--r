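#' Link nuclei across time-lapse frames
#'
#' Deterministic greedy nearest-neighbour linker for slow-moving adherent
#' cells: for each pair of consecutive frames, candidate object pairs are
#' sorted by ascending centroid distance and matched one-to-one, discarding
#' pairs further apart than `max_disp_px`. Unmatched objects start new
#' tracks, and tracks shorter than `min_len` frames are dropped. A cell that
#' transitions live to dead keeps its identity; its class is recorded per
#' timepoint.
#'
#' @param frames List of [semantic_map()]s, one per timepoint, co-registered.
#' @param max_disp_px Maximum frame-to-frame centroid displacement.
#' @param min_len Minimum track length in frames.
#' @param min_area_px Minimum object area passed to [extract_objects()].
#' @return A tibble with columns `track_id`, `frame`, `nucleus_id`,
#'   `centroid_row`, `centroid_col`, `area_px`, `class`, ordered by track
#'   and frame.
#' @export
link_tracks <- function(frames, max_disp_px = 30, min_len = 5,
                        min_area_px = 50) {
  if (!is.list(frames) || length(frames) < 2) {
    abort("`frames` must be a list of at least 2 semantic maps.",
          class = "phaseviab_arg_error")
  }
  objs <- lapply(seq_along(frames), function(f) {
    o <- extract_objects(frames[[f]], min_area_px = min_area_px)
    o$frame <- f
    o
  })
  # active track bookkeeping: per object of the previous frame, its track id
  next_track <- 1L
  rows <- list()
  prev <- NULL
  for (f in seq_along(objs)) {
    cur <- objs[[f]]
    cur$track_id <- NA_integer_
    if (!is.null(prev) && nrow(prev) > 0 && nrow(cur) > 0) {
      d <- outer(prev$centroid_row, cur$centroid_row, "-")^2 +
        outer(prev$centroid_col, cur$centroid_col, "-")^2
      cand <- which(d <= max_disp_px^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand])
        used_prev <- logical(nrow(prev))
        used_cur <- logical(nrow(cur))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_prev[i] || used_cur[j]) next
          used_prev[i] <- TRUE
          used_cur[j] <- TRUE
          cur$track_id[j] <- prev$track_id[i]
        }
      }
    }
    new_idx <- which(is.na(cur$track_id))
    if (length(new_idx) > 0) {
      cur$track_id[new_idx] <- next_track + seq_along(new_idx) - 1L
      next_track <- next_track + length(new_idx)
    }
    rows[[f]] <- cur
    prev <- cur
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "track_id", "frame", nucleus_id = "id",
                       "centroid_row", "centroid_col", "area_px", "class",
                       "pixels")
  keep <- dplyr::count(out, .data$track_id)
  keep <- keep$track_id[keep$n >= min_len]
  out <- out[out$track_id %in% keep, ]
  # renumber tracks consecutively in order of first appearance
  out$track_id <- match(out$track_id, unique(out$track_id))
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Fill per-timepoint area and dry mass into tracks
#'
#' For each tracked nucleus at each timepoint, the physical area is the
#' object pixel count times the squared pixel pitch and the dry mass is the
#' phase integral over the object mask via [compute_dry_mass()].
#'
#' @param tracks Tibble from [link_tracks()] (must retain the `pixels`
#'   list-column).
#' @param phases List of [phase_map()]s aligned with the frames the tracks
#'   were linked on.
#' @param cfg An [optics_config()].
#' @return The tracks tibble with added columns `area_um2` and
#'   `dry_mass_pg`, without the pixel sets.
#' @export
measure_track <- function(tracks, phases, cfg = optics_config()) {
  stopifnot(is.data.frame(tracks), "pixels" %in% names(tracks))
  if (max(tracks$frame) > length(phases)) {
    abort("Track frame index exceeds the number of phase maps.",
          class = "phaseviab_arg_error")
  }
  n <- nrow(tracks)
  area <- numeric(n)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    pm <- phases[[tracks$frame[i]]]
    px <- tracks$pixels[[i]]
    area[i] <- length(px) * pm$pixel_size_um^2
    mask <- matrix(FALSE, nrow(pm$phase), ncol(pm$phase))
    mask[px] <- TRUE
    mass[i] <- compute_dry_mass(pm, mask, cfg)
  }
  tracks$area_um2 <- area
  tracks$dry_mass_pg <- mass
  dplyr::select(tracks, -"pixels")
}

#' Normalize a per-timepoint series to its first value
#'
#' @param values Numeric vector ordered by time; `values[1]` must be
#'   non-zero.
#' @return `values / values[1]` (so the series starts at exactly 1).
#' @export
normalize_series <- function(values) {
  if (length(values) == 0) return(values)
  if (values[1] == 0) {
    abort("Cannot normalize: value at the first timepoint is zero.",
          class = "phaseviab_arg_error")
  }
  values / values[1]
}

#' Per-timepoint group statistics with Welch t-tests
#'
#' Normalizes the chosen quantity of every track to its value at the track's
#' first timepoint, then compares the two groups at every common timepoint:
#' group means, standard errors, and the two-sided Welch (unequal variances)
#' t-test p-value.
#'
#' @param tracks_a,tracks_b Measured track tibbles (from [measure_track()]),
#'   one per group.
#' @param quantity Column to analyze, e.g. `"area_um2"` or `"dry_mass_pg"`.
#' @param min_n Minimum tracks per group required at a timepoint.
#' @return A tibble with columns `frame`, `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `t`, `p`.
#' @export
group_stats <- function(tracks_a, tracks_b, quantity = "area_um2",
                        min_n = 2L) {
  norm_group <- function(tr) {
    stopifnot(quantity %in% names(tr))
    tr <- dplyr::arrange(tr, .data$track_id, .data$frame)
    dplyr::mutate(dplyr::group_by(tr, .data$track_id),
                  rel = normalize_series(.data[[quantity]])) |>
      dplyr::ungroup()
  }
  a <- norm_group(tracks_a)
  b <- norm_group(tracks_b)
  common <- intersect(unique(a$frame), unique(b$frame))
  rows <- lapply(sort(common), function(f) {
    va <- a$rel[a$frame == f]
    vb <- b$rel[b$frame == f]
    if (length(va) < min_n || length(vb) < min_n) {
      abort(sprintf("Fewer than %d tracks in a group at frame %d.", min_n, f),
            class = "phaseviab_arg_error")
    }
    if (sd(va) == 0 && sd(vb) == 0) {
      tt <- list(statistic = c(t = if (mean(va) == mean(vb)) 0 else Inf),
                 p.value = if (mean(va) == mean(vb)) 1 else 0)
    } else {
      tt <- t.test(va, vb, var.equal = FALSE)
    }
    tibble::tibble(
      frame = f,
      mean_a = mean(va), sem_a = sd(va) / sqrt(length(va)), n_a = length(va),
      mean_b = mean(vb), sem_b = sd(vb) / sqrt(length(vb)), n_b = length(vb),
      t = unname(tt$statistic), p = tt$p.value
    )
  })
  dplyr::bind_rows(rows)
}
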