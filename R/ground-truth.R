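#' Ground-truth generation settings
#'
#' Parameters for converting paired viability-stain fluorescence channels
#' into three-class semantic maps.
#'
#' @param smoothing_sigma_px Gaussian pre-smoothing applied to the all-nuclei
#'   (blue) channel before thresholding, in pixels.
#' @param min_area_px Connected components smaller than this are discarded.
#' @param ratio_threshold Per-nucleus dead call: a nucleus with
#'   mean(green)/mean(blue) strictly above, or exactly equal to, this value is
#'   labeled dead.
#' @param edge_policy `"keep"` (default) or `"drop"` nuclei touching the
#'   image border.
#' @return An object of class `gt_config`.
#' @export
gt_config <- function(smoothing_sigma_px = 2,
                      min_area_px = 50,
                      ratio_threshold = 0.5,
                      edge_policy = c("keep", "drop")) {
  stopifnot(smoothing_sigma_px >= 0, min_area_px >= 1, ratio_threshold > 0)
  edge_policy <- match.arg(edge_policy)
  structure(
    list(
      smoothing_sigma_px = smoothing_sigma_px,
      min_area_px = min_area_px,
      ratio_threshold = ratio_threshold,
      edge_policy = edge_policy
    ),
    class = "gt_config"
  )
}

#' Paired live/dead fluorescence channels
#'
#' @param blue 2-D non-negative image of the all-nuclei ("live") reagent.
#' @param green 2-D non-negative image of the compromised-membrane ("dead")
#'   reagent, co-registered with `blue`.
#' @return An object of class `fluor_pair`.
#' @export
fluor_pair <- function(blue, green) {
  if (!is.matrix(blue) || !is.matrix(green) ||
      !identical(dim(blue), dim(green))) {
    abort("`blue` and `green` must be matrices of identical dimensions.",
          class = "phaseviab_arg_error")
  }
  if (any(blue < 0) || any(green < 0)) {
    abort("Fluorescence intensities must be non-negative.",
          class = "phaseviab_arg_error")
  }
  structure(list(blue = blue, green = green), class = "fluor_pair")
}

#' Validate a three-class semantic map
#'
#' Semantic maps are integer matrices with 0 = live, 1 = dead,
#' 2 = background.
#'
#' @param labels Matrix with values in \{0, 1, 2\}.
#' @return The validated integer matrix, classed `semantic_map`.
#' @export
semantic_map <- function(labels) {
  if (!is.matrix(labels)) {
    abort("`labels` must be a matrix.", class = "phaseviab_arg_error")
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) {
    abort("Semantic maps may only contain values 0 (live), 1 (dead), 2 (background).",
          class = "phaseviab_format_error")
  }
  structure(labels, class = c("semantic_map", "matrix", "array"))
}

as_label_matrix <- function(x) {
  if (inherits(x, "semantic_map")) {
    return(unclass(x))
  }
  unclass(semantic_map(x))
}

#' Segment nuclei from the all-nuclei fluorescence channel
#'
#' Gaussian smooth, global Otsu threshold, 8-connected components, minimum
#' area filter, optional border-object removal.
#'
#' @param blue 2-D non-negative image (the "live" reagent channel, which
#'   stains all nuclei).
#' @param cfg A [gt_config()].
#' @return Integer matrix of nucleus ids (0 = background).
#' @export
segment_nuclei <- function(blue, cfg = gt_config()) {
  stopifnot(is.matrix(blue))
  if (any(blue < 0)) {
    abort("`blue` must be non-negative.", class = "phaseviab_arg_error")
  }
  if (diff(range(blue)) == 0) {
    abort("Nucleus segmentation found no foreground: constant image.",
          class = "phaseviab_segmentation_error")
  }
  sm <- blue
  if (cfg$smoothing_sigma_px > 0) {
    sm <- EBImage::gblur(blue, sigma = cfg$smoothing_sigma_px)
  }
  rng <- range(sm)
  thr <- EBImage::otsu(sm, range = rng)
  mask <- sm > thr
  if (!any(mask)) {
    abort("Nucleus segmentation found no foreground after thresholding.",
          class = "phaseviab_segmentation_error")
  }
  lab <- label_components_cpp(mask)
  lab <- filter_components(lab, cfg$min_area_px, cfg$edge_policy)
  lab
}

# Drop small components and (optionally) border-touching ones; relabel
# compactly in scan order.
filter_components <- function(lab, min_area_px, edge_policy = "keep") {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab, nbins = max(lab))
  keep <- areas >= min_area_px
  if (edge_policy == "drop") {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_ids <- border_ids[border_ids > 0L]
    keep[border_ids] <- FALSE
  }
  remap <- integer(length(areas))
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Classify segmented nuclei as live or dead from relative stain intensity
#'
#' For each nucleus n the relative intensity
#' \eqn{r(n) = \mathrm{mean}(\mathrm{green}) / (\mathrm{mean}(\mathrm{blue}) +
#' \epsilon)} is computed over the nucleus pixels. Nuclei with
#' \eqn{r \ge} `cfg$ratio_threshold` are labeled dead (ties go to dead), the
#' rest live; non-nucleus pixels become background.
#'
#' @param nuclei Integer nucleus-id matrix from [segment_nuclei()].
#' @param pair A [fluor_pair()] with the same dimensions.
#' @param cfg A [gt_config()].
#' @return A [semantic_map()]. Attribute `nuclei` carries a tibble with one
#'   row per nucleus: id, centroid, area, intensity ratio and class.
#' @export
classify_nuclei <- function(nuclei, pair, cfg = gt_config()) {
  stopifnot(inherits(pair, "fluor_pair"))
  if (!identical(dim(nuclei), dim(pair$blue))) {
    abort("`nuclei` must match the fluorescence image dimensions.",
          class = "phaseviab_arg_error")
  }
  eps <- 1e-9
  out <- matrix(2L, nrow(nuclei), ncol(nuclei))
  n <- max(nuclei)
  ids <- seq_len(n)
  if (n > 0L && any(tabulate(nuclei, nbins = n) == 0L)) {
    abort("Nucleus id present without pixels: inconsistent label map.",
          class = "phaseviab_internal_error")
  }
  rows <- lapply(ids, function(id) {
    px <- which(nuclei == id)
    r <- mean(pair$green[px]) / (mean(pair$blue[px]) + eps)
    dead <- r >= cfg$ratio_threshold
    out[px] <<- if (dead) 1L else 0L
    ij <- arrayInd(px, dim(nuclei))
    tibble::tibble(
      id = id,
      centroid_row = mean(ij[, 1]),
      centroid_col = mean(ij[, 2]),
      area_px = length(px),
      ratio = r,
      class = if (dead) "dead" else "live"
    )
  })
  res <- semantic_map(out)
  attr(res, "nuclei") <- dplyr::bind_rows(rows)
  res
}

#' Generate a three-class semantic ground-truth map from fluorescence
#'
#' Composition of [segment_nuclei()] (on the blue channel) and
#' [classify_nuclei()] (on the green/blue intensity ratio). This is the
#' training-target generator of the assay: nuclei wholly labeled live (0) or
#' dead (1), everything else background (2).
#'
#' @inheritParams classify_nuclei
#' @param pair A [fluor_pair()].
#' @return A [semantic_map()] with a per-nucleus tibble in attribute
#'   `nuclei`.
#' @export
make_semantic_map <- function(pair, cfg = gt_config()) {
  stopifnot(inherits(pair, "fluor_pair"))
  nuclei <- tryCatch(
    segment_nuclei(pair$blue, cfg),
    phaseviab_segmentation_error = function(e) NULL
  )
  if (is.null(nuclei)) {
    # an empty field of view is a valid (all-background) target
    res <- semantic_map(matrix(2L, nrow(pair$blue), ncol(pair$blue)))
    attr(res, "nuclei") <- tibble::tibble(
      id = integer(), centroid_row = numeric(), centroid_col = numeric(),
      area_px = integer(), ratio = numeric(), class = character()
    )
    return(res)
  }
  classify_nuclei(nuclei, pair, cfg)
}
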