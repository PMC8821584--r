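#' Extract nucleus objects from a semantic map
#'
#' Objects are 8-connected components of the non-background mask. Each
#' object's viability class is the majority of its own pixel labels (a
#' live/dead tie is called dead, the conservative choice for viability).
#' Components smaller than `min_area_px` are discarded.
#'
#' @param map A [semantic_map()] (or \{0,1,2\} matrix).
#' @param min_area_px Minimum object area in pixels; shares its default with
#'   [gt_config()].
#' @return A tibble with one row per object: `id`, `centroid_row`,
#'   `centroid_col`, `area_px`, `class` ("live"/"dead"), and `pixels` (a
#'   list-column of linear pixel indices).
#' @export
extract_objects <- function(map, min_area_px = 50) {
  lab <- as_label_matrix(map)
  mask <- lab != 2L
  if (!any(mask)) {
    return(tibble::tibble(
      id = integer(), centroid_row = numeric(), centroid_col = numeric(),
      area_px = integer(), class = character(), pixels = list()
    ))
  }
  comp <- label_components_cpp(mask)
  comp <- filter_components(comp, min_area_px, "keep")
  n <- max(comp)
  rows <- lapply(seq_len(n), function(id) {
    px <- which(comp == id)
    ij <- arrayInd(px, dim(lab))
    n_dead <- sum(lab[px] == 1L)
    tibble::tibble(
      id = id,
      centroid_row = mean(ij[, 1]),
      centroid_col = mean(ij[, 2]),
      area_px = length(px),
      class = if (n_dead >= length(px) - n_dead) "dead" else "live",
      pixels = list(px)
    )
  })
  dplyr::bind_rows(rows)
}

#' Dominant predicted label inside a ground-truth object
#'
#' Looks at the prediction's pixels inside the ground-truth object's pixel
#' set. If background dominates (strictly more than half of the object's
#' pixels) the object is `"missed"`; otherwise the majority non-background
#' class wins, with a live/dead tie going to dead.
#'
#' @param pixels Integer vector of linear pixel indices of the ground-truth
#'   object (e.g. from [extract_objects()]'s `pixels` column).
#' @param pred A [semantic_map()] prediction of the same image.
#' @return One of `"live"`, `"dead"`, `"missed"`.
#' @export
dominant_label <- function(pixels, pred) {
  if (length(pixels) == 0) {
    abort("Empty object.", class = "phaseviab_arg_error")
  }
  p <- as_label_matrix(pred)[pixels]
  n_bg <- sum(p == 2L)
  if (n_bg > length(p) / 2) return("missed")
  n_dead <- sum(p == 1L)
  n_live <- sum(p == 0L)
  if (n_dead >= n_live) "dead" else "live"
}

#' Object-based live/dead confusion matrix
#'
#' For every ground-truth nucleus the dominant predicted label inside its
#' pixel set is tallied into a 2 x 2 confusion matrix (rows = prediction,
#' columns = ground truth). Objects whose prediction is dominated by
#' background are reported separately as `missed` and excluded from the
#' 2 x 2 counts.
#'
#' @param gt Ground-truth [semantic_map()].
#' @param pred Predicted [semantic_map()] of the same dimensions.
#' @param min_area_px Minimum ground-truth object area.
#' @return An object of class `viab_confusion`: a list with `counts` (2 x 2
#'   integer matrix), `n_live`, `n_dead` (ground-truth totals entering the
#'   matrix), and `missed` (named vector of background-dominated objects per
#'   ground-truth class).
#' @export
object_confusion <- function(gt, pred, min_area_px = 50) {
  gt_m <- as_label_matrix(gt)
  pred_m <- as_label_matrix(pred)
  if (!identical(dim(gt_m), dim(pred_m))) {
    abort("Ground truth and prediction dimensions differ.",
          class = "phaseviab_arg_error")
  }
  objs <- extract_objects(gt_m, min_area_px = min_area_px)
  counts <- matrix(0L, 2, 2,
                   dimnames = list(pred = c("live", "dead"),
                                   gt = c("live", "dead")))
  missed <- c(live = 0L, dead = 0L)
  for (i in seq_len(nrow(objs))) {
    vote <- dominant_label(objs$pixels[[i]], pred_m)
    gt_cls <- objs$class[i]
    if (vote == "missed") {
      missed[gt_cls] <- missed[gt_cls] + 1L
    } else {
      counts[vote, gt_cls] <- counts[vote, gt_cls] + 1L
    }
  }
  structure(
    list(
      counts = counts,
      n_live = sum(counts[, "live"]),
      n_dead = sum(counts[, "dead"]),
      missed = missed
    ),
    class = "viab_confusion"
  )
}

#' @export
print.viab_confusion <- function(x, ...) {
  cat(sprintf("<viab_confusion> n_live = %d, n_dead = %d, missed = %d\n",
              x$n_live, x$n_dead, sum(x$missed)))
  print(x$counts)
  invisible(x)
}

#' Column-normalize an object confusion matrix to percentages
#'
#' Each column (ground-truth class) is divided by its class total and
#' expressed in percent, so columns sum to 100.
#'
#' @param cm A `viab_confusion` from [object_confusion()], or a plain 2 x 2
#'   count matrix (prediction rows, ground-truth columns).
#' @return 2 x 2 numeric matrix of percentages; columns with a zero
#'   ground-truth total are `NaN` and flagged with a warning.
#' @export
normalize_confusion <- function(cm) {
  counts <- if (inherits(cm, "viab_confusion")) cm$counts else as.matrix(cm)
  stopifnot(identical(dim(counts), c(2L, 2L)) || identical(dim(counts), c(2, 2)))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("Ground-truth class with zero objects: normalized column undefined.")
  }
  sweep(counts, 2, totals, "/") * 100
}

#' F1 score from precision and recall percentages
#'
#' @param precision_pct,recall_pct Values in `[0, 100]`, not both 0.
#' @return `2 P R / (P + R)`, in percent (full precision; round for
#'   table-style reporting).
#' @export
#' @examples
#' f1_from_pr(91.2, 97.6)
f1_from_pr <- function(precision_pct, recall_pct) {
  stopifnot(all(precision_pct >= 0 & precision_pct <= 100),
            all(recall_pct >= 0 & recall_pct <= 100))
  if (any(precision_pct + recall_pct == 0)) {
    abort("Precision and recall may not both be zero.",
          class = "phaseviab_arg_error")
  }
  2 * precision_pct * recall_pct / (precision_pct + recall_pct)
}

#' Precision / recall / F1 report from an object confusion matrix
#'
#' Per-class precision (`TP / (TP + FP)`), recall (`TP / (TP + FN)`) and F1
#' over the 2 x 2 live/dead matrix, plus the macro (unweighted mean) F1 as
#' the overall performance indicator. By construction each class's recall
#' equals the corresponding diagonal entry of [normalize_confusion()].
#'
#' @param cm A `viab_confusion` or 2 x 2 count matrix.
#' @return A tibble with rows `live`, `dead`, `macro` and columns
#'   `precision_pct`, `recall_pct`, `f1_pct` (precision/recall are `NA` for
#'   the macro row). Zero-denominator metrics are reported as 0 with a
#'   warning.
#' @export
prf1 <- function(cm) {
  counts <- if (inherits(cm, "viab_confusion")) cm$counts else as.matrix(cm)
  cls <- c("live", "dead")
  rows <- lapply(cls, function(k) {
    tp <- counts[k, k]
    fp <- sum(counts[k, ]) - tp
    fn <- sum(counts[, k]) - tp
    prec <- if (tp + fp == 0) {
      warning(sprintf("No predictions of class %s: precision set to 0.", k)); 0
    } else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0) {
      warning(sprintf("No ground-truth objects of class %s: recall set to 0.", k)); 0
    } else 100 * tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else f1_from_pr(prec, rec)
    tibble::tibble(class = k, precision_pct = prec, recall_pct = rec,
                   f1_pct = f1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(
    out,
    tibble::tibble(class = "macro", precision_pct = NA_real_,
                   recall_pct = NA_real_, f1_pct = mean(out$f1_pct))
  )
}

#' Pixel-wise segmentation metrics
#'
#' Standard per-class pixel-count precision, recall, F1 and IoU over the
#' three classes live (0), dead (1) and background (2).
#'
#' @param gt,pred [semantic_map()]s of identical dimensions.
#' @return A tibble with one row per class (plus a macro row for F1), values
#'   in percent.
#' @export
pixel_metrics <- function(gt, pred) {
  g <- as_label_matrix(gt)
  p <- as_label_matrix(pred)
  if (!identical(dim(g), dim(p))) {
    abort("Ground truth and prediction dimensions differ.",
          class = "phaseviab_arg_error")
  }
  cls <- c(live = 0L, dead = 1L, background = 2L)
  rows <- lapply(names(cls), function(k) {
    c0 <- cls[[k]]
    tp <- sum(g == c0 & p == c0)
    fp <- sum(g != c0 & p == c0)
    fn <- sum(g == c0 & p != c0)
    prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else f1_from_pr(prec, rec)
    iou <- if (tp + fp + fn == 0) 0 else 100 * tp / (tp + fp + fn)
    tibble::tibble(class = k, precision_pct = prec, recall_pct = rec,
                   f1_pct = f1, iou_pct = iou)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(
    out,
    tibble::tibble(class = "macro", precision_pct = NA_real_,
                   recall_pct = NA_real_, f1_pct = mean(out$f1_pct),
                   iou_pct = mean(out$iou_pct))
  )
}

#' Round percentages the way assay tables are formatted
#'
#' Round-half-up to one decimal (so 94.25 becomes 94.3, unlike banker's
#' rounding).
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
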