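#' Losses for three-class viability segmentation
#'
#' The segmenter is trained with a compound of a focal loss and a dice loss
#' over the classes live (0), dead (1) and background (2).
#'
#' The focal loss over a batch of B images of M x N pixels is
#' \deqn{L_{focal} = -\frac{1}{B}\sum_{i=1}^{B}\frac{1}{MN}\sum_{x\in\Omega}
#'   [1 - y_i(x)^T p_i(x)]^{\gamma}\; y_i(x)^T \log_2 p_i(x)}
#' with one-hot targets \eqn{y}, predicted class probabilities \eqn{p} and
#' focusing exponent \eqn{\gamma}. Note the base-2 logarithm: values differ
#' from natural-log focal losses by a factor 1/ln 2. At \eqn{\gamma = 0} the
#' focal loss reduces to the mean base-2 cross-entropy.
#'
#' The dice loss is
#' \deqn{L_{dice} = 1 - \frac{1}{3}\sum_{c=0}^{2}
#'   \frac{2\,TP_c + \epsilon}{2\,TP_c + FP_c + FN_c + \epsilon}}
#' where TP/FP/FN are accumulated over all pixels of all images in the batch
#' (micro-averaged). In `hard` mode they are counts of argmax labels; in soft
#' mode they are probability masses, which makes the loss differentiable.
#' A class with no ground-truth pixels in the batch scores 1 (it cannot be
#' missed), so a perfect prediction always has dice loss 0.
#'
#' @param probs Predicted probabilities: an H x W x 3 array, or a list of
#'   such arrays for a batch.
#' @param truth Ground truth: an integer label matrix with values in
#'   \{0, 1, 2\}, an H x W x 3 one-hot array, or a list of either (one per
#'   batch element).
#' @param gamma Focusing exponent (>= 0).
#' @param clip Probabilities are clipped to `[clip, 1]` before the logarithm.
#' @return A non-negative scalar.
#' @name losses
NULL

#' @rdname losses
#' @export
focal_loss <- function(probs, truth, gamma = 2, clip = 1e-7) {
  stopifnot(gamma >= 0)
  b <- canonical_batch(probs, truth)
  vals <- purrr::map2_dbl(b$probs, b$onehot, function(p, y) {
    pt <- apply_onehot(p, y)       # true-class probability per pixel
    pt_clipped <- pmax(pt, clip)
    mean((1 - pt)^gamma * (-log2(pt_clipped)))
  })
  mean(vals)
}

#' @rdname losses
#' @param hard If `TRUE`, TP/FP/FN count argmax labels; if `FALSE`, they are
#'   soft probability masses.
#' @param epsilon Smoothing constant in the per-class dice score.
#' @export
dice_loss <- function(probs, truth, hard = TRUE, epsilon = 1e-6) {
  b <- canonical_batch(probs, truth)
  stats <- dice_stats(b$probs, b$onehot, hard = hard)
  score <- ifelse(
    stats$tp + stats$fn == 0,
    1,
    (2 * stats$tp + epsilon) / (2 * stats$tp + stats$fp + stats$fn + epsilon)
  )
  1 - mean(score)
}

#' @rdname losses
#' @param alpha,beta Indicator weights in \{0, 1\} for the focal and dice
#'   terms; not both may be 0.
#' @export
combined_loss <- function(probs, truth, alpha = 1, beta = 0, gamma = 2,
                          hard = TRUE, clip = 1e-7, epsilon = 1e-6) {
  if (!alpha %in% c(0, 1) || !beta %in% c(0, 1)) {
    abort("`alpha` and `beta` must each be 0 or 1.",
          class = "phaseviab_config_error")
  }
  if (alpha == 0 && beta == 0) {
    abort("At least one of the focal and dice indicators must be 1.",
          class = "phaseviab_config_error")
  }
  out <- 0
  if (alpha == 1) out <- out + focal_loss(probs, truth, gamma = gamma, clip = clip)
  if (beta == 1) out <- out + dice_loss(probs, truth, hard = hard, epsilon = epsilon)
  out
}

# ---- internal helpers -------------------------------------------------------

# Normalize (probs, truth) to parallel lists of H x W x 3 arrays.
canonical_batch <- function(probs, truth) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truth)) truth <- list(truth)
  if (length(probs) != length(truth)) {
    abort("Batch sizes of predictions and targets differ.",
          class = "phaseviab_arg_error")
  }
  onehot <- purrr::map2(probs, truth, function(p, y) {
    if (length(dim(p)) != 3L || dim(p)[3] != 3L) {
      abort("Predictions must be H x W x 3 probability arrays.",
            class = "phaseviab_arg_error")
    }
    y <- as_onehot(y)
    if (!identical(dim(y), dim(p))) {
      abort("Prediction and target dimensions differ.",
            class = "phaseviab_arg_error")
    }
    y
  })
  list(probs = probs, onehot = onehot)
}

as_onehot <- function(y) {
  if (length(dim(y)) == 3L) {
    if (!all(y %in% c(0, 1)) || !all(abs(apply_sum3(y) - 1) < 1e-12)) {
      abort("Targets given as arrays must be one-hot over the class axis.",
            class = "phaseviab_arg_error")
    }
    return(y)
  }
  lab <- as_label_matrix(y)
  oh <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  for (c in 0:2) oh[, , c + 1][lab == c] <- 1
  oh
}

apply_sum3 <- function(a) a[, , 1] + a[, , 2] + a[, , 3]

# per-pixel true-class probability  y(x)^T p(x)
apply_onehot <- function(p, y) {
  p[, , 1] * y[, , 1] + p[, , 2] * y[, , 2] + p[, , 3] * y[, , 3]
}

argmax3 <- function(p) {
  # ties broken toward the lower class index, matching max.col("first")
  hw <- dim(p)[1:2]
  m <- matrix(p, prod(hw), 3L)
  matrix(max.col(m, ties.method = "first") - 1L, hw[1], hw[2])
}

# Batch TP/FP/FN per class (vectors of length 3).
dice_stats <- function(probs, onehot, hard = TRUE) {
  tp <- fp <- fn <- numeric(3)
  for (i in seq_along(probs)) {
    p <- probs[[i]]
    y <- onehot[[i]]
    if (hard) {
      lab <- argmax3(p)
      p <- as_onehot(lab)
    }
    for (c in 1:3) {
      tp[c] <- tp[c] + sum(y[, , c] * p[, , c])
      fp[c] <- fp[c] + sum((1 - y[, , c]) * p[, , c])
      fn[c] <- fn[c] + sum(y[, , c] * (1 - p[, , c]))
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Gradient of the (base-2) focal loss w.r.t. the softmax logits for one
# sample, already including the 1/(MN) factor but not the 1/B factor.
focal_grad_logits <- function(p, y, gamma = 2, clip = 1e-7) {
  ln2 <- log(2)
  pt <- apply_onehot(p, y)
  ptc <- pmax(pt, clip)
  # dL/dp_t for each pixel (only the true-class component is nonzero)
  gpt <- (gamma * (1 - pt)^(max(gamma - 1, 0)) * log(ptc) -
            (1 - pt)^gamma / ptc) / ln2
  if (gamma == 0) gpt <- -1 / (ptc * ln2)
  mn <- prod(dim(p)[1:2])
  gpt <- gpt / mn
  # chain through softmax: dL/dz_k = p_k (g_k - sum_i g_i p_i); g_i = gpt*y_i
  dot <- gpt * pt    # sum_i g_i p_i  since g is supported on the true class
  gz <- p * (y * array(gpt, dim(p)) - array(dot, dim(p)))
  gz
}

# Gradient of the soft dice loss w.r.t. logits for one sample, given
# batch-level TP/FP/FN statistics (soft mode).
soft_dice_grad_logits <- function(p, y, stats, epsilon = 1e-6) {
  gp <- array(0, dim(p))
  for (c in 1:3) {
    if (stats$tp[c] + stats$fn[c] == 0) next  # score pinned at 1
    s <- 2 * stats$tp[c] + stats$fp[c] + stats$fn[c] + epsilon
    num <- 2 * stats$tp[c] + epsilon
    # dD_c/dp_c(x) = (2 y s - num) / s^2 ; L = 1 - mean_c D_c
    gp[, , c] <- -(2 * y[, , c] * s - num) / (3 * s^2)
  }
  dot <- p[, , 1] * gp[, , 1] + p[, , 2] * gp[, , 2] + p[, , 3] * gp[, , 3]
  p * (gp - array(dot, dim(p)))
}
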