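#' Training configuration for the viability segmenter
#'
#' Defaults follow the published training recipe: Adam with exponential
#' moment decay rates 0.9/0.999 and numerical constant 1e-7, initial learning
#' rate 5e-4 multiplied by 0.8 whenever the validation loss has not decreased
#' for 10 epochs, focal exponent gamma = 2, and indicator weights
#' `[alpha, beta]` selecting the focal and/or dice terms. The full-scale
#' recipe uses 512 x 512 patches, batch sizes 14 or 4 and 100 epochs; the
#' defaults here are the desk-scale profile (128 px patches, batch 8,
#' 12 epochs) that trains in minutes on one CPU.
#'
#' @param gamma Focal exponent (>= 0).
#' @param loss_alpha,loss_beta Indicators in \{0, 1\} enabling the focal and
#'   dice terms; not both 0.
#' @param learning_rate Initial Adam learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stability constant.
#' @param batch_size Images per optimization step.
#' @param patch_px Square patch size fed to the network.
#' @param epochs Number of training epochs.
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is decayed.
#' @param lr_decay Multiplicative learning-rate decay factor.
#' @param seed Seed controlling weight init, shuffling and augmentation.
#' @param encoder_name Encoder passed to [build_model()].
#' @param augment Logical: apply on-the-fly augmentation to training patches.
#' @return An object of class `train_config`.
#' @export
train_config <- function(gamma = 2,
                         loss_alpha = 1,
                         loss_beta = 0,
                         learning_rate = 5e-4,
                         adam_beta1 = 0.9,
                         adam_beta2 = 0.999,
                         adam_eps = 1e-7,
                         batch_size = 8L,
                         patch_px = 128L,
                         epochs = 12L,
                         plateau_patience = 10L,
                         lr_decay = 0.8,
                         seed = 1L,
                         encoder_name = "tiny",
                         augment = TRUE) {
  stopifnot(gamma >= 0, learning_rate > 0, batch_size >= 1, patch_px >= 16,
            epochs >= 1, plateau_patience >= 1, lr_decay > 0, lr_decay <= 1)
  if (!loss_alpha %in% c(0, 1) || !loss_beta %in% c(0, 1) ||
      (loss_alpha == 0 && loss_beta == 0)) {
    abort("loss_alpha and loss_beta must be 0/1 indicators, not both 0.",
          class = "phaseviab_config_error")
  }
  structure(
    list(
      gamma = gamma, loss_alpha = loss_alpha, loss_beta = loss_beta,
      learning_rate = learning_rate, adam_beta1 = adam_beta1,
      adam_beta2 = adam_beta2, adam_eps = adam_eps,
      batch_size = as.integer(batch_size), patch_px = as.integer(patch_px),
      epochs = as.integer(epochs),
      plateau_patience = as.integer(plateau_patience),
      lr_decay = lr_decay, seed = as.integer(seed),
      encoder_name = encoder_name, augment = isTRUE(augment)
    ),
    class = "train_config"
  )
}

#' Split time-lapse sequences into train/validation/test partitions
#'
#' Sequences (not frames) are the unit of splitting, so that frames of one
#' recording never straddle partitions. Counts are allocated proportionally
#' to `ratios` with largest-remainder rounding, and every partition receives
#' at least one sequence.
#'
#' @param sequence_ids Vector of unique sequence identifiers (>= 3).
#' @param ratios Length-3 numeric vector of train/validation/test weights.
#' @param seed Integer seed for the shuffle.
#' @return A list with character/integer vectors `train`, `validation`,
#'   `test`.
#' @export
#' @examples
#' split_sequences(1:8, seed = 1)
split_sequences <- function(sequence_ids, ratios = c(6, 1, 1), seed = 1L) {
  sequence_ids <- unique(sequence_ids)
  n <- length(sequence_ids)
  if (n < 3) {
    abort("At least 3 sequences are required to form a 3-way split.",
          class = "phaseviab_arg_error")
  }
  stopifnot(length(ratios) == 3, all(ratios > 0))
  set.seed(seed)
  shuffled <- sample(sequence_ids)
  exact <- n * ratios / sum(ratios)
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(exact - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  # every partition gets at least one sequence
  while (any(counts == 0)) {
    i <- which.min(counts)
    j <- which.max(counts)
    counts[i] <- counts[i] + 1
    counts[j] <- counts[j] - 1
  }
  idx <- cumsum(counts)
  list(
    train = shuffled[seq_len(idx[1])],
    validation = shuffled[(idx[1] + 1):idx[2]],
    test = shuffled[(idx[2] + 1):idx[3]]
  )
}

reflect_index <- function(i, n) {
  # reflect out-of-range indices back into 1..n (boundary mirrored)
  i <- (i - 1) %% (2 * n)
  ifelse(i < n, i + 1, 2 * n - i)
}

#' Randomly augment a training patch
#'
#' Applies, in order: random crop to `cfg$patch_px`, independent horizontal
#' and vertical flips (p = 0.5 each), integer translation of up to 10% of the
#' patch with reflect padding, additive Gaussian noise (sigma = 1% of the
#' image range) and a brightness offset (up to 5% of the range). Geometric
#' transforms are applied identically to the label map (nearest-neighbour:
#' labels are only ever copied, never interpolated); photometric transforms
#' touch the image only.
#'
#' @param image Numeric matrix (phase image), at least `patch_px` on a side.
#' @param labels Integer \{0,1,2\} label matrix of the same size.
#' @param cfg A [train_config()]; `cfg$augment = FALSE` reduces to a center
#'   crop.
#' @param seed Optional integer seed for reproducible augmentation.
#' @return A list with elements `image` and `labels`.
#' @export
augment_patch <- function(image, labels, cfg = train_config(), seed = NULL) {
  stopifnot(is.matrix(image), identical(dim(image), dim(labels)))
  ps <- cfg$patch_px
  if (nrow(image) < ps || ncol(image) < ps) {
    abort("Patch size exceeds image dimensions.",
          class = "phaseviab_arg_error")
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- as_label_matrix(labels)
  if (!cfg$augment) {
    r0 <- (nrow(image) - ps) %/% 2
    c0 <- (ncol(image) - ps) %/% 2
    return(list(image = image[r0 + seq_len(ps), c0 + seq_len(ps)],
                labels = semantic_map(labels[r0 + seq_len(ps), c0 + seq_len(ps)])))
  }
  r0 <- sample.int(nrow(image) - ps + 1L, 1L) - 1L
  c0 <- sample.int(ncol(image) - ps + 1L, 1L) - 1L
  img <- image[r0 + seq_len(ps), c0 + seq_len(ps)]
  lab <- labels[r0 + seq_len(ps), c0 + seq_len(ps)]
  if (runif(1) < 0.5) { img <- img[ps:1, ]; lab <- lab[ps:1, ] }
  if (runif(1) < 0.5) { img <- img[, ps:1]; lab <- lab[, ps:1] }
  smax <- max(1L, floor(0.1 * ps))
  dr <- sample(-smax:smax, 1L)
  dc <- sample(-smax:smax, 1L)
  ri <- reflect_index(seq_len(ps) + dr, ps)
  ci <- reflect_index(seq_len(ps) + dc, ps)
  img <- img[ri, ci]
  lab <- lab[ri, ci]
  rng <- diff(range(img))
  if (rng == 0) rng <- 1
  img <- img + matrix(rnorm(ps * ps, sd = 0.01 * rng), ps, ps)
  img <- img + runif(1, -0.05, 0.05) * rng
  list(image = img, labels = semantic_map(lab))
}

# Per-image z-score used both in training and inference.
standardize_image <- function(x) {
  s <- sd(x)
  (x - mean(x)) / (s + 1e-8)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(
    mw = array(0, dim(p$w)), vw = array(0, dim(p$w)),
    mb = numeric(length(p$b)), vb = numeric(length(p$b))
  ))
}

adam_step <- function(params, grads, state, lr, b1, b2, eps, t) {
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mw <- b1 * st$mw + (1 - b1) * g$w
    st$vw <- b2 * st$vw + (1 - b2) * g$w^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w - lr * (st$mw / c1) / (sqrt(st$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

check_frames <- function(frames) {
  req <- c("sequence_id", "image", "labels")
  if (!is.data.frame(frames) || !all(req %in% names(frames))) {
    abort("`frames` must be a data frame with columns sequence_id, image, labels.",
          class = "phaseviab_arg_error")
  }
  invisible(frames)
}

# Loss gradient at the logits for one sample. Per-sample gradients are later
# averaged over the batch; the focal term wants that 1/B factor, the dice
# term is already a batch-level loss, so it is pre-multiplied by B here.
sample_grad <- function(probs, onehot, cfg, dice_batch_stats = NULL,
                        batch_size = 1L) {
  g <- array(0, dim(probs))
  if (cfg$loss_alpha == 1) {
    g <- g + focal_grad_logits(probs, onehot, gamma = cfg$gamma)
  }
  if (cfg$loss_beta == 1 && !is.null(dice_batch_stats)) {
    g <- g + batch_size *
      soft_dice_grad_logits(probs, onehot, dice_batch_stats)
  }
  g
}

#' Train the viability segmenter
#'
#' Minimizes the combined focal/dice loss with Adam over randomly shuffled
#' mini-batches of augmented patches. After every epoch the loss is computed
#' on the whole validation partition; the weights with the lowest validation
#' loss are kept, and the learning rate is multiplied by `cfg$lr_decay`
#' whenever the validation loss has not decreased for
#' `cfg$plateau_patience` consecutive epochs.
#'
#' When the dice indicator is active the training gradient uses the soft
#' (probability-mass) dice over the mini-batch, which is differentiable;
#' reported loss values use the same soft statistic. Hard-label dice is used
#' for evaluation via [dice_loss()].
#'
#' @param model An `eunet` from [build_model()] (or `NULL` to build one from
#'   `cfg$encoder_name` and `cfg$seed`).
#' @param frames Data frame with columns `sequence_id`, `image` (list of
#'   numeric matrices) and `labels` (list of \{0,1,2\} label matrices), e.g.
#'   from [sim_frames()].
#' @param split A partition from [split_sequences()]; training uses
#'   `split$train`, validation `split$validation`.
#' @param cfg A [train_config()].
#' @return The trained model. The best (lowest validation loss) weights are
#'   installed; the per-epoch history is attached as `model$history`, a
#'   tibble with columns `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
train_segmenter <- function(model = NULL, frames, split, cfg = train_config()) {
  check_frames(frames)
  if (is.null(model)) model <- build_model(cfg$encoder_name, seed = cfg$seed)
  tr <- frames[frames$sequence_id %in% split$train, ]
  va <- frames[frames$sequence_id %in% split$validation, ]
  if (nrow(tr) == 0 || nrow(va) == 0) {
    abort("Training and validation partitions must both be non-empty.",
          class = "phaseviab_arg_error")
  }
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  lr <- cfg$learning_rate
  t_step <- 0L
  best_val <- Inf
  best_params <- model$params
  stall <- 0L
  history <- vector("list", cfg$epochs)

  val_images <- lapply(va$image, standardize_image)
  val_onehot <- lapply(va$labels, as_onehot)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(nrow(tr))
    batch_losses <- c()
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      pats <- lapply(idx, function(i)
        augment_patch(tr$image[[i]], tr$labels[[i]], cfg))
      xs <- lapply(pats, function(p) standardize_image(p$image))
      ys <- lapply(pats, function(p) as_onehot(p$labels))

      # one forward pass per sample, caches kept for the whole mini-batch so
      # the batch-level soft dice statistics reuse the same activations
      fws <- lapply(xs, function(x) net_forward(model, x, keep_cache = TRUE))
      dice_stats_batch <- NULL
      if (cfg$loss_beta == 1) {
        dice_stats_batch <- dice_stats(lapply(fws, `[[`, "out"), ys,
                                       hard = FALSE)
      }

      grads_sum <- NULL
      loss_sum <- 0
      for (j in seq_along(xs)) {
        p <- fws[[j]]$out
        if (cfg$loss_alpha == 1) {
          loss_sum <- loss_sum + focal_loss(p, ys[[j]], gamma = cfg$gamma)
        }
        gz <- sample_grad(p, ys[[j]], cfg, dice_stats_batch, length(xs))
        g <- net_backward(model, fws[[j]]$cache, gz)
        if (is.null(grads_sum)) {
          grads_sum <- g
        } else {
          for (nm in names(g)) {
            grads_sum[[nm]]$w <- grads_sum[[nm]]$w + g[[nm]]$w
            grads_sum[[nm]]$b <- grads_sum[[nm]]$b + g[[nm]]$b
          }
        }
      }
      nb <- length(xs)
      loss_val <- loss_sum / nb
      for (nm in names(grads_sum)) {
        grads_sum[[nm]]$w <- grads_sum[[nm]]$w / nb
        grads_sum[[nm]]$b <- grads_sum[[nm]]$b / nb
      }
      if (cfg$loss_beta == 1) {
        eps <- 1e-6
        sc <- ifelse(dice_stats_batch$tp + dice_stats_batch$fn == 0, 1,
                     (2 * dice_stats_batch$tp + eps) /
                       (2 * dice_stats_batch$tp + dice_stats_batch$fp +
                          dice_stats_batch$fn + eps))
        loss_val <- loss_val + (1 - mean(sc))
      }
      if (!is.finite(loss_val)) {
        abort(sprintf("Non-finite training loss at epoch %d.", epoch),
              class = "phaseviab_training_error")
      }
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads_sum, state, lr,
                       cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps, t_step)
      model$params <- upd$params
      state <- upd$state
      batch_losses <- c(batch_losses, loss_val)
    }

    # whole-validation-set loss
    val_probs <- lapply(val_images, function(x) net_forward(model, x)$out)
    val_loss <- 0
    if (cfg$loss_alpha == 1) {
      val_loss <- val_loss + focal_loss(val_probs, val_onehot, gamma = cfg$gamma)
    }
    if (cfg$loss_beta == 1) {
      val_loss <- val_loss + dice_loss(val_probs, val_onehot, hard = FALSE)
    }
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_params <- model$params
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$plateau_patience) {
        lr <- lr * cfg$lr_decay
        stall <- 0L
      }
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(batch_losses),
      val_loss = val_loss, lr = lr
    )
  }
  model$params <- best_params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model$train_cfg <- cfg
  model
}

# ---- inference --------------------------------------------------------------

# Pad a matrix on the bottom/right by reflection so dims are multiples of m.
pad_to_multiple <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  H <- ceiling(h / m) * m
  W <- ceiling(w / m) * m
  if (H == h && W == w) return(list(x = x, h = h, w = w))
  ri <- reflect_index(seq_len(H), h)
  ci <- reflect_index(seq_len(W), w)
  list(x = x[ri, ci], h = h, w = w)
}

#' Predict viability maps for a phase image
#'
#' Runs the trained segmenter on a (per-image standardized) phase image and
#' returns both the three-class probability map and the argmax semantic map.
#' Images whose side exceeds the training patch size are processed in
#' overlapping tiles (stride = half patch) whose logits are averaged;
#' images are reflect-padded so dimensions divide the network's total
#' downsampling factor.
#'
#' @param object A trained `eunet`.
#' @param pm A [phase_map()] or a plain numeric matrix.
#' @param patch_px Tile size; defaults to the training patch size (or the
#'   full image if the model carries none).
#' @param ... Unused.
#' @return A list with `probs` (H x W x 3 array, rows sum to 1) and `labels`
#'   (a [semantic_map()]).
#' @export
predict.eunet <- function(object, pm, patch_px = NULL, ...) {
  if (!object$trained) {
    abort("Model has not been trained; train it or load weights first.",
          class = "phaseviab_arg_error")
  }
  x <- if (inherits(pm, "phase_map")) pm$phase else pm
  stopifnot(is.matrix(x))
  x <- standardize_image(x)
  if (is.null(patch_px)) {
    patch_px <- if (!is.null(object$train_cfg)) object$train_cfg$patch_px
                else max(dim(x))
  }
  m <- object$down_factor
  padded <- pad_to_multiple(x, m)
  xp <- padded$x
  H <- nrow(xp); W <- ncol(xp)
  if (H <= patch_px && W <= patch_px) {
    logits <- forward_logits(object, xp)
  } else {
    step <- max(m, (patch_px %/% 2) %/% m * m)
    ps <- min(patch_px, H, W)
    acc <- array(0, c(H, W, 3))
    cnt <- matrix(0, H, W)
    r_starts <- unique(pmin(seq(1, H, by = step), H - ps + 1))
    c_starts <- unique(pmin(seq(1, W, by = step), W - ps + 1))
    for (r0 in r_starts) {
      for (c0 in c_starts) {
        rows <- r0:(r0 + ps - 1)
        cols <- c0:(c0 + ps - 1)
        lt <- forward_logits(object, xp[rows, cols])
        acc[rows, cols, ] <- acc[rows, cols, ] + lt
        cnt[rows, cols] <- cnt[rows, cols] + 1
      }
    }
    logits <- acc / array(cnt, dim(acc))
  }
  probs <- softmax3(logits)
  probs <- probs[seq_len(padded$h), seq_len(padded$w), , drop = FALSE]
  labels <- semantic_map(argmax3(probs))
  list(probs = probs, labels = labels)
}

# forward pass returning pre-softmax logits
forward_logits <- function(model, x) {
  net_forward(model, x)$logits
}
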