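# Model construction, forward/backward correctness, augmentation, splitting.

test_that("models emit simplex-constrained probability maps of input size", {
  for (enc in c("tiny", "b0")) {
    m <- build_model(enc, seed = 1)
    x <- matrix(rnorm(64 * 64), 64)
    out <- phaseviab:::net_forward(m, x)$out
    expect_equal(dim(out), c(64, 64, 3))
    expect_true(all(out >= 0))
    expect_lt(max(abs(out[, , 1] + out[, , 2] + out[, , 3] - 1)), 1e-10)
  }
})

test_that("forward pass is deterministic and divisibility is enforced", {
  m <- build_model("tiny", seed = 3)
  x <- matrix(rnorm(32 * 32), 32)
  expect_identical(phaseviab:::net_forward(m, x)$out,
                   phaseviab:::net_forward(m, x)$out)
  expect_error(phaseviab:::net_forward(m, matrix(0, 30, 30)),
               class = "phaseviab_arg_error")
  expect_error(build_model("vgg"), class = "phaseviab_arg_error")
})

test_that("encoder capacity increases from tiny through the B-like family", {
  n_tiny <- n_params(build_model("tiny"))
  n_b0 <- n_params(build_model("b0"))
  n_b3 <- n_params(build_model("b3"))
  n_b7 <- n_params(build_model("b7"))
  expect_lt(n_tiny, n_b0)
  expect_lt(n_b0, n_b3)
  expect_lt(n_b3, n_b7)
  expect_lt(n_tiny, 5e5)  # desk-scale profile stays lightweight
})

test_that("conv kernels match a brute-force convolution oracle", {
  ref_conv <- function(x, w, b, k, stride, pad) {
    H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; Cout <- ncol(w)
    Ho <- (H + 2 * pad - k) %/% stride + 1
    Wo <- (W + 2 * pad - k) %/% stride + 1
    out <- array(0, c(Ho, Wo, Cout))
    for (co in 1:Cout) for (oi in 1:Ho) for (oj in 1:Wo) {
      acc <- b[co]
      for (c in 1:C) for (ki in 1:k) for (kj in 1:k) {
        ii <- (oi - 1) * stride + ki - pad
        jj <- (oj - 1) * stride + kj - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + x[ii, jj, c] * w[(c - 1) * k * k + (kj - 1) * k + ki, co]
        }
      }
      out[oi, oj, co] <- acc
    }
    out
  }
  set.seed(2)
  for (cfgs in list(c(3, 1, 1), c(3, 2, 1), c(1, 1, 0))) {
    k <- cfgs[1]; s <- cfgs[2]; p <- cfgs[3]
    x <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
    w <- matrix(rnorm(k * k * 3 * 4), k * k * 3, 4)
    b <- rnorm(4)
    expect_equal(phaseviab:::conv2d_fwd_cpp(x, w, b, k, s, p),
                 ref_conv(x, w, b, k, s, p), tolerance = 1e-12)
  }
  # depthwise equals a block-diagonal full convolution
  x <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  w <- matrix(rnorm(9 * 3), 9, 3); b <- rnorm(3)
  wf <- matrix(0, 27, 3)
  for (c in 1:3) wf[(c - 1) * 9 + 1:9, c] <- w[, c]
  expect_equal(phaseviab:::dwconv2d_fwd_cpp(x, w, b, 3L, 2L, 1L),
               ref_conv(x, wf, b, 3, 2, 1), tolerance = 1e-12)
})

test_that("network gradients match numerical differentiation", {
  pv <- asNamespace("phaseviab")
  set.seed(7)
  for (enc in c("tiny", "b0")) {
    m <- build_model(enc, seed = 2)
    x <- matrix(rnorm(32 * 32), 32)
    ylab <- matrix(sample(0:2, 32 * 32, TRUE), 32)
    y <- pv$as_onehot(ylab)
    fw <- pv$net_forward(m, x, keep_cache = TRUE)
    gz <- pv$focal_grad_logits(fw$out, y, gamma = 2)
    g <- pv$net_backward(m, fw$cache, gz)
    lf <- function(model) focal_loss(pv$net_forward(model, x)$out, ylab,
                                     gamma = 2)
    tensors <- if (enc == "tiny") c("stem", "enc3_a", "dec2", "head")
               else c("stem", "mb2_1_dw", "mb3_1_exp", "head")
    for (nm in tensors) {
      i <- sample(length(m$params[[nm]]$w), 1)
      eps <- 1e-5
      m2 <- m; m2$params[[nm]]$w[i] <- m2$params[[nm]]$w[i] + eps
      m3 <- m; m3$params[[nm]]$w[i] <- m3$params[[nm]]$w[i] - eps
      num <- (lf(m2) - lf(m3)) / (2 * eps)
      expect_equal(g[[nm]]$w[i], num, tolerance = 1e-3)
    }
  }
})

test_that("sequence splitting allocates 6:1:1 with largest remainders", {
  s8 <- split_sequences(1:8, seed = 1)
  expect_equal(lengths(s8)[c("train", "validation", "test")],
               c(train = 6L, validation = 1L, test = 1L))
  s16 <- split_sequences(1:16, seed = 1)
  expect_equal(lengths(s16)[c("train", "validation", "test")],
               c(train = 12L, validation = 2L, test = 2L))
  # reproducible, disjoint, exhaustive
  expect_identical(split_sequences(1:11, seed = 9), split_sequences(1:11, seed = 9))
  s <- split_sequences(letters[1:10], seed = 4)
  expect_length(intersect(s$train, s$validation), 0)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(unlist(s), letters[1:10])
  expect_error(split_sequences(1:2), class = "phaseviab_arg_error")
})

test_that("augmentation preserves label values and is seed-reproducible", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64)
  lab <- matrix(sample(0:2, 64 * 64, TRUE), 64)
  cfg <- train_config(patch_px = 32)
  a1 <- augment_patch(img, lab, cfg, seed = 5)
  a2 <- augment_patch(img, lab, cfg, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(unclass(a1$labels) %in% 0:2))
  expect_equal(dim(a1$image), c(32, 32))

  # disabled augmentation: center crop, labels untouched
  cfg_off <- train_config(patch_px = 32, augment = FALSE)
  a0 <- augment_patch(img, lab, cfg_off)
  expect_equal(a0$image, img[17:48, 17:48])
  expect_equal(unclass(a0$labels), lab[17:48, 17:48])

  expect_error(augment_patch(matrix(0, 16, 16), matrix(0L, 16, 16),
                             train_config(patch_px = 32)),
               class = "phaseviab_arg_error")
})

test_that("checkpoints round-trip and gate prediction on training", {
  m <- build_model("tiny", seed = 1)
  expect_error(predict(m, matrix(0, 32, 32)), class = "phaseviab_arg_error")
  path <- tempfile(fileext = ".rds")
  save_weights(m, path)
  m2 <- load_weights(build_model("tiny", seed = 99), path)
  expect_true(m2$trained)
  x <- matrix(rnorm(32 * 32), 32)
  expect_equal(phaseviab:::net_forward(m2, x)$out,
               phaseviab:::net_forward(m, x)$out)
  expect_error(load_weights(build_model("b0"), path),
               class = "phaseviab_arg_error")
})

test_that("a tiny model fits linearly separable synthetic data", {
  # dead nuclei brighter in phase: near-zero training focal loss, and the
  # plateau rule leaves lr untouched while validation keeps improving
  set.seed(33)
  mk <- function(seed) {
    set.seed(seed)
    img <- matrix(0, 32, 32)
    lab <- matrix(2L, 32, 32)
    for (i in 1:2) {
      r <- sample(8:24, 1); c <- sample(8:24, 1)
      cls <- sample(0:1, 1)
      m <- disk_mask(32, 32, r, c, 4)
      img[m] <- img[m] + if (cls == 1) 2 else 1
      lab[m] <- cls
    }
    list(image = img + matrix(rnorm(1024, sd = 0.02), 32), labels = lab)
  }
  samples <- lapply(1:30, mk)
  frames <- tibble::tibble(
    sequence_id = rep(c("a", "b", "c"), each = 10),
    frame = rep(1:10, 3),
    image = lapply(samples, `[[`, "image"),
    labels = lapply(samples, function(s) semantic_map(s$labels))
  )
  split <- list(train = c("a", "b"), validation = "c", test = "c")
  cfg <- train_config(patch_px = 32, epochs = 8, batch_size = 5,
                      learning_rate = 2e-3, seed = 2, augment = FALSE)
  model <- train_segmenter(NULL, frames, split, cfg)
  h <- model$history
  expect_equal(nrow(h), 8)
  expect_lt(h$train_loss[8], h$train_loss[1])
  expect_lt(min(h$val_loss), 0.1)
  expect_equal(h$lr[8], cfg$learning_rate)  # no plateau decay while improving
  # the recovered best model segments a fresh separable frame
  s <- mk(999)
  pred <- predict(model, s$image)
  expect_true(all(unclass(pred$labels) %in% 0:2))
  expect_lt(max(abs(apply(pred$probs, c(1, 2), sum) - 1)), 1e-10)
  expect_gt(mean(unclass(pred$labels) == s$labels), 0.9)

  # an image larger than the training patch goes through overlap tiling
  big <- rbind(cbind(mk(7)$image, mk(8)$image), cbind(mk(9)$image, mk(10)$image))
  pred_big <- predict(model, big)
  expect_equal(dim(pred_big$probs), c(64, 64, 3))
  expect_lt(max(abs(apply(pred_big$probs, c(1, 2), sum) - 1)), 1e-10)

  # non-multiple-of-16 input is reflect-padded and cropped back
  pred_odd <- predict(model, big[1:50, 1:45])
  expect_equal(dim(unclass(pred_odd$labels)), c(50, 45))
})

test_that("plateau rule decays the learning rate after patience epochs", {
  # constant images carry no gradient signal for separating classes, so the
  # validation loss stalls and the 0.8 decay fires after `patience` epochs
  frames <- tibble::tibble(
    sequence_id = rep(c("a", "b", "c"), each = 2),
    frame = rep(1:2, 3),
    image = replicate(6, matrix(0, 16, 16), simplify = FALSE),
    labels = replicate(6, semantic_map(matrix(2L, 16, 16)), simplify = FALSE)
  )
  split <- list(train = c("a", "b"), validation = "c", test = "c")
  # learning rate so small that the validation loss cannot move by more than
  # the improvement tolerance: epoch 1 sets the best, epochs 2-4 stall
  cfg <- train_config(patch_px = 16, epochs = 5, batch_size = 4,
                      plateau_patience = 3, learning_rate = 1e-15,
                      seed = 1, augment = FALSE)
  model <- train_segmenter(NULL, frames, split, cfg)
  h <- model$history
  expect_equal(h$lr[3], 1e-15)
  expect_equal(h$lr[4], 0.8e-15, tolerance = 1e-6)
  expect_equal(h$lr[5], 0.8e-15, tolerance = 1e-6)
})
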