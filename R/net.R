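#' @section Network engine:
#' The segmenter is a U-Net-style encoder-decoder built from a small set of
#' primitives (2-D convolution, depthwise convolution, nearest-neighbour
#' upsampling, channel concatenation, residual addition) with explicit
#' forward and reverse passes; weights are plain R matrices so a model is an
#' ordinary serializable list.
#' @name eunet-engine
#' @keywords internal
NULL

act_fwd <- function(x, act) {
  switch(act,
    linear = x,
    relu = pmax(x, 0),
    relu6 = pmin(pmax(x, 0), 6),
    abort(paste0("Unknown activation: ", act), class = "phaseviab_arg_error")
  )
}

act_bwd <- function(grad, pre, act) {
  switch(act,
    linear = grad,
    relu = grad * (pre > 0),
    relu6 = grad * (pre > 0 & pre < 6),
    abort(paste0("Unknown activation: ", act), class = "phaseviab_arg_error")
  )
}

up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

down2sum <- function(g) {
  d <- dim(g)
  a <- g[seq(1, d[1], 2), , , drop = FALSE] + g[seq(2, d[1], 2), , , drop = FALSE]
  a[, seq(1, d[2], 2), , drop = FALSE] + a[, seq(2, d[2], 2), , drop = FALSE]
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

softmax3 <- function(z) {
  m <- pmax(pmax(z[, , 1], z[, , 2]), z[, , 3])
  e <- exp(z - array(m, dim(z)))
  s <- e[, , 1] + e[, , 2] + e[, , 3]
  e / array(s, dim(z))
}

# ---- architecture construction ---------------------------------------------

he_weights <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$blocks <- list()
  env$params <- list()
  env$n <- 0L
  env
}

add_conv <- function(bd, name, k, stride, cin, cout, act = "relu") {
  bd$blocks[[length(bd$blocks) + 1L]] <-
    list(op = "conv", name = name, k = k, stride = stride,
         pad = if (k == 1) 0L else (k - 1L) %/% 2L,
         cin = cin, cout = cout, act = act)
  bd$params[[name]] <- list(w = he_weights(k, cin, cout), b = numeric(cout))
  invisible(cout)
}

add_dwconv <- function(bd, name, k, stride, c, act = "relu") {
  bd$blocks[[length(bd$blocks) + 1L]] <-
    list(op = "dwconv", name = name, k = k, stride = stride,
         pad = (k - 1L) %/% 2L, c = c, act = act)
  bd$params[[name]] <- list(
    w = matrix(rnorm(k * k * c, sd = sqrt(2 / (k * k))), k * k, c),
    b = numeric(c)
  )
  invisible(c)
}

add_op <- function(bd, op, tag = NULL) {
  bd$blocks[[length(bd$blocks) + 1L]] <- list(op = op, tag = tag)
  invisible(NULL)
}

add_mbconv <- function(bd, prefix, cin, cout, stride, expand) {
  act <- if (expand == 1) "relu" else "relu6"
  use_res <- stride == 1 && cin == cout
  if (use_res) add_op(bd, "save", paste0(prefix, "_res"))
  ce <- cin
  if (expand > 1) {
    ce <- cin * expand
    add_conv(bd, paste0(prefix, "_exp"), 1L, 1L, cin, ce, act)
  }
  add_dwconv(bd, paste0(prefix, "_dw"), 3L, stride, ce, act)
  add_conv(bd, paste0(prefix, "_proj"), 1L, 1L, ce, cout, "linear")
  if (use_res) add_op(bd, "add", paste0(prefix, "_res"))
  invisible(cout)
}

scaled <- function(x, coef) pmax(4L, as.integer(round(x * coef / 4) * 4))

bcfg_table <- list(
  b0 = c(w = 1.0, d = 1.0), b1 = c(w = 1.0, d = 1.1),
  b2 = c(w = 1.1, d = 1.2), b3 = c(w = 1.2, d = 1.4),
  b4 = c(w = 1.4, d = 1.8), b5 = c(w = 1.6, d = 2.2),
  b6 = c(w = 1.8, d = 2.6), b7 = c(w = 2.0, d = 3.1)
)

build_tiny <- function(bd, in_channels) {
  ch <- c(8L, 16L, 24L, 32L, 48L)
  add_conv(bd, "stem", 3L, 1L, in_channels, ch[1])
  add_op(bd, "save", "e1")
  for (s in 2:5) {
    add_conv(bd, sprintf("enc%d_a", s), 3L, 2L, ch[s - 1], ch[s])
    add_conv(bd, sprintf("enc%d_b", s), 3L, 1L, ch[s], ch[s])
    if (s < 5) add_op(bd, "save", sprintf("e%d", s))
  }
  cur <- ch[5]
  for (s in 4:1) {
    add_op(bd, "upsample")
    add_op(bd, "concat", sprintf("e%d", s))
    cur <- add_conv(bd, sprintf("dec%d", s), 3L, 1L, cur + ch[s], ch[s])
  }
  add_conv(bd, "head", 1L, 1L, cur, 3L, "linear")
  add_op(bd, "softmax")
  16L
}

build_blike <- function(bd, variant, in_channels) {
  coef <- bcfg_table[[variant]]
  wc <- coef[["w"]]; dc <- coef[["d"]]
  stem <- scaled(16L, wc)
  widths <- vapply(c(12L, 16L, 24L, 40L, 64L), scaled, integer(1), coef = wc)
  depths <- as.integer(ceiling(c(1L, 2L, 2L, 2L, 2L) * dc))
  expands <- c(1L, 6L, 6L, 6L, 6L)
  strides <- c(1L, 2L, 2L, 2L, 2L)
  add_conv(bd, "stem", 3L, 2L, in_channels, stem)      # /2
  cur <- stem
  for (s in seq_along(widths)) {
    for (r in seq_len(depths[s])) {
      cur <- add_mbconv(bd, sprintf("mb%d_%d", s, r), cur, widths[s],
                        if (r == 1) strides[s] else 1L, expands[s])
    }
    if (s < 5) add_op(bd, "save", sprintf("e%d", s))   # /2 /4 /8 /16
  }
  dec_w <- vapply(c(32L, 24L, 16L, 12L, 8L), scaled, integer(1), coef = wc)
  for (s in 1:5) {
    add_op(bd, "upsample")
    skip_s <- 5L - s
    if (skip_s >= 1L) {
      add_op(bd, "concat", sprintf("e%d", skip_s))
      cin <- cur + widths[skip_s]
    } else {
      cin <- cur
    }
    cur <- add_conv(bd, sprintf("dec%d", s), 3L, 1L, cin, dec_w[s])
  }
  add_conv(bd, "head", 1L, 1L, cur, 3L, "linear")
  add_op(bd, "softmax")
  32L
}

#' Build an encoder-decoder viability segmenter
#'
#' Constructs a U-Net-style model mapping a single-channel phase image to a
#' three-class probability map (live, dead, background), with skip
#' connections between matching encoder and decoder resolutions and a
#' softmax head.
#'
#' Encoders:
#' * `"tiny"`: four stride-2 stages of plain conv + ReLU blocks
#'   (about 0.2 M parameters) - the desk-scale profile used throughout the
#'   tests and examples.
#' * `"b0"` .. `"b7"`: EfficientNet-style encoders built from
#'   inverted-bottleneck MBConv blocks (expansion 1 with ReLU, expansion 6
#'   with ReLU6), five downsampling stages and five decoding stages, with
#'   compound width/depth scaling increasing from b0 to b7. These are
#'   reduced-width analogues intended for structural fidelity, not for
#'   ImageNet-scale capacity.
#'
#' Weights are randomly initialized (He normal, seeded). Externally trained
#' encoder weights can be injected with [load_weights()].
#'
#' @param encoder_name One of `"tiny"`, `"b0"` .. `"b7"`.
#' @param seed Integer seed for weight initialization.
#' @param in_channels Number of input image channels.
#' @return An object of class `eunet`.
#' @export
#' @examples
#' m <- build_model("tiny", seed = 1)
#' glance(m)
build_model <- function(encoder_name = "tiny", seed = 1L, in_channels = 1L) {
  encoder_name <- tolower(encoder_name)
  if (!encoder_name %in% c("tiny", names(bcfg_table))) {
    abort(sprintf("Unknown encoder '%s'.", encoder_name),
          class = "phaseviab_arg_error")
  }
  bd <- new_builder()
  set.seed(seed)
  down <- if (encoder_name == "tiny") build_tiny(bd, in_channels)
          else build_blike(bd, encoder_name, in_channels)
  structure(
    list(
      encoder = encoder_name,
      in_channels = as.integer(in_channels),
      down_factor = down,
      blocks = bd$blocks,
      params = bd$params,
      seed = as.integer(seed),
      trained = FALSE
    ),
    class = "eunet"
  )
}

#' @export
print.eunet <- function(x, ...) {
  cat(sprintf(
    "<eunet> encoder '%s', %d parameter tensors, %s parameters, %strained\n",
    x$encoder, length(x$params), format(n_params(x), big.mark = ","),
    if (x$trained) "" else "un"
  ))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `eunet` model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

# ---- forward / backward -----------------------------------------------------

# x: H x W (matrix) or H x W x C array. Returns list(probs, cache).
net_forward <- function(model, x, keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] %% model$down_factor != 0 || d[2] %% model$down_factor != 0) {
    abort(sprintf("Input dimensions must be divisible by %d.",
                  model$down_factor),
          class = "phaseviab_arg_error")
  }
  saves <- list()
  cache <- if (keep_cache) vector("list", length(model$blocks)) else NULL
  logits <- NULL
  cur <- x
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    if (bl$op == "conv") {
      p <- model$params[[bl$name]]
      pre <- conv2d_fwd_cpp(cur, p$w, p$b, bl$k, bl$stride, bl$pad)
      if (keep_cache) cache[[i]] <- list(x = cur, pre = pre)
      cur <- act_fwd(pre, bl$act)
    } else if (bl$op == "dwconv") {
      p <- model$params[[bl$name]]
      pre <- dwconv2d_fwd_cpp(cur, p$w, p$b, bl$k, bl$stride, bl$pad)
      if (keep_cache) cache[[i]] <- list(x = cur, pre = pre)
      cur <- act_fwd(pre, bl$act)
    } else if (bl$op == "save") {
      saves[[bl$tag]] <- cur
    } else if (bl$op == "upsample") {
      cur <- up2(cur)
    } else if (bl$op == "concat") {
      if (keep_cache) cache[[i]] <- list(n_main = dim(cur)[3])
      cur <- cat_channels(cur, saves[[bl$tag]])
    } else if (bl$op == "add") {
      cur <- cur + saves[[bl$tag]]
    } else if (bl$op == "softmax") {
      logits <- cur
      cur <- softmax3(cur)
    }
  }
  list(out = cur, cache = cache, logits = logits)
}

# grad_logits: gradient of the loss w.r.t. the pre-softmax logits.
# Returns named list of param gradients (w, b per conv).
net_backward <- function(model, cache, grad_logits) {
  grads <- list()
  tag_grads <- list()
  grad <- grad_logits
  for (i in rev(seq_along(model$blocks))) {
    bl <- model$blocks[[i]]
    if (bl$op == "softmax") {
      next  # gradient enters at the logits
    } else if (bl$op == "conv") {
      gpre <- act_bwd(grad, cache[[i]]$pre, bl$act)
      p <- model$params[[bl$name]]
      bw <- conv2d_bwd_cpp(cache[[i]]$x, p$w, gpre, bl$k, bl$stride, bl$pad)
      gprev <- grads[[bl$name]]
      if (is.null(gprev)) {
        grads[[bl$name]] <- list(w = bw$gw, b = as.numeric(bw$gb))
      } else {
        grads[[bl$name]] <- list(w = gprev$w + bw$gw,
                                 b = gprev$b + as.numeric(bw$gb))
      }
      grad <- bw$gx
    } else if (bl$op == "dwconv") {
      gpre <- act_bwd(grad, cache[[i]]$pre, bl$act)
      p <- model$params[[bl$name]]
      bw <- dwconv2d_bwd_cpp(cache[[i]]$x, p$w, gpre, bl$k, bl$stride, bl$pad)
      gprev <- grads[[bl$name]]
      if (is.null(gprev)) {
        grads[[bl$name]] <- list(w = bw$gw, b = as.numeric(bw$gb))
      } else {
        grads[[bl$name]] <- list(w = gprev$w + bw$gw,
                                 b = gprev$b + as.numeric(bw$gb))
      }
      grad <- bw$gx
    } else if (bl$op == "save") {
      tg <- tag_grads[[bl$tag]]
      if (!is.null(tg)) grad <- grad + tg
    } else if (bl$op == "upsample") {
      grad <- down2sum(grad)
    } else if (bl$op == "concat") {
      nm <- cache[[i]]$n_main
      total <- dim(grad)[3]
      skip_part <- grad[, , (nm + 1):total, drop = FALSE]
      tg <- tag_grads[[bl$tag]]
      tag_grads[[bl$tag]] <- if (is.null(tg)) skip_part else tg + skip_part
      grad <- grad[, , seq_len(nm), drop = FALSE]
    } else if (bl$op == "add") {
      tg <- tag_grads[[bl$tag]]
      tag_grads[[bl$tag]] <- if (is.null(tg)) grad else tg + grad
    }
  }
  grads
}

#' Save or load model weights
#'
#' Weights are stored with `saveRDS()` together with the architecture name,
#' so a checkpoint can be restored into a freshly built model. Loading a
#' checkpoint marks the model as trained. `load_weights()` also accepts a
#' plain named list of parameter tensors covering a subset of the layers
#' (e.g. an externally pre-trained encoder).
#'
#' @param model An `eunet` model.
#' @param path File path for the checkpoint.
#' @return `save_weights()` returns `path` invisibly; `load_weights()`
#'   returns the updated model.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "eunet"))
  saveRDS(list(encoder = model$encoder, params = model$params,
               trained = model$trained), path)
  invisible(path)
}

#' @rdname save_weights
#' @param weights Either a checkpoint path or a named list of
#'   `list(w =, b =)` tensors.
#' @export
load_weights <- function(model, weights) {
  stopifnot(inherits(model, "eunet"))
  if (is.character(weights)) {
    ck <- readRDS(weights)
    if (!identical(ck$encoder, model$encoder)) {
      abort(sprintf("Checkpoint was built for encoder '%s', model uses '%s'.",
                    ck$encoder, model$encoder),
            class = "phaseviab_arg_error")
    }
    weights <- ck$params
  }
  for (nm in names(weights)) {
    if (!nm %in% names(model$params)) {
      abort(sprintf("Unknown parameter tensor '%s'.", nm),
            class = "phaseviab_arg_error")
    }
    tpl <- model$params[[nm]]
    if (!identical(dim(tpl$w), dim(weights[[nm]]$w)) ||
        length(tpl$b) != length(weights[[nm]]$b)) {
      abort(sprintf("Shape mismatch for parameter tensor '%s'.", nm),
            class = "phaseviab_arg_error")
    }
    model$params[[nm]] <- weights[[nm]]
  }
  model$trained <- TRUE
  model
}
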