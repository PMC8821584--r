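#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects.
#'
#' `tidy.eunet()` returns one row per parameter tensor; `glance.eunet()` a
#' one-row model summary (best validation loss, epochs, parameter count).
#' `tidy.viab_confusion()` returns the object confusion in long form with
#' raw counts and column-normalized percentages; `glance.viab_confusion()`
#' the per-class precision/recall/F1 pivoted wide with the macro F1.
#'
#' @param x An `eunet` or `viab_confusion` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy eunet
#' @export
tidy.eunet <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$params), function(nm) {
    p <- x$params[[nm]]
    tibble::tibble(
      tensor = nm,
      n_weights = length(p$w),
      n_bias = length(p$b),
      weight_sd = stats::sd(p$w)
    )
  }))
}

#' @rdname tidiers
#' @method glance eunet
#' @export
glance.eunet <- function(x, ...) {
  tibble::tibble(
    encoder = x$encoder,
    n_parameters = n_params(x),
    trained = x$trained,
    epochs = if (!is.null(x$history)) nrow(x$history) else NA_integer_,
    best_val_loss = if (!is.null(x$history)) min(x$history$val_loss) else NA_real_
  )
}

#' @rdname tidiers
#' @method tidy viab_confusion
#' @export
tidy.viab_confusion <- function(x, ...) {
  norm <- tryCatch(normalize_confusion(x), warning = function(w) NULL)
  grid <- expand.grid(pred = c("live", "dead"), gt = c("live", "dead"),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    prediction = grid$pred,
    ground_truth = grid$gt,
    n = as.integer(x$counts[cbind(grid$pred, grid$gt)]),
    pct = if (is.null(norm)) NA_real_ else norm[cbind(grid$pred, grid$gt)]
  )
}

#' @rdname tidiers
#' @method glance viab_confusion
#' @export
glance.viab_confusion <- function(x, ...) {
  pr <- prf1(x)
  tibble::tibble(
    n_live = x$n_live,
    n_dead = x$n_dead,
    n_missed = sum(x$missed),
    precision_live_pct = pr$precision_pct[pr$class == "live"],
    recall_live_pct = pr$recall_pct[pr$class == "live"],
    f1_live_pct = pr$f1_pct[pr$class == "live"],
    precision_dead_pct = pr$precision_pct[pr$class == "dead"],
    recall_dead_pct = pr$recall_pct[pr$class == "dead"],
    f1_dead_pct = pr$f1_pct[pr$class == "dead"],
    macro_f1_pct = pr$f1_pct[pr$class == "macro"]
  )
}
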