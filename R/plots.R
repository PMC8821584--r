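#' Plot methods
#'
#' ggplot2 visualizations of the package's result types: phase maps and
#' semantic maps as rasters, training history as loss curves, group series
#' as mean +/- SEM ribbons.
#'
#' @name plots
NULL

raster_df <- function(m, value = "value") {
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d[[value]] <- as.vector(m)
  tibble::as_tibble(d)
}

#' @rdname plots
#' @param object A [phase_map()].
#' @param ... Unused.
#' @method autoplot phase_map
#' @export
autoplot.phase_map <- function(object, ...) {
  d <- raster_df(object$phase, "phase")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname plots
#' @method autoplot semantic_map
#' @export
autoplot.semantic_map <- function(object, ...) {
  d <- raster_df(unclass(object), "class")
  d$class <- factor(d$class, levels = 0:2,
                    labels = c("live", "dead", "background"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(
      values = c(live = "#2166ac", dead = "#b2182b", background = "grey90"),
      name = NULL
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname plots
#' @param model A trained `eunet` (with history).
#' @export
plot_history <- function(model) {
  stopifnot(inherits(model, "eunet"), !is.null(model$history))
  d <- tidyr::pivot_longer(model$history, c("train_loss", "val_loss"),
                           names_to = "partition", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL)
}

#' @rdname plots
#' @param stats A tibble from [group_stats()].
#' @param labels Length-2 character vector naming the two groups.
#' @export
plot_group_series <- function(stats, labels = c("group A", "group B")) {
  long <- dplyr::bind_rows(
    tibble::tibble(frame = stats$frame, group = labels[1],
                   mean = stats$mean_a, sem = stats$sem_a),
    tibble::tibble(frame = stats$frame, group = labels[2],
                   mean = stats$mean_b, sem = stats$sem_b)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "relative value", colour = NULL,
                  fill = NULL)
}
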