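# broom-style accessors and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training fit into its per-epoch history
#'
#' @param x An `sf_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_dsc`.
#' @method tidy sf_fit
#' @export
tidy.sf_fit <- function(x, ...) x$history

#' One-row summary of a training fit
#'
#' @param x An `sf_fit`.
#' @param ... Unused.
#' @return A tibble with phase, epochs run, best epoch and best validation
#'   global DSC.
#' @method glance sf_fit
#' @export
glance.sf_fit <- function(x, ...) {
  tibble::tibble(phase = x$phase, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_dsc = x$best_val_dsc,
                 final_train_loss = utils::tail(x$history$train_loss, 1))
}

#' Plot training curves
#'
#' Training loss and validation global DSC per epoch.
#'
#' @param object An `sf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sf_fit <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_dsc"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = paste0("Training (", object$phase, ")"),
                  x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a fusion-weights object
#'
#' @param x A `fusion_weights` object (see [msma_scores()]).
#' @param ... Unused.
#' @return A long tibble with `channel`, `modality`, `weight`.
#' @method tidy fusion_weights
#' @export
tidy.fusion_weights <- function(x, ...) {
  tibble::tibble(channel = rep(seq_along(x$alpha), 3L),
                 modality = rep(c("t2w", "dwi", "adc"),
                                each = length(x$alpha)),
                 weight = c(x$alpha, x$beta, x$gamma))
}

#' Plot per-method DSC distributions from evaluation records
#'
#' Violin-style summary of per-image DSC by method, mirroring the standard
#' presentation of segmentation benchmarks.
#'
#' @param records A tibble of [eval_record()] rows for several methods.
#' @return A ggplot object.
#' @export
plot_dsc_distributions <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$method, y = .data$dsc)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 8,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = "per-image DSC") +
    ggplot2::theme_minimal()
}

#' Plot a modality triple
#'
#' Panels for T2W, DWI, ADC (and the mask outline when present).
#'
#' @param object A [modality_triple()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modality_triple <- function(object, ...) {
  to_df <- function(m, nm) {
    tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                   col = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m), panel = nm)
  }
  panels <- dplyr::bind_rows(to_df(object$t2w, "T2W"),
                             to_df(object$dwi, "DWI"),
                             to_df(object$adc, "ADC"))
  if (!is.null(object$mask)) {
    panels <- dplyr::bind_rows(panels, to_df(object$mask + 0, "mask"))
  }
  panels$panel <- factor(panels$panel,
                         levels = c("T2W", "DWI", "ADC", "mask"))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
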