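# autoplot() methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an importance profile
#'
#' One line per constituent over the channel axis.
#'
#' @param object An `importance_profile` from [perturbation_importance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$channel, y = .data$score,
                               colour = .data$constituent)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "channel index", y = "importance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attention map
#'
#' Heatmap of query (rows) against key (columns) patch positions.
#'
#' @param object An `attention_map` from [extract_attention()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attention_map <- function(object, ...) {
  L <- nrow(object)
  df <- tidyr::expand_grid(query = seq_len(L) - 1L, key = seq_len(L) - 1L)
  df$weight <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "key position", y = "query position",
                  fill = "attention",
                  title = sprintf("layer %s, head %s", attr(object, "layer"),
                                  attr(object, "head"))) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training and validation loss (log scale) with the learning-rate
#' schedule as a secondary panel-free line.
#'
#' @param object A `spectral_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history[c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "series",
                            values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "composite loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot spectra
#'
#' Absorbance curves over wavelength for (a subset of) a dataset.
#'
#' @param object A [spectra_dataset()].
#' @param n Maximum number of spectra to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_dataset <- function(object, n = 20L, ...) {
  idx <- seq_len(min(n, nrow(object$X)))
  df <- tidyr::expand_grid(sample_id = object$sample_ids[idx],
                           wavelength_nm = wavelengths(object$grid))
  df$absorbance <- as.vector(t(object$X[idx, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$absorbance,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance") +
    ggplot2::theme_minimal()
}
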