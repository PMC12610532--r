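# broom-style tidiers for fitted models.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a training run
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, train/val loss, learning
#'   rate, loss components).
#' @export
tidy.spectral_fit <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model kind, parameter count, epochs run, best
#'   epoch, best validation loss, maximum post-clip gradient norm.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(kind = x$model$kind,
                 n_params = n_parameters(x$model$params),
                 epochs = x$stopped_epoch,
                 best_epoch = x$best_epoch,
                 best_val_loss = x$model$meta$best_val_loss,
                 max_grad_norm = if (length(x$grad_norms)) max(x$grad_norms)
                   else NA_real_)
}

#' Tidy a metrics table
#'
#' @param x A `metrics_table`.
#' @param ... Unused.
#' @return The per-constituent tibble.
#' @export
tidy.metrics_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row macro summary of a metrics table
#'
#' @param x A `metrics_table`.
#' @param ... Unused.
#' @return Tibble with `avg_r2`, `avg_rmse`, `avg_mae`, `avg_nrmse`.
#' @export
glance.metrics_table <- function(x, ...) metrics_summary(x)
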