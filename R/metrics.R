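# Regression metrics in original percent units, matching the layout of the
# benchmark's comparison tables (per-task R2 / RMSE / MAE plus unweighted
# macro averages).

#' Per-task regression metrics
#'
#' `R2 = 1 - SS_res/SS_tot` on the evaluation split's own target variance,
#' RMSE and MAE per constituent. A task with zero target variance gets
#' `NA` R2 with a warning. The macro averages (`Avg_R2`, `Avg_RMSE`) are
#' unweighted means across the four tasks; because raw RMSEs live on very
#' different scales across constituents, a scale-free companion (`nrmse`,
#' RMSE divided by the target standard deviation) is reported alongside.
#'
#' @param y_true,y_pred `N x 4` matrices (`N >= 2`).
#' @return A `metrics_table` tibble with one row per constituent and
#'   attribute `summary` holding the macro averages.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("shape mismatch between y_true and y_pred", call. = FALSE)
  }
  stopifnot(nrow(y_true) >= 2)
  res <- y_pred - y_true
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(y_true, 2L, colMeans(y_true))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  if (anyNA(r2)) {
    warning("zero target variance in task(s) ",
            paste(which(is.na(r2)), collapse = ", "),
            ": R2 undefined, reported as NA", call. = FALSE)
  }
  rmse <- sqrt(colMeans(res^2))
  mae <- colMeans(abs(res))
  sdv <- sqrt(ss_tot / nrow(y_true))
  tbl <- tibble::tibble(constituent = constituent_names(),
                        r2 = unname(r2), rmse = unname(rmse),
                        mae = unname(mae),
                        nrmse = unname(ifelse(sdv > 0, rmse / sdv, NA_real_)))
  attr(tbl, "summary") <- tibble::tibble(
    avg_r2 = mean(tbl$r2), avg_rmse = mean(tbl$rmse),
    avg_mae = mean(tbl$mae), avg_nrmse = mean(tbl$nrmse))
  class(tbl) <- c("metrics_table", class(tbl))
  tbl
}

#' @rdname regression_metrics
#' @param tbl A `metrics_table`.
#' @export
metrics_summary <- function(tbl) attr(tbl, "summary")

#' Evaluate a model on a dataset
#'
#' @param model A fitted `spectral_model` or a `spectral_fit`.
#' @param ds A [spectra_dataset()].
#' @return A `metrics_table` (see [regression_metrics()]).
#' @export
evaluate_model <- function(model, ds) {
  if (inherits(model, "spectral_fit")) model <- model$model
  regression_metrics(ds$Y, predict(model, ds))
}
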