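#' Wrap a plain function as a (parameter-free) spectral model
#'
#' Useful as a deterministic reference model: perturbation importance of a
#' model that ignores its input is identically zero, and a model that
#' copies a single channel concentrates all importance on windows covering
#' that channel. Also serves as a frozen model for exercising the early
#' stopping logic, since it has no trainable parameters.
#'
#' @param fn Function mapping a numeric spectrum to a length-4 numeric
#'   vector of predictions.
#' @param grid The [wavelength_grid()] the model expects.
#' @return A `functional_model` / `spectral_model` object.
#' @examples
#' m <- functional_model(function(x) rep(mean(x), 4))
#' @export
functional_model <- function(fn, grid = wavelength_grid()) {
  stopifnot(is.function(fn))
  structure(list(kind = "functional", fn = fn, grid = grid,
                 params = list(), scaler = NULL, config = list(),
                 buffers = new.env(parent = emptyenv()),
                 meta = list(epochs_seen = 0L, best_val_loss = NA_real_)),
            class = c("functional_model", "spectral_model"))
}

#' @export
model_forward.functional_model <- function(model, X, tape, training = FALSE,
                                           collector = NULL) {
  Y <- t(apply(X, 1L, function(r) as.numeric(model$fn(r))))
  if (ncol(Y) != 4L) stop("functional model must return 4 outputs",
                          call. = FALSE)
  tp_leaf(tape, Y)
}
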