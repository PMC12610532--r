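# Wavelength-level interpretability: occlusion-style perturbation
# importance along the spectral axis, and extraction of post-softmax
# attention maps from the enhanced Transformer blocks.

#' Perturbation-based wavelength importance
#'
#' Slides a window along the spectrum, replaces the windowed channels with
#' reference values (typically the training-set per-channel mean — zeroing
#' absorbance would create out-of-distribution spectra), re-runs the
#' forward pass, and records `|y_perturbed - y_base|` per task. Each
#' channel's score is the mean over all windows covering it.
#'
#' @param model Any `spectral_model`.
#' @param x Numeric spectrum.
#' @param reference Per-channel fill values (defaults to the spectrum's
#'   mean absorbance on every channel).
#' @param window Window width in channels.
#' @param stride Window stride in channels.
#' @param normalize `"max1"` scales each task row to max 1 (all-zero rows
#'   stay zero); `"none"` keeps raw output deviations.
#' @return An `importance_profile`: tibble with columns `constituent`,
#'   `channel` (0-based), `wavelength_nm`, `score`.
#' @export
perturbation_importance <- function(model, x, reference = NULL,
                                    window = 10L, stride = 5L,
                                    normalize = c("max1", "none")) {
  normalize <- match.arg(normalize)
  nch <- length(x)
  stopifnot(window >= 1, stride >= 1)
  if (window > nch) stop("window exceeds the number of channels", call. = FALSE)
  if (is.null(reference)) reference <- rep(mean(x), nch)
  if (length(reference) != nch) {
    stop("reference must supply one fill value per channel", call. = FALSE)
  }
  base <- predict(model, matrix(x, nrow = 1L))
  starts <- seq.int(1L, nch - window + 1L, by = stride)
  if (starts[length(starts)] + window - 1L < nch) {
    starts <- c(starts, nch - window + 1L) # cover the tail
  }
  Xp <- matrix(rep(x, each = length(starts)), nrow = length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    Xp[i, idx] <- reference[idx]
  }
  Yp <- predict(model, Xp)
  dev <- abs(sweep(Yp, 2L, as.vector(base))) # windows x 4
  scores <- matrix(0, 4L, nch)
  cover <- numeric(nch)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    scores[, idx] <- scores[, idx] + dev[i, ]
    cover[idx] <- cover[idx] + 1
  }
  scores <- sweep(scores, 2L, pmax(cover, 1), `/`)
  if (normalize == "max1") {
    mx <- apply(scores, 1L, max)
    scores <- scores / ifelse(mx > 0, mx, 1)
  }
  wl <- if (nch == model$grid$n_channels) wavelengths(model$grid) else
    seq_len(nch)
  out <- tidyr::expand_grid(constituent = constituent_names(),
                            channel = seq_len(nch) - 1L) |>
    dplyr::mutate(wavelength_nm = wl[.data$channel + 1L],
                  score = as.vector(t(scores)))
  structure(out, class = c("importance_profile", class(out)),
            normalize = normalize, window = window, stride = stride)
}

#' Importance profile as a 4 x channels matrix
#'
#' @param profile An `importance_profile`.
#' @return Numeric matrix, rows named by constituent.
#' @export
importance_matrix <- function(profile) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(profile)[
    c("constituent", "channel", "score")],
    names_from = "channel", values_from = "score")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$constituent
  m[constituent_names(), , drop = FALSE]
}

#' Extract a post-softmax attention map
#'
#' Runs an evaluation-mode forward pass and captures the attention weights
#' of the requested enhanced Transformer block (for SpecTran) or encoder
#' layer (for the Transformer baseline). Rows are query positions and sum
#' to one.
#'
#' @param model A `spectran_model` or `transformer_model`.
#' @param x Numeric spectrum.
#' @param layer Block/layer index, `1 <= layer <= n_blocks`.
#' @param head Head index, or `"mean"` to average heads.
#' @return An `attention_map`: the `L x L` weight matrix with attributes
#'   `layer` and `head`.
#' @export
extract_attention <- function(model, x, layer = NULL, head = "mean") {
  n_blocks <- if (inherits(model, "spectran_model")) model$config$n_blocks
    else if (inherits(model, "transformer_model")) model$config$n_layers
    else stop("attention extraction needs an attention-based model",
              call. = FALSE)
  if (is.null(layer)) layer <- n_blocks
  if (layer < 1 || layer > n_blocks) {
    stop("layer must be in 1..", n_blocks, call. = FALSE)
  }
  collector <- new.env(parent = emptyenv())
  collector$attn <- list()
  tape <- tape_new(4096L)
  model_forward(model, matrix(x, nrow = 1L), tape, training = FALSE,
                collector = collector)
  tag <- if (inherits(model, "spectran_model")) paste0("block", layer)
    else paste0("enc", layer, "#1")
  heads <- collector$attn[[tag]]
  W <- if (identical(head, "mean")) {
    Reduce(`+`, heads) / length(heads)
  } else {
    stopifnot(head >= 1, head <= length(heads))
    heads[[head]]
  }
  structure(W, class = c("attention_map", "matrix"), layer = layer,
            head = head)
}

#' Attention rollout as a channel saliency estimator
#'
#' Averages the chosen layer's heads, takes the column mass each key patch
#' receives, and spreads each patch's mass uniformly over the channels it
#' covers. This is a *distinct* estimator from [perturbation_importance()]:
#' it reflects where attention concentrates, not output sensitivity.
#'
#' @inheritParams extract_attention
#' @return Numeric vector of per-channel saliency (length `n_channels`;
#'   channels beyond the patch coverage get zero).
#' @export
attention_saliency <- function(model, x, layer = NULL) {
  W <- extract_attention(model, x, layer = layer, head = "mean")
  L <- nrow(W)
  mass <- colMeans(unclass(W))
  k <- max(model$config$patch_kernels)
  nch <- model$grid$n_channels
  out <- numeric(nch)
  for (p in seq_len(L)) {
    idx <- ((p - 1L) * k + 1L):min(p * k, nch)
    out[idx] <- mass[p] / k
  }
  out
}

#' Map a patch index to its wavelength range
#'
#' Patch `p` (0-based, matching attention-map axis labels) covers channels
#' `[p * k_max, (p+1) * k_max)`; the range is returned in nm, half-open.
#'
#' @param p Patch index, `0 <= p < L`.
#' @param cfg A [spectran_config()].
#' @param grid A [wavelength_grid()].
#' @return Named numeric vector `c(nm_start, nm_end)`.
#' @examples
#' patch_to_wavelength(0) # 1100 1132
#' @export
patch_to_wavelength <- function(p, cfg = spectran_config(),
                                grid = wavelength_grid()) {
  L <- patch_count(cfg, grid$n_channels)
  if (p < 0 || p >= L) stop("patch index must be in 0..", L - 1, call. = FALSE)
  k <- max(cfg$patch_kernels)
  c(nm_start = grid$start_nm + grid$step_nm * p * k,
    nm_end = grid$start_nm + grid$step_nm * (p + 1) * k)
}
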