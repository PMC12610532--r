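# SpecTran: a multi-scale attention network for NIR spectral regression.
#
# Pipeline per spectrum x in R^700:
#   1. adaptive multi-scale patch embedding: parallel stride-k 1-D convs
#      with kernels {8,12,16}, branches truncated to L = min_m floor(700/k_m)
#      patches and combined with softmax-learned branch weights;
#   2. spectral positional encoding: sinusoidal encoding scaled by
#      (1 + lambda * p/(L-1));
#   3. multi-scale spectral attention: four same-padded convs (kernels
#      {3,7,15,31}) + ReLU, channel-concatenated, projected back to d_model
#      and passed through MHSA with a residual LayerNorm;
#   4. a stack of enhanced Transformer blocks: MHSA + ConvFFN
#      (conv d->4d, GELU, conv 4d->d), each sublayer residual + LayerNorm;
#   5. multi-path fusion: global (mean-pool -> MLP), local (conv ->
#      max-pool -> MLP) and sequential (BiLSTM -> mean-pool) 64-dim paths,
#      refined by self-attention over the three path tokens;
#   6. hybrid heads: four task-specific MLPs and one deeper shared MLP,
#      blended by a learnable convex weight alpha.

#' SpecTran architecture configuration
#'
#' @param patch_kernels Patch-embedding kernel/stride sizes.
#' @param d_model Shared embedding width (divisible by `n_heads`).
#' @param lambda_pe Wavelength-order emphasis of the spectral positional
#'   encoding; 0 recovers the classic sinusoidal encoding.
#' @param msa_kernels Kernels of the multi-scale spectral-attention convs.
#' @param n_blocks Number of enhanced Transformer blocks.
#' @param n_heads Attention heads per MHSA.
#' @param ffn_expansion ConvFFN expansion factor.
#' @param path_dim Width of each fusion path (fused width is `3 * path_dim`).
#' @param head_widths Hidden widths of the four task-specific heads,
#'   ordered as the constituents.
#' @param combine_alpha_init Initial value of the task/shared blending
#'   weight alpha.
#' @param combine_alpha_learnable Should alpha be learned (logistic
#'   parameterization)? If `FALSE` it stays fixed at `combine_alpha_init`.
#' @param dropout Dropout rate applied after attention and FFN sublayers
#'   during training.
#' @return A `spectran_config` object.
#' @export
spectran_config <- function(patch_kernels = c(8L, 12L, 16L),
                            d_model = 128L,
                            lambda_pe = 0.1,
                            msa_kernels = c(3L, 7L, 15L, 31L),
                            n_blocks = 6L,
                            n_heads = 4L,
                            ffn_expansion = 4L,
                            path_dim = 64L,
                            head_widths = c(64L, 64L, 96L, 128L),
                            combine_alpha_init = 0.5,
                            combine_alpha_learnable = TRUE,
                            dropout = 0.1) {
  stopifnot(d_model %% n_heads == 0, d_model %% 2 == 0,
            all(patch_kernels > 0), all(msa_kernels > 0),
            length(head_widths) == 4L, path_dim %% 2 == 0,
            combine_alpha_init > 0, combine_alpha_init < 1 ||
              !combine_alpha_learnable)
  structure(list(patch_kernels = as.integer(patch_kernels),
                 d_model = as.integer(d_model), lambda_pe = lambda_pe,
                 msa_kernels = as.integer(msa_kernels),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 ffn_expansion = as.integer(ffn_expansion),
                 path_dim = as.integer(path_dim),
                 head_widths = as.integer(head_widths),
                 combine_alpha_init = combine_alpha_init,
                 combine_alpha_learnable = combine_alpha_learnable,
                 dropout = dropout, n_outputs = 4L),
            class = "spectran_config")
}

# Patch count after truncation to the shortest branch.
patch_count <- function(cfg, n_channels) {
  min(n_channels %/% cfg$patch_kernels)
}

#' Build an untrained SpecTran model
#'
#' @param cfg A [spectran_config()].
#' @param grid The [wavelength_grid()] the model expects.
#' @param seed Seed for parameter initialization.
#' @return A `spectran_model` (also `spectral_model`) object.
#' @export
spectran_model <- function(cfg = spectran_config(), grid = wavelength_grid(),
                           seed = 1L) {
  stopifnot(inherits(cfg, "spectran_config"))
  if (grid$n_channels < max(cfg$patch_kernels)) {
    stop("grid has fewer channels than the largest patch kernel", call. = FALSE)
  }
  d <- cfg$d_model; P <- cfg$path_dim
  params <- withr::with_seed(seed, {
    g <- list()
    for (m in seq_along(cfg$patch_kernels)) {
      g[[paste0("pe", m)]] <- init_conv(cfg$patch_kernels[m], 1L, d)
    }
    g$pefuse <- list(w = zeros(1L, length(cfg$patch_kernels)))
    for (s in seq_along(cfg$msa_kernels)) {
      g[[paste0("ms", s)]] <- init_conv(cfg$msa_kernels[s], d, d)
    }
    g$msproj <- init_linear(length(cfg$msa_kernels) * d, d)
    g$msattn <- init_mhsa(d)
    g$msln <- init_layernorm(d)
    for (i in seq_len(cfg$n_blocks)) {
      pre <- paste0("blk", i)
      g[[paste0(pre, "attn")]] <- init_mhsa(d)
      g[[paste0(pre, "ln1")]] <- init_layernorm(d)
      g[[paste0(pre, "ffn1")]] <- init_conv(3L, d, cfg$ffn_expansion * d)
      g[[paste0(pre, "ffn2")]] <- init_conv(1L, cfg$ffn_expansion * d, d)
      g[[paste0(pre, "ln2")]] <- init_layernorm(d)
    }
    g$fg1 <- init_linear(d, P); g$fg2 <- init_linear(P, P)
    g$lc <- init_conv(3L, d, d)
    g$fl1 <- init_linear(d, P); g$fl2 <- init_linear(P, P)
    g$lstmf <- init_lstm(d, P %/% 2L)
    g$lstmb <- init_lstm(d, P %/% 2L)
    g$fa <- init_mhsa(P)
    for (j in seq_len(4L)) {
      g[[paste0("th", j, "1")]] <- init_linear(3L * P, cfg$head_widths[j])
      g[[paste0("th", j, "2")]] <- init_linear(cfg$head_widths[j], 1L)
    }
    g$sh1 <- init_linear(3L * P, 128L)
    g$sh2 <- init_linear(128L, 64L)
    g$sh3 <- init_linear(64L, 4L)
    if (cfg$combine_alpha_learnable) {
      a0 <- log(cfg$combine_alpha_init / (1 - cfg$combine_alpha_init))
      g$alpha <- list(raw = matrix(a0))
    }
    flatten_params(g)
  })
  structure(list(kind = "spectran", config = cfg, grid = grid,
                 params = params, scaler = NULL,
                 buffers = new.env(parent = emptyenv()),
                 meta = list(epochs_seen = 0L, best_val_loss = NA_real_)),
            class = c("spectran_model", "spectral_model"))
}

#' Spectral positional encoding
#'
#' Sinusoidal positional encoding with a wavelength-order emphasis: row `p`
#' (0-based) of the classic encoding is scaled by `1 + lambda * p/(L-1)`,
#' so later patches — longer wavelengths — carry a slightly stronger
#' positional signal. `lambda = 0` reproduces the classic encoding exactly.
#'
#' @param L Sequence length (patches). For `L = 1` the scale is defined as
#'   1 (with a warning), since `p/(L-1)` is undefined.
#' @param d_model Embedding width (even).
#' @param lambda_pe Emphasis strength.
#' @return An `L x d_model` matrix.
#' @export
spectral_positional_encoding <- function(L, d_model, lambda_pe = 0.1) {
  stopifnot(L >= 1, d_model >= 2)
  p <- seq_len(L) - 1
  scale <- if (L == 1L) {
    warning("L = 1: positional scale phi(p) undefined, using 1", call. = FALSE)
    rep(1, L)
  } else {
    1 + lambda_pe * p / (L - 1)
  }
  half <- ceiling(d_model / 2)
  i <- seq_len(half) - 1
  ang <- outer(p, 1 / 10000^(2 * i / d_model))
  PE <- matrix(0, L, 2L * half)
  PE[, 2 * i + 1] <- sin(ang)
  PE[, 2 * i + 2] <- cos(ang)
  (PE * scale)[, seq_len(d_model), drop = FALSE]
}

## ---- forward pass ----------------------------------------------------------

# Build the full forward computation for one spectrum on `tape`.
# Returns node ids of the named stages. `pn` (named list of parameter leaf
# ids) is created when absent; batched callers create it once so that the
# parameter leaves occupy the first nodes of a fresh tape (the training
# loop relies on this to read gradients back).
st_forward_one <- function(model, x, tape, training = FALSE,
                           collector = NULL, pn = NULL) {
  cfg <- model$config
  if (is.null(pn)) pn <- param_leaves(tape, model$params)
  d <- cfg$d_model
  nch <- length(x)
  xin <- tp_leaf(tape, matrix(x, ncol = 1L))

  # 1. multi-scale patch embedding
  L <- patch_count(cfg, nch)
  aw <- tp_softmax_rows(tape, pn[["pefuse.w"]])
  z <- NULL
  for (m in seq_along(cfg$patch_kernels)) {
    k <- cfg$patch_kernels[m]
    br <- tp_conv1d(tape, xin, pn[[paste0("pe", m, ".W")]],
                    pn[[paste0("pe", m, ".b")]], k, stride = k)
    br <- tp_rows(tape, br, seq_len(L))
    br <- tp_mul_scalar(tape, br, tp_cols(tape, aw, m))
    z <- if (is.null(z)) br else tp_add(tape, z, br)
  }
  z_embed <- z

  # 2. spectral positional encoding
  pe <- tp_leaf(tape, spectral_positional_encoding(L, d, cfg$lambda_pe))
  z <- tp_add(tape, z, pe)

  # 3. multi-scale spectral attention
  hs <- integer(length(cfg$msa_kernels))
  for (s in seq_along(cfg$msa_kernels)) {
    k <- cfg$msa_kernels[s]
    h <- tp_conv1d(tape, z, pn[[paste0("ms", s, ".W")]],
                   pn[[paste0("ms", s, ".b")]], k, pad = conv_same_pad(k))
    hs[s] <- tp_relu(tape, h)
  }
  hcat <- tp_linear(tape, tp_cbind(tape, hs), pn, "msproj")
  att <- tp_mhsa(tape, hcat, pn, "msattn", cfg$n_heads, collector, "msattn")
  att <- tp_dropout(tape, att, cfg$dropout, training)
  z <- tp_layernorm(tape, tp_add(tape, z, att), pn[["msln.gamma"]],
                    pn[["msln.beta"]])

  # 4. enhanced Transformer blocks
  for (i in seq_len(cfg$n_blocks)) {
    pre <- paste0("blk", i)
    a <- tp_mhsa(tape, z, pn, paste0(pre, "attn"), cfg$n_heads,
                 collector, paste0("block", i))
    a <- tp_dropout(tape, a, cfg$dropout, training)
    a <- tp_layernorm(tape, tp_add(tape, z, a),
                      pn[[paste0(pre, "ln1.gamma")]],
                      pn[[paste0(pre, "ln1.beta")]])
    f <- tp_conv1d(tape, a, pn[[paste0(pre, "ffn1.W")]],
                   pn[[paste0(pre, "ffn1.b")]], 3L, pad = conv_same_pad(3L))
    f <- tp_gelu(tape, f)
    f <- tp_conv1d(tape, f, pn[[paste0(pre, "ffn2.W")]],
                   pn[[paste0(pre, "ffn2.b")]], 1L)
    f <- tp_dropout(tape, f, cfg$dropout, training)
    z <- tp_layernorm(tape, tp_add(tape, a, f),
                      pn[[paste0(pre, "ln2.gamma")]],
                      pn[[paste0(pre, "ln2.beta")]])
  }
  b_out <- z

  # 5. multi-path fusion
  fg <- tp_mlp2(tape, tp_mean_rows(tape, z), pn, "fg")
  lc <- tp_conv1d(tape, z, pn[["lc.W"]], pn[["lc.b"]], 3L,
                  pad = conv_same_pad(3L))
  fl <- tp_mlp2(tape, tp_max_rows(tape, lc), pn, "fl")
  hf <- tp_lstm(tape, z, pn[["lstmf.Wx"]], pn[["lstmf.Wh"]], pn[["lstmf.b"]])
  hb <- tp_lstm(tape, z, pn[["lstmb.Wx"]], pn[["lstmb.Wh"]], pn[["lstmb.b"]],
                reverse = TRUE)
  fs <- tp_mean_rows(tape, tp_cbind(tape, c(hf, hb)))
  tokens <- tp_rbind(tape, c(fg, fl, fs))
  fused_tok <- tp_mhsa(tape, tokens, pn, "fa", 1L, collector, "fusion")
  f_fused <- tp_cbind(tape, c(tp_rows(tape, fused_tok, 1L),
                              tp_rows(tape, fused_tok, 2L),
                              tp_rows(tape, fused_tok, 3L)))

  # 6. hybrid prediction heads
  tasks <- integer(4L)
  for (j in seq_len(4L)) {
    tasks[j] <- tp_mlp2(tape, f_fused, pn, paste0("th", j))
  }
  y_task <- tp_cbind(tape, tasks)
  sh <- tp_relu(tape, tp_linear(tape, f_fused, pn, "sh1"))
  sh <- tp_relu(tape, tp_linear(tape, sh, pn, "sh2"))
  y_shared <- tp_linear(tape, sh, pn, "sh3")
  if (model$config$combine_alpha_learnable) {
    alpha <- tp_sigmoid(tape, pn[["alpha.raw"]])
    y <- tp_add(tape, tp_mul_scalar(tape, y_task, alpha),
                tp_mul_scalar(tape, tp_scale(tape, y_shared, -1),
                              alpha))
    y <- tp_add(tape, y, y_shared) # a*t + s - a*s = a*t + (1-a)*s
  } else {
    a0 <- model$config$combine_alpha_init
    y <- tp_add(tape, tp_scale(tape, y_task, a0),
                tp_scale(tape, y_shared, 1 - a0))
  }
  list(y = y, y_task = y_task, y_shared = y_shared, f_fused = f_fused,
       fg = fg, fl = fl, fs = fs, b = b_out, z_embed = z_embed,
       fusion_weights = aw, pn = pn, L = L)
}

# Batched forward used by the training loop: returns the node id of the
# N x 4 stacked (standardized-scale) predictions.
model_forward <- function(model, X, tape, training = FALSE,
                          collector = NULL) {
  UseMethod("model_forward")
}

#' @export
model_forward.spectran_model <- function(model, X, tape, training = FALSE,
                                         collector = NULL) {
  pn <- param_leaves(tape, model$params)
  rows <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    rows[i] <- st_forward_one(model, X[i, ], tape, training, collector, pn)$y
  }
  if (length(rows) == 1L) rows[1L] else tp_rbind(tape, rows)
}

check_channels <- function(model, X) {
  if (ncol(X) != model$grid$n_channels) {
    stop("input has ", ncol(X), " channels but the model expects ",
         model$grid$n_channels, call. = FALSE)
  }
}

# Apply the model's per-channel input scaler (set during training).
scale_inputs <- function(model, X) {
  if (is.null(model$x_scaler)) return(X)
  sweep(sweep(X, 2L, model$x_scaler$mean, `-`), 2L, model$x_scaler$sd, `/`)
}

as_input_matrix <- function(newdata) {
  if (inherits(newdata, "spectra_dataset")) newdata$X
  else if (is.matrix(newdata)) newdata
  else matrix(newdata, nrow = 1L)
}

#' Predict constituent concentrations
#'
#' Evaluation-mode forward pass (dropout off, deterministic). Predictions
#' are returned in original percent units: models trained with target
#' standardization de-standardize internally.
#'
#' @param object A fitted or freshly built model.
#' @param newdata A [spectra_dataset()], a numeric matrix (one spectrum per
#'   row) or a single spectrum vector.
#' @param ... Unused.
#' @return An `N x 4` matrix with constituent columns.
#' @export
predict.spectral_model <- function(object, newdata, ...) {
  X <- as_input_matrix(newdata)
  check_channels(object, X)
  X <- scale_inputs(object, X)
  tape <- tape_new(4096L)
  yid <- model_forward(object, X, tape, training = FALSE)
  Y <- tp_value(tape, yid)
  if (!is.null(object$scaler)) {
    Y <- sweep(sweep(Y, 2L, object$scaler$sd, `*`), 2L, object$scaler$mean, `+`)
  }
  colnames(Y) <- constituent_names()
  rownames(Y) <- if (inherits(newdata, "spectra_dataset")) newdata$sample_ids
  Y
}

#' @export
print.spectran_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<spectran_model> d_model %d, %d blocks, %d heads, ",
                     "%d params%s\n"),
              cfg$d_model, cfg$n_blocks, cfg$n_heads,
              n_parameters(x$params),
              if (is.na(x$meta$best_val_loss)) " (untrained)" else
                sprintf(", best val loss %.4g", x$meta$best_val_loss)))
  invisible(x)
}

## ---- inspectable stage wrappers -------------------------------------------

#' Multi-scale patch embedding of one spectrum
#'
#' @param x Numeric spectrum of length `n_channels`.
#' @param model A [spectran_model()].
#' @return List with the `L x d_model` embedded sequence `values`, the
#'   patch count `L` and the softmax branch `fusion_weights` (sum to 1).
#' @export
patch_embed <- function(x, model) {
  cfg <- model$config
  if (length(x) < max(cfg$patch_kernels)) {
    stop("spectrum shorter than the largest patch kernel", call. = FALSE)
  }
  tape <- tape_new()
  st <- st_forward_one(model, x, tape)
  list(values = tp_value(tape, st$z_embed), L = st$L,
       fusion_weights = as.vector(tp_value(tape, st$fusion_weights)))
}

#' Multi-scale spectral attention applied to an embedded sequence
#'
#' @param z An `L x d_model` matrix.
#' @param model A [spectran_model()].
#' @return An `L x d_model` matrix (shape preserved).
#' @export
multi_scale_spectral_attention <- function(z, model) {
  cfg <- model$config
  tape <- tape_new()
  pn <- param_leaves(tape, model$params)
  zi <- tp_leaf(tape, z)
  hs <- integer(length(cfg$msa_kernels))
  for (s in seq_along(cfg$msa_kernels)) {
    k <- cfg$msa_kernels[s]
    h <- tp_conv1d(tape, zi, pn[[paste0("ms", s, ".W")]],
                   pn[[paste0("ms", s, ".b")]], k, pad = conv_same_pad(k))
    hs[s] <- tp_relu(tape, h)
  }
  hcat <- tp_linear(tape, tp_cbind(tape, hs), pn, "msproj")
  att <- tp_mhsa(tape, hcat, pn, "msattn", cfg$n_heads)
  out <- tp_layernorm(tape, tp_add(tape, zi, att), pn[["msln.gamma"]],
                      pn[["msln.beta"]])
  tp_value(tape, out)
}

#' One enhanced Transformer block
#'
#' @param a An `L x d_model` matrix.
#' @param model A [spectran_model()].
#' @param block Block index in `1:n_blocks`.
#' @return An `L x d_model` matrix.
#' @export
enhanced_block <- function(a, model, block = 1L) {
  cfg <- model$config
  stopifnot(block >= 1, block <= cfg$n_blocks)
  tape <- tape_new()
  pn <- param_leaves(tape, model$params)
  zi <- tp_leaf(tape, a)
  pre <- paste0("blk", block)
  at <- tp_mhsa(tape, zi, pn, paste0(pre, "attn"), cfg$n_heads)
  aa <- tp_layernorm(tape, tp_add(tape, zi, at),
                     pn[[paste0(pre, "ln1.gamma")]],
                     pn[[paste0(pre, "ln1.beta")]])
  f <- tp_conv1d(tape, aa, pn[[paste0(pre, "ffn1.W")]],
                 pn[[paste0(pre, "ffn1.b")]], 3L, pad = conv_same_pad(3L))
  f <- tp_gelu(tape, f)
  f <- tp_conv1d(tape, f, pn[[paste0(pre, "ffn2.W")]],
                 pn[[paste0(pre, "ffn2.b")]], 1L)
  out <- tp_layernorm(tape, tp_add(tape, aa, f),
                      pn[[paste0(pre, "ln2.gamma")]],
                      pn[[paste0(pre, "ln2.beta")]])
  tp_value(tape, out)
}

#' Multi-path feature fusion
#'
#' @param b An `L x d_model` matrix (block-stack output).
#' @param model A [spectran_model()].
#' @return List with `f_global`, `f_local`, `f_sequential` (length
#'   `path_dim` each) and `f_fused` (length `3 * path_dim`).
#' @export
multi_path_fusion <- function(b, model) {
  tape <- tape_new()
  pn <- param_leaves(tape, model$params)
  zi <- tp_leaf(tape, b)
  fg <- tp_mlp2(tape, tp_mean_rows(tape, zi), pn, "fg")
  lc <- tp_conv1d(tape, zi, pn[["lc.W"]], pn[["lc.b"]], 3L,
                  pad = conv_same_pad(3L))
  fl <- tp_mlp2(tape, tp_max_rows(tape, lc), pn, "fl")
  hf <- tp_lstm(tape, zi, pn[["lstmf.Wx"]], pn[["lstmf.Wh"]], pn[["lstmf.b"]])
  hb <- tp_lstm(tape, zi, pn[["lstmb.Wx"]], pn[["lstmb.Wh"]], pn[["lstmb.b"]],
                reverse = TRUE)
  fs <- tp_mean_rows(tape, tp_cbind(tape, c(hf, hb)))
  tokens <- tp_rbind(tape, c(fg, fl, fs))
  fused_tok <- tp_mhsa(tape, tokens, pn, "fa", 1L)
  ft <- tp_value(tape, fused_tok)
  list(f_global = as.vector(tp_value(tape, fg)),
       f_local = as.vector(tp_value(tape, fl)),
       f_sequential = as.vector(tp_value(tape, fs)),
       f_fused = as.vector(t(ft)))
}

#' Hybrid prediction heads
#'
#' Blends four task-specific MLP outputs with a deeper shared predictor:
#' `y = alpha * y_task + (1 - alpha) * y_shared`.
#'
#' @param f Fused feature vector of length `3 * path_dim`, or the list
#'   returned by [multi_path_fusion()].
#' @param model A [spectran_model()].
#' @param alpha Optional override of the blending weight in `[0, 1]`.
#' @return List with `y`, `y_task`, `y_shared` (length-4 vectors) and the
#'   `alpha` used.
#' @export
predict_heads <- function(f, model, alpha = NULL) {
  if (is.list(f)) f <- f$f_fused
  tape <- tape_new()
  pn <- param_leaves(tape, model$params)
  fi <- tp_leaf(tape, matrix(f, nrow = 1L))
  tasks <- integer(4L)
  for (j in seq_len(4L)) tasks[j] <- tp_mlp2(tape, fi, pn, paste0("th", j))
  y_task <- as.vector(tp_value(tape, tp_cbind(tape, tasks)))
  sh <- tp_relu(tape, tp_linear(tape, fi, pn, "sh1"))
  sh <- tp_relu(tape, tp_linear(tape, sh, pn, "sh2"))
  y_shared <- as.vector(tp_value(tape, tp_linear(tape, sh, pn, "sh3")))
  if (is.null(alpha)) {
    alpha <- if (model$config$combine_alpha_learnable) {
      stats::plogis(model$params[["alpha.raw"]][1L, 1L])
    } else {
      model$config$combine_alpha_init
    }
  }
  stopifnot(alpha >= 0, alpha <= 1)
  list(y = alpha * y_task + (1 - alpha) * y_shared,
       y_task = y_task, y_shared = y_shared, alpha = alpha)
}

## ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, parameters, target scaler,
#' normalization buffers and a config hash that is validated on load; a
#' round-trip reproduces forward outputs bit for bit.
#'
#' @param model A `spectral_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  ck <- list(kind = model$kind, config = model$config, grid = model$grid,
             params = model$params, scaler = model$scaler,
             x_scaler = model$x_scaler,
             buffers = as.list(model$buffers), meta = model$meta,
             class = class(model),
             config_hash = rlang::hash(list(model$kind, model$config)))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$config_hash, rlang::hash(list(ck$kind, ck$config)))) {
    stop("checkpoint config hash mismatch: file corrupted or incompatible",
         call. = FALSE)
  }
  buffers <- new.env(parent = emptyenv())
  for (nm in names(ck$buffers)) buffers[[nm]] <- ck$buffers[[nm]]
  structure(list(kind = ck$kind, config = ck$config, grid = ck$grid,
                 params = ck$params, scaler = ck$scaler,
                 x_scaler = ck$x_scaler, buffers = buffers,
                 meta = ck$meta),
            class = ck$class)
}
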