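# Four neural baselines sharing the training stack: an MLP and a CNN on
# the raw 700-channel spectrum, and a Transformer encoder and an
# LSTM-attention hybrid (LSTTN) on a patch-projected token sequence.

#' Baseline model configuration
#'
#' @param kind One of `"mlp"`, `"cnn"`, `"transformer"`, `"lsttn"`.
#' @param hidden_widths MLP hidden layer widths.
#' @param filters,kernels CNN conv-block filter counts and kernel sizes
#'   (equal length); each block is conv + batch norm + ReLU + max-pool 2.
#' @param dense_width CNN dense hidden width.
#' @param patch_size Token size for the sequence baselines.
#' @param d_model,n_heads,n_layers Transformer encoder dimensions.
#' @param lstm_hidden,lstm_layers LSTTN stacked-LSTM dimensions.
#' @param dropout Dropout rate (sequence baselines).
#' @return A `baseline_config` object.
#' @export
baseline_config <- function(kind = c("mlp", "cnn", "transformer", "lsttn"),
                            hidden_widths = c(256L, 128L, 64L),
                            filters = c(32L, 64L, 64L),
                            kernels = c(3L, 5L, 7L),
                            dense_width = 128L,
                            patch_size = 16L,
                            d_model = 128L,
                            n_heads = 4L,
                            n_layers = 4L,
                            lstm_hidden = 64L,
                            lstm_layers = 2L,
                            dropout = 0.1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown baseline kind: ",
                                            kind[1L], call. = FALSE))
  stopifnot(length(filters) == length(kernels), d_model %% n_heads == 0)
  structure(list(kind = kind, hidden_widths = as.integer(hidden_widths),
                 filters = as.integer(filters), kernels = as.integer(kernels),
                 dense_width = as.integer(dense_width),
                 patch_size = as.integer(patch_size),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 dropout = dropout, n_outputs = 4L),
            class = "baseline_config")
}

#' Build an untrained baseline model
#'
#' @param cfg A [baseline_config()].
#' @param grid The [wavelength_grid()] the model expects.
#' @param seed Seed for parameter initialization.
#' @return A `spectral_model` whose class includes `"<kind>_model"`.
#' @export
build_baseline <- function(cfg, grid = wavelength_grid(), seed = 1L) {
  stopifnot(inherits(cfg, "baseline_config"))
  nch <- grid$n_channels
  params <- withr::with_seed(seed, {
    g <- list()
    if (cfg$kind == "mlp") {
      widths <- c(nch, cfg$hidden_widths, 4L)
      for (l in seq_len(length(widths) - 1L)) {
        g[[paste0("fc", l)]] <- init_linear(widths[l], widths[l + 1L])
      }
    } else if (cfg$kind == "cnn") {
      c_in <- 1L
      L <- nch
      for (bkl in seq_along(cfg$filters)) {
        g[[paste0("conv", bkl)]] <- init_conv(cfg$kernels[bkl], c_in,
                                              cfg$filters[bkl])
        g[[paste0("bn", bkl)]] <- init_layernorm(cfg$filters[bkl])
        c_in <- cfg$filters[bkl]
        L <- L %/% 2L # same-padded conv then max-pool 2
      }
      g$dense1 <- init_linear(L * c_in, cfg$dense_width)
      g$dense2 <- init_linear(cfg$dense_width, 4L)
    } else if (cfg$kind == "transformer") {
      g$embed <- init_linear(cfg$patch_size, cfg$d_model)
      for (l in seq_len(cfg$n_layers)) {
        pre <- paste0("enc", l)
        g[[paste0(pre, "attn")]] <- init_mhsa(cfg$d_model)
        g[[paste0(pre, "ln1")]] <- init_layernorm(cfg$d_model)
        g[[paste0(pre, "ffn1")]] <- init_linear(cfg$d_model, 4L * cfg$d_model)
        g[[paste0(pre, "ffn2")]] <- init_linear(4L * cfg$d_model, cfg$d_model)
        g[[paste0(pre, "ln2")]] <- init_layernorm(cfg$d_model)
      }
      g$head1 <- init_linear(cfg$d_model, 64L)
      g$head2 <- init_linear(64L, 4L)
    } else { # lsttn
      g$embed <- init_linear(cfg$patch_size, cfg$d_model)
      c_in <- cfg$d_model
      for (l in seq_len(cfg$lstm_layers)) {
        g[[paste0("lstm", l)]] <- init_lstm(c_in, cfg$lstm_hidden)
        c_in <- cfg$lstm_hidden
      }
      for (j in seq_len(4L)) {
        g[[paste0("head", j, "1")]] <- init_linear(cfg$lstm_hidden, 32L)
        g[[paste0("head", j, "2")]] <- init_linear(32L, 1L)
      }
    }
    flatten_params(g)
  })
  structure(list(kind = cfg$kind, config = cfg, grid = grid, params = params,
                 scaler = NULL, buffers = new.env(parent = emptyenv()),
                 meta = list(epochs_seen = 0L, best_val_loss = NA_real_)),
            class = c(paste0(cfg$kind, "_model"), "spectral_model"))
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<%s_model> %d params%s\n", x$kind, n_parameters(x$params),
              if (is.na(x$meta$best_val_loss)) " (untrained)" else
                sprintf(", best val loss %.4g", x$meta$best_val_loss)))
  invisible(x)
}

# Non-overlapping patchification of a batch: N x nch -> (N*L) x patch_size.
patchify <- function(X, patch_size) {
  L <- ncol(X) %/% patch_size
  N <- nrow(X)
  out <- matrix(0, N * L, patch_size)
  for (p in seq_len(L)) {
    cols <- ((p - 1L) * patch_size + 1L):(p * patch_size)
    out[(seq_len(N) - 1L) * L + p, ] <- X[, cols, drop = FALSE]
  }
  out
}

#' @export
model_forward.mlp_model <- function(model, X, tape, training = FALSE,
                                    collector = NULL) {
  pn <- param_leaves(tape, model$params)
  h <- tp_leaf(tape, X)
  n_fc <- length(model$config$hidden_widths) + 1L
  for (l in seq_len(n_fc)) {
    h <- tp_linear(tape, h, pn, paste0("fc", l))
    if (l < n_fc) h <- tp_relu(tape, h)
  }
  h
}

#' @export
model_forward.cnn_model <- function(model, X, tape, training = FALSE,
                                    collector = NULL) {
  cfg <- model$config
  pn <- param_leaves(tape, model$params)
  N <- nrow(X)
  h <- tp_leaf(tape, matrix(as.vector(t(X)), ncol = 1L)) # (N*nch) x 1
  L <- ncol(X)
  for (bkl in seq_along(cfg$filters)) {
    k <- cfg$kernels[bkl]
    h <- tp_conv1d(tape, h, pn[[paste0("conv", bkl, ".W")]],
                   pn[[paste0("conv", bkl, ".b")]], k,
                   pad = conv_same_pad(k), n_seq = N)
    h <- tp_batchnorm(tape, h, pn[[paste0("bn", bkl, ".gamma")]],
                      pn[[paste0("bn", bkl, ".beta")]], model$buffers,
                      paste0("bn", bkl), training)
    h <- tp_relu(tape, h)
    h <- tp_maxpool1d(tape, h, 2L, n_seq = N)
    L <- L %/% 2L
  }
  h <- tp_flatten_seq(tape, h, N)
  h <- tp_relu(tape, tp_linear(tape, h, pn, "dense1"))
  tp_linear(tape, h, pn, "dense2")
}

transformer_forward_one <- function(model, x, tape, pn, training, collector,
                                    sample_tag = "") {
  cfg <- model$config
  P <- patchify(matrix(x, nrow = 1L), cfg$patch_size)
  h <- tp_linear(tape, tp_leaf(tape, P), pn, "embed")
  pe <- tp_leaf(tape, spectral_positional_encoding(nrow(P), cfg$d_model, 0))
  h <- tp_add(tape, h, pe)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("enc", l)
    a <- tp_mhsa(tape, h, pn, paste0(pre, "attn"), cfg$n_heads, collector,
                 paste0("enc", l, sample_tag))
    a <- tp_dropout(tape, a, cfg$dropout, training)
    h <- tp_layernorm(tape, tp_add(tape, h, a),
                      pn[[paste0(pre, "ln1.gamma")]],
                      pn[[paste0(pre, "ln1.beta")]])
    f <- tp_relu(tape, tp_linear(tape, h, pn, paste0(pre, "ffn1")))
    f <- tp_linear(tape, f, pn, paste0(pre, "ffn2"))
    f <- tp_dropout(tape, f, cfg$dropout, training)
    h <- tp_layernorm(tape, tp_add(tape, h, f),
                      pn[[paste0(pre, "ln2.gamma")]],
                      pn[[paste0(pre, "ln2.beta")]])
  }
  h <- tp_mean_rows(tape, h)
  h <- tp_relu(tape, tp_linear(tape, h, pn, "head1"))
  tp_linear(tape, h, pn, "head2")
}

#' @export
model_forward.transformer_model <- function(model, X, tape, training = FALSE,
                                            collector = NULL) {
  pn <- param_leaves(tape, model$params)
  rows <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    rows[i] <- transformer_forward_one(model, X[i, ], tape, pn, training,
                                       collector, paste0("#", i))
  }
  if (length(rows) == 1L) rows[1L] else tp_rbind(tape, rows)
}

lsttn_forward_one <- function(model, x, tape, pn, training, collector,
                              sample_tag = "") {
  cfg <- model$config
  P <- patchify(matrix(x, nrow = 1L), cfg$patch_size)
  h <- tp_linear(tape, tp_leaf(tape, P), pn, "embed")
  for (l in seq_len(cfg$lstm_layers)) {
    h <- tp_lstm(tape, h, pn[[paste0("lstm", l, ".Wx")]],
                 pn[[paste0("lstm", l, ".Wh")]], pn[[paste0("lstm", l, ".b")]])
  }
  # dot-product attention Softmax(H H^T / sqrt(d)) H over the LSTM output
  sc <- tp_scale(tape, tp_matmul(tape, h, tp_transpose(tape, h)),
                 1 / sqrt(ncol(tp_value(tape, h))))
  at <- tp_softmax_rows(tape, sc)
  if (!is.null(collector)) {
    collector$attn[[paste0("lsttn", sample_tag)]] <- list(tp_value(tape, at))
  }
  h <- tp_mean_rows(tape, tp_matmul(tape, at, h))
  outs <- integer(4L)
  for (j in seq_len(4L)) outs[j] <- tp_mlp2(tape, h, pn, paste0("head", j))
  tp_cbind(tape, outs)
}

#' @export
model_forward.lsttn_model <- function(model, X, tape, training = FALSE,
                                      collector = NULL) {
  pn <- param_leaves(tape, model$params)
  rows <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    rows[i] <- lsttn_forward_one(model, X[i, ], tape, pn, training,
                                 collector, paste0("#", i))
  }
  if (length(rows) == 1L) rows[1L] else tp_rbind(tape, rows)
}

#' Dot-product attention over an LSTM output sequence
#'
#' Computes `Softmax(H H^T / sqrt(d)) H` with row-wise softmax — the
#' attention reweighting of the LSTM-Transformer hybrid.
#'
#' @param H A `T x d` matrix of hidden states.
#' @return A `T x d` matrix.
#' @examples
#' lsttn_attention(matrix(1:4 / 4, 2)) # rows are convex mixes of H's rows
#' @export
lsttn_attention <- function(H) {
  H <- as.matrix(H)
  S <- H %*% t(H) / sqrt(ncol(H))
  S <- S - apply(S, 1L, max)
  W <- exp(S) / rowSums(exp(S))
  W %*% H
}
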