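# Parameter initialization and composite layers shared by SpecTran and the
# baselines. A model's parameters live in a named list of matrices; at the
# start of each forward pass every parameter becomes a tape leaf so its
# gradient can be read back after the reverse sweep.

glorot <- function(n_in, n_out, nrow = n_in, ncol = n_out) {
  sd <- sqrt(2 / (n_in + n_out))
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

zeros <- function(nrow, ncol) matrix(0, nrow, ncol)

# Push all parameters of `params` onto the tape, returning a named list of
# node ids.
param_leaves <- function(tape, params) {
  lapply(params, function(p) tp_leaf(tape, p))
}

init_linear <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out), b = zeros(1L, n_out))
}

# Conv kernel stored as (k * c_in) x c_out so the conv op is block matmuls.
init_conv <- function(k, c_in, c_out) {
  list(W = glorot(k * c_in, c_out), b = zeros(1L, c_out))
}

init_layernorm <- function(d) {
  list(gamma = matrix(1, 1L, d), beta = zeros(1L, d))
}

init_mhsa <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d),
       Wv = glorot(d, d), Wo = glorot(d, d))
}

init_lstm <- function(c_in, h) {
  list(Wx = glorot(c_in, 4L * h, c_in, 4L * h),
       Wh = glorot(h, 4L * h, h, 4L * h),
       b = zeros(1L, 4L * h))
}

tp_linear <- function(tape, x, pn, prefix) {
  tp_add_rowvec(tape, tp_matmul(tape, x, pn[[paste0(prefix, ".W")]]),
                pn[[paste0(prefix, ".b")]])
}

# Multi-head self-attention over an L x d sequence. Returns the output node;
# the post-softmax per-head attention matrices (values) are appended to
# `collector$attn[[tag]]` when a collector environment is supplied.
tp_mhsa <- function(tape, x, pn, prefix, n_heads, collector = NULL,
                    tag = NULL) {
  q <- tp_matmul(tape, x, pn[[paste0(prefix, ".Wq")]])
  k <- tp_matmul(tape, x, pn[[paste0(prefix, ".Wk")]])
  v <- tp_matmul(tape, x, pn[[paste0(prefix, ".Wv")]])
  d <- ncol(tp_value(tape, q))
  dh <- d %/% n_heads
  outs <- integer(n_heads)
  heads_attn <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- tp_cols(tape, q, idx)
    kh <- tp_cols(tape, k, idx)
    vh <- tp_cols(tape, v, idx)
    sc <- tp_scale(tape, tp_matmul(tape, qh, tp_transpose(tape, kh)),
                   1 / sqrt(dh))
    at <- tp_softmax_rows(tape, sc)
    heads_attn[[h]] <- tp_value(tape, at)
    outs[h] <- tp_matmul(tape, at, vh)
  }
  if (!is.null(collector) && !is.null(tag)) {
    collector$attn[[tag]] <- heads_attn
  }
  tp_matmul(tape, tp_cbind(tape, outs), pn[[paste0(prefix, ".Wo")]])
}

# Two-layer perceptron head: linear -> ReLU -> linear.
tp_mlp2 <- function(tape, x, pn, prefix) {
  h <- tp_relu(tape, tp_linear(tape, x, pn, paste0(prefix, "1")))
  tp_linear(tape, h, pn, paste0(prefix, "2"))
}

# Flatten a nested list of layer params into "name.part" entries.
flatten_params <- function(groups) {
  out <- list()
  for (nm in names(groups)) {
    g <- groups[[nm]]
    for (p in names(g)) out[[paste0(nm, ".", p)]] <- g[[p]]
  }
  out
}

n_parameters <- function(params) sum(vapply(params, length, 1L))
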