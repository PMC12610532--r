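# Reverse-mode automatic differentiation on matrices.
#
# Every value on the tape is a base-R numeric matrix. A node records its
# value, its parent node ids, and a backward closure mapping the incoming
# gradient to a list of parent gradients. Networks are expressed as
# compositions of the `tp_*` ops below; `tape_backward()` runs the reverse
# sweep. Values are computed eagerly, so a forward pass is just building
# the tape and reading the last value.

# Nodes are stored in a hashed environment keyed by their index so that a
# push never copies the tape (list-in-environment mutation would). Each
# node is list(value, parents, backward).
tape_new <- function(capacity = 512L) {
  tp <- new.env(parent = emptyenv())
  tp$node <- new.env(parent = emptyenv(), size = capacity, hash = TRUE)
  tp$n <- 0L
  tp
}

tp_push <- function(tape, value, parents = NULL, backward = NULL) {
  n <- tape$n + 1L
  tape$n <- n
  assign(as.character(n), list(value, parents, backward), envir = tape$node)
  n
}

tp_value <- function(tape, id) {
  force(id) # id may be an op call that pushes onto the tape
  .subset2(get(as.character(id), envir = tape$node), 1L)
}

# Leaf node: an input or parameter. Gradients accumulate but nothing
# propagates further.
tp_leaf <- function(tape, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  tp_push(tape, value)
}

#' @noRd
tape_backward <- function(tape, id) {
  grads <- vector("list", tape$n)
  v <- tp_value(tape, id)
  grads[[id]] <- matrix(1, nrow(v), ncol(v))
  node <- tape$node
  for (k in seq.int(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    nd <- get(as.character(k), envir = node)
    f <- .subset2(nd, 3L)
    if (is.null(f)) next
    pg <- f(g)
    ps <- .subset2(nd, 2L)
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

## ---- elementwise and linear-algebra ops -----------------------------------

tp_matmul <- function(tape, a, b) {
  force(a); force(b)
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  tp_push(tape, A %*% B, c(a, b), function(g) {
    list(tcrossprod(g, B), crossprod(A, g))
  })
}

tp_add <- function(tape, a, b) {
  force(a); force(b)
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  tp_push(tape, A + B, c(a, b), function(g) list(g, g))
}

# Add a 1 x d row vector (bias) to every row of a.
tp_add_rowvec <- function(tape, a, b) {
  force(a); force(b)
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  V <- A + matrix(B, nrow(A), ncol(A), byrow = TRUE)
  tp_push(tape, V, c(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

tp_sub <- function(tape, a, b) {
  force(a); force(b)
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  tp_push(tape, A - B, c(a, b), function(g) list(g, -g))
}

tp_mul <- function(tape, a, b) {
  force(a); force(b)
  A <- tp_value(tape, a); B <- tp_value(tape, b)
  tp_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_scale <- function(tape, a, s) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, A * s, a, function(g) list(g * s))
}

# Multiply a matrix node by a 1 x 1 scalar node.
tp_mul_scalar <- function(tape, a, s) {
  force(a); force(s)
  A <- tp_value(tape, a); S <- tp_value(tape, s)[1L, 1L]
  tp_push(tape, A * S, c(a, s), function(g) {
    list(g * S, matrix(sum(g * A)))
  })
}

tp_square <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, A * A, a, function(g) list(2 * g * A))
}

tp_abs <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, abs(A), a, function(g) list(g * sign(A)))
}

tp_sum <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, matrix(sum(A)), a, function(g) {
    list(matrix(g[1L], nrow(A), ncol(A)))
  })
}

## ---- nonlinearities -------------------------------------------------------

tp_relu <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  M <- A > 0
  tp_push(tape, A * M, a, function(g) list(g * M))
}

# Exact GELU: x * Phi(x).
tp_gelu <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  P <- stats::pnorm(A)
  tp_push(tape, A * P, a, function(g) {
    list(g * (P + A * stats::dnorm(A)))
  })
}

tp_tanh <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  Tv <- tanh(A)
  tp_push(tape, Tv, a, function(g) list(g * (1 - Tv^2)))
}

tp_sigmoid <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  S <- 1 / (1 + exp(-A))
  tp_push(tape, S, a, function(g) list(g * S * (1 - S)))
}

# Row-wise softmax.
tp_softmax_rows <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  M <- A - A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(M)
  S <- E / rowSums(E)
  tp_push(tape, S, a, function(g) {
    list(S * (g - rowSums(g * S)))
  })
}

## ---- normalization --------------------------------------------------------

# Row-wise layer normalization with learnable 1 x d gain/offset.
tp_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  A <- tp_value(tape, a)
  Gm <- tp_value(tape, gamma); Bt <- tp_value(tape, beta)
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  V <- xhat * matrix(Gm, nrow(A), d, byrow = TRUE) +
    matrix(Bt, nrow(A), d, byrow = TRUE)
  tp_push(tape, V, c(a, gamma, beta), function(g) {
    dxh <- g * matrix(Gm, nrow(g), d, byrow = TRUE)
    dx <- inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

# Column-wise batch normalization over all rows (batch x positions), with
# running-statistic buffers held in `buf_env` under `name`.
tp_batchnorm <- function(tape, a, gamma, beta, buf_env, name,
                         training, momentum = 0.1, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  A <- tp_value(tape, a)
  Gm <- tp_value(tape, gamma); Bt <- tp_value(tape, beta)
  n <- nrow(A); d <- ncol(A)
  if (training) {
    mu <- colMeans(A)
    va <- colMeans(A^2) - mu^2
    if (is.null(buf_env[[name]])) {
      buf_env[[name]] <- list(mean = mu, var = va)
    } else {
      b <- buf_env[[name]]
      buf_env[[name]] <- list(mean = (1 - momentum) * b$mean + momentum * mu,
                              var = (1 - momentum) * b$var + momentum * va)
    }
  } else {
    b <- buf_env[[name]]
    if (is.null(b)) b <- list(mean = numeric(d), var = rep(1, d))
    mu <- b$mean; va <- b$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (A - matrix(mu, n, d, byrow = TRUE)) *
    matrix(inv, n, d, byrow = TRUE)
  V <- xhat * matrix(Gm, n, d, byrow = TRUE) + matrix(Bt, n, d, byrow = TRUE)
  tp_push(tape, V, c(a, gamma, beta), function(g) {
    dxh <- g * matrix(Gm, n, d, byrow = TRUE)
    if (training) {
      dx <- matrix(inv, n, d, byrow = TRUE) *
        (dxh -
           matrix(colMeans(dxh), n, d, byrow = TRUE) -
           xhat * matrix(colMeans(dxh * xhat), n, d, byrow = TRUE))
    } else {
      dx <- dxh * matrix(inv, n, d, byrow = TRUE)
    }
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

## ---- structure ops --------------------------------------------------------

tp_rows <- function(tape, a, idx) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, A[idx, , drop = FALSE], a, function(g) {
    D <- matrix(0, nrow(A), ncol(A))
    D[idx, ] <- g
    list(D)
  })
}

tp_cols <- function(tape, a, idx) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, A[, idx, drop = FALSE], a, function(g) {
    D <- matrix(0, nrow(A), ncol(A))
    D[, idx] <- g
    list(D)
  })
}

tp_cbind <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp_value(tape, i))
  ws <- vapply(vals, ncol, 1L)
  ends <- cumsum(ws)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tp_push(tape, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(j) {
      g[, starts[j]:ends[j], drop = FALSE]
    })
  })
}

tp_rbind <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp_value(tape, i))
  hs <- vapply(vals, nrow, 1L)
  ends <- cumsum(hs)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tp_push(tape, do.call(rbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(j) {
      g[starts[j]:ends[j], , drop = FALSE]
    })
  })
}

tp_transpose <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  tp_push(tape, t(A), a, function(g) list(t(g)))
}

# Mean over rows (sequence positions) -> 1 x d.
tp_mean_rows <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  L <- nrow(A)
  tp_push(tape, matrix(colMeans(A), 1L), a, function(g) {
    list(matrix(g / L, L, ncol(A), byrow = TRUE))
  })
}

# Max over rows per column -> 1 x d; gradient routed to the argmax row.
tp_max_rows <- function(tape, a) {
  force(a)
  A <- tp_value(tape, a)
  am <- max.col(t(A), ties.method = "first")
  V <- matrix(A[cbind(am, seq_len(ncol(A)))], 1L)
  tp_push(tape, V, a, function(g) {
    D <- matrix(0, nrow(A), ncol(A))
    D[cbind(am, seq_len(ncol(A)))] <- g
    list(D)
  })
}

# Inverted dropout; identity when not training or p == 0.
tp_dropout <- function(tape, a, p, training) {
  force(a)
  if (!training || p <= 0) return(a)
  A <- tp_value(tape, a)
  M <- matrix(stats::rbinom(length(A), 1L, 1 - p), nrow(A)) / (1 - p)
  tp_push(tape, A * M, a, function(g) list(g * M))
}

## ---- 1-D convolution over a (stacked) sequence ----------------------------

# x: (n_seq * L_in) x C_in matrix holding n_seq sequences of equal length
# stacked along rows. W: (k * C_in) x C_out with kernel positions as row
# blocks; b: 1 x C_out. `pad` uses zeros; stride `s` patches when s == k.
tp_conv1d <- function(tape, x, W, b, k, stride = 1L, pad = c(0L, 0L),
                      n_seq = 1L) {
  force(x); force(W); force(b)
  X <- tp_value(tape, x)
  Wv <- tp_value(tape, W); bv <- tp_value(tape, b)
  cin <- ncol(X)
  L_in <- nrow(X) %/% n_seq
  Lp <- L_in + pad[1L] + pad[2L]
  L_out <- (Lp - k) %/% stride + 1L
  cout <- ncol(Wv)
  nr <- n_seq * L_out
  # im2col: column block j gathers the input rows at kernel offset j
  # (zero-padded positions stay zero); the conv is then one matmul.
  pos0 <- seq.int(0L, by = stride, length.out = L_out)
  seq_off_in <- (seq_len(n_seq) - 1L) * L_in
  seq_off_out <- (seq_len(n_seq) - 1L) * L_out
  Xcol <- matrix(0, nr, k * cin)
  blocks <- vector("list", k)
  for (j in seq_len(k)) {
    src <- pos0 + j - pad[1L] # 1-based within unpadded sequence
    valid <- src >= 1L & src <= L_in
    if (!any(valid)) next
    src_rows <- as.vector(outer(src[valid], seq_off_in, `+`))
    dst_rows <- as.vector(outer(which(valid), seq_off_out, `+`))
    cols <- ((j - 1L) * cin + 1L):(j * cin)
    Xcol[dst_rows, cols] <- X[src_rows, , drop = FALSE]
    blocks[[j]] <- list(src = src_rows, dst = dst_rows, cols = cols)
  }
  V <- Xcol %*% Wv + matrix(bv, nr, cout, byrow = TRUE)
  tp_push(tape, V, c(x, W, b), function(g) {
    dW <- crossprod(Xcol, g)
    dXcol <- tcrossprod(g, Wv)
    dX <- matrix(0, nrow(X), cin)
    for (j in seq_len(k)) {
      bj <- blocks[[j]]
      if (is.null(bj)) next
      dX[bj$src, ] <- dX[bj$src, ] + dXcol[bj$dst, bj$cols, drop = FALSE]
    }
    list(dX, dW, matrix(colSums(g), 1L))
  })
}

# "Same" padding for stride-1 convolutions.
conv_same_pad <- function(k) c((k - 1L) %/% 2L, k %/% 2L)

## ---- max pooling over sequence positions ----------------------------------

# Non-overlapping max pool (window = stride) on stacked sequences.
tp_maxpool1d <- function(tape, x, window, n_seq = 1L) {
  force(x)
  X <- tp_value(tape, x)
  L_in <- nrow(X) %/% n_seq
  L_out <- L_in %/% window
  d <- ncol(X)
  keep <- L_out * window
  # rows grouped per sequence
  out <- matrix(-Inf, n_seq * L_out, d)
  arg <- matrix(0L, n_seq * L_out, d)
  for (w in seq_len(window)) {
    rows <- as.vector(outer(seq.int(w, keep, by = window),
                            (seq_len(n_seq) - 1L) * L_in, `+`))
    cand <- X[rows, , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- matrix(rows, length(rows), d)[upd]
  }
  tp_push(tape, out, x, function(g) {
    D <- matrix(0, nrow(X), d)
    ij <- cbind(as.vector(arg), rep(seq_len(d), each = nrow(arg)))
    # accumulate (argmax rows are distinct per output cell)
    D[ij] <- D[ij] + as.vector(g)
    list(D)
  })
}

# Flatten stacked sequences: (n_seq * L) x C  ->  n_seq x (L * C).
tp_flatten_seq <- function(tape, x, n_seq) {
  force(x)
  X <- tp_value(tape, x)
  L <- nrow(X) %/% n_seq
  d <- ncol(X)
  V <- matrix(0, n_seq, L * d)
  for (i in seq_len(n_seq)) {
    V[i, ] <- as.vector(t(X[((i - 1L) * L + 1L):(i * L), , drop = FALSE]))
  }
  tp_push(tape, V, x, function(g) {
    D <- matrix(0, nrow(X), d)
    for (i in seq_len(n_seq)) {
      D[((i - 1L) * L + 1L):(i * L), ] <- matrix(g[i, ], L, d, byrow = TRUE)
    }
    list(D)
  })
}

## ---- fused LSTM (manual backpropagation through time) ---------------------

# Single-direction LSTM over an L x C input; returns L x H hidden states.
# Wx: C x 4H, Wh: H x 4H, b: 1 x 4H with gate order (i, f, g, o).
tp_lstm <- function(tape, x, Wx, Wh, b, reverse = FALSE) {
  force(x); force(Wx); force(Wh); force(b)
  X <- tp_value(tape, x)
  WX <- tp_value(tape, Wx); WH <- tp_value(tape, Wh); B <- tp_value(tape, b)
  L <- nrow(X); H <- nrow(WH)
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  Ig <- Fg <- Gg <- Og <- Cc <- Tc <- Hs <- matrix(0, L, H)
  h <- matrix(0, 1L, H); cst <- matrix(0, 1L, H)
  XW <- X %*% WX # precompute input part for all steps
  for (t in ord) {
    z <- XW[t, , drop = FALSE] + h %*% WH + B
    i_t <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    f_t <- 1 / (1 + exp(-z[, ff, drop = FALSE]))
    g_t <- tanh(z[, gg, drop = FALSE])
    o_t <- 1 / (1 + exp(-z[, oo, drop = FALSE]))
    cst <- f_t * cst + i_t * g_t
    tc <- tanh(cst)
    h <- o_t * tc
    Ig[t, ] <- i_t; Fg[t, ] <- f_t; Gg[t, ] <- g_t; Og[t, ] <- o_t
    Cc[t, ] <- cst; Tc[t, ] <- tc; Hs[t, ] <- h
  }
  tp_push(tape, Hs, c(x, Wx, Wh, b), function(g) {
    dX <- matrix(0, L, ncol(X))
    dWX <- matrix(0, nrow(WX), 4L * H)
    dWH <- matrix(0, H, 4L * H)
    dB <- matrix(0, 1L, 4L * H)
    dh <- matrix(0, 1L, H); dc <- matrix(0, 1L, H)
    steps <- rev(ord)
    for (s in seq_along(steps)) {
      t <- steps[s]
      t_prev <- if (s == length(steps)) 0L else steps[s + 1L]
      dh_t <- g[t, , drop = FALSE] + dh
      o_t <- Og[t, , drop = FALSE]; tc <- Tc[t, , drop = FALSE]
      i_t <- Ig[t, , drop = FALSE]; f_t <- Fg[t, , drop = FALSE]
      g_t <- Gg[t, , drop = FALSE]
      dc <- dc + dh_t * o_t * (1 - tc^2)
      c_prev <- if (t_prev == 0L) matrix(0, 1L, H) else Cc[t_prev, , drop = FALSE]
      dz <- cbind(dc * g_t * i_t * (1 - i_t),
                  dc * c_prev * f_t * (1 - f_t),
                  dc * i_t * (1 - g_t^2),
                  dh_t * tc * o_t * (1 - o_t))
      h_prev <- if (t_prev == 0L) matrix(0, 1L, H) else Hs[t_prev, , drop = FALSE]
      dWX <- dWX + crossprod(X[t, , drop = FALSE], dz)
      dWH <- dWH + crossprod(h_prev, dz)
      dB <- dB + dz
      dX[t, ] <- dz %*% t(WX)
      dh <- dz %*% t(WH)
      dc <- dc * f_t
    }
    list(dX, dWX, dWH, dB)
  })
}
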