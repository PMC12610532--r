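test_that("every baseline maps a spectrum batch to four outputs", {
  g <- tiny_grid()
  X <- matrix(rnorm(3 * 96), 3)
  cfgs <- list(
    baseline_config("mlp", hidden_widths = c(32L, 16L)),
    baseline_config("cnn", filters = c(8L, 8L), kernels = c(3L, 5L),
                    dense_width = 16L),
    baseline_config("transformer", d_model = 16L, n_heads = 2L,
                    n_layers = 2L, patch_size = 8L, dropout = 0),
    baseline_config("lsttn", d_model = 16L, lstm_hidden = 16L,
                    lstm_layers = 2L, patch_size = 8L))
  for (cfg in cfgs) {
    m <- build_baseline(cfg, g, seed = 1L)
    p <- predict(m, X)
    expect_equal(dim(p), c(3L, 4L))
    expect_true(all(is.finite(p)))
    expect_equal(unname(predict(m, X[2, ])), unname(p[2, , drop = FALSE]),
                 tolerance = 1e-5)
  }
  expect_error(baseline_config("gru"), "unknown baseline kind")
})

test_that("the 1-D convolution matches hand arithmetic", {
  # kernel (1, 0, -1), bias 0, identity activation, x = (1, 2, 4)
  ns <- asNamespace("spectran")
  tape <- ns$tape_new()
  x <- ns$tp_leaf(tape, matrix(c(1, 2, 4), ncol = 1))
  W <- ns$tp_leaf(tape, matrix(c(1, 0, -1), ncol = 1))
  b <- ns$tp_leaf(tape, matrix(0))
  y <- ns$tp_conv1d(tape, x, W, b, 3L)
  expect_equal(ns$tp_value(tape, y), matrix(-3))
})

test_that("CNN pooling lengths follow the closed-form size formula", {
  g <- tiny_grid() # 96 channels
  cfg <- baseline_config("cnn", filters = c(8L, 8L), kernels = c(3L, 5L),
                         dense_width = 16L)
  m <- build_baseline(cfg, g, seed = 2L)
  # same-padded conv keeps L, each max-pool halves: 96 -> 48 -> 24
  expect_equal(dim(m$params[["dense1.W"]]), c(24L * 8L, 16L))
  expect_equal(dim(predict(m, matrix(rnorm(96), 1))), c(1L, 4L))
})

test_that("LSTM attention reweighting is row-stochastic and matches a
           direct arithmetic oracle", {
  expect_equal(lsttn_attention(matrix(5)), matrix(5)) # T = 1: softmax is 1
  H2 <- matrix(c(1, 1, 0.3, 0.3), 2) # identical rows
  out2 <- lsttn_attention(H2)
  expect_equal(out2[1, ], out2[2, ])
  # 2 x 2 hand case: H = I, d = 2
  H <- diag(2)
  S <- H %*% t(H) / sqrt(2)
  W <- exp(S) / rowSums(exp(S))
  expect_equal(lsttn_attention(H), W %*% H, tolerance = 1e-12)
  expect_equal(unname(W[1, ]),
               unname(exp(c(1 / sqrt(2), 0)) / sum(exp(c(1 / sqrt(2), 0)))))
  # rows of the internal weights always sum to 1
  set.seed(3)
  Hr <- matrix(rnorm(20), 5)
  expect_equal(rowSums(lsttn_attention(diag(5))), rep(1, 5),
               tolerance = 1e-6) # diag rows are convex mixes summing to 1
  expect_true(all(is.finite(lsttn_attention(Hr))))
})

test_that("each baseline improves validation loss over its initialization
           under the shared training loop", {
  ds <- tiny_dataset(n = 40L, seed = 30L)
  parts <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 31L)
  tcfg <- train_config(max_epochs = 8L, patience = 8L, batch_size = 8L,
                       eta_max = 3e-3, seed = 32L)
  cfgs <- list(
    baseline_config("mlp", hidden_widths = c(32L, 16L)),
    baseline_config("cnn", filters = c(6L, 6L), kernels = c(3L, 5L),
                    dense_width = 12L),
    baseline_config("transformer", d_model = 16L, n_heads = 2L,
                    n_layers = 1L, patch_size = 12L, dropout = 0),
    baseline_config("lsttn", d_model = 12L, lstm_hidden = 12L,
                    lstm_layers = 1L, patch_size = 12L))
  for (cfg in cfgs) {
    m0 <- build_baseline(cfg, ds$grid, seed = 33L)
    fit <- train_model(m0, parts$train, parts$val, tcfg)
    expect_lt(fit$model$meta$best_val_loss, fit$history$val_loss[1] + 1e-9)
    expect_lt(fit$history$val_loss[fit$best_epoch],
              max(fit$history$val_loss))
  }
})

test_that("the transformer baseline exposes row-stochastic attention", {
  m <- build_baseline(baseline_config("transformer", d_model = 16L,
                                      n_heads = 2L, n_layers = 2L,
                                      patch_size = 8L, dropout = 0),
                      tiny_grid(), seed = 5L)
  am <- extract_attention(m, rnorm(96), layer = 2L)
  expect_equal(dim(am), c(12L, 12L))
  expect_equal(unname(rowSums(am)), rep(1, 12), tolerance = 1e-6)
  expect_true(all(am >= 0))
})
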