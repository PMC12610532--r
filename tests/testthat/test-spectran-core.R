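test_that("patch embedding truncates to 43 patches on the 700-channel grid", {
  cfg <- tiny_spectran_config()
  m <- spectran_model(cfg, wavelength_grid(), seed = 1L)
  pe <- patch_embed(rnorm(700), m)
  expect_equal(pe$L, 43L) # min(floor(700/8), floor(700/12), floor(700/16))
  expect_equal(dim(pe$values), c(43L, cfg$d_model))
  expect_equal(sum(pe$fusion_weights), 1, tolerance = 1e-6)
  # zero-initialized fusion logits give exactly equal branch weights
  expect_equal(pe$fusion_weights, rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(patch_embed(rnorm(10), m), "kernel")
})

test_that("spectral positional encoding reduces to the classic sinusoid at
           lambda = 0 and scales rows linearly in position", {
  for (prm in list(c(43, 16), c(7, 8))) {
    L <- prm[1]; d <- prm[2]
    expect_lt(max(abs(spectral_positional_encoding(L, d, 0) -
                        classic_sinusoidal_pe(L, d))), 1e-12)
    pe <- spectral_positional_encoding(L, d, 0.1)
    # p = 0 row: sin 0 / cos 0 pattern, any lambda
    expect_equal(pe[1, ], rep(c(0, 1), d / 2))
    # last row scaled by (1 + lambda)
    expect_equal(pe[L, ], 1.1 * classic_sinusoidal_pe(L, d)[L, ],
                 tolerance = 1e-12)
  }
  expect_warning(pe1 <- spectral_positional_encoding(1, 8, 0.5), "L = 1")
  expect_equal(pe1[1, ], classic_sinusoidal_pe(1, 8)[1, ])
})

test_that("multi-scale spectral attention preserves sequence shape for
           lengths shorter and longer than its largest kernel", {
  m <- spectran_model(tiny_spectran_config(), wavelength_grid(), seed = 2L)
  for (L in c(10L, 43L)) {
    z <- matrix(rnorm(L * 16), L)
    out <- multi_scale_spectral_attention(z, m)
    expect_equal(dim(out), c(L, 16L))
    expect_true(all(is.finite(out)))
  }
})

test_that("enhanced blocks preserve shape and emit LayerNorm-ed rows", {
  cfg <- tiny_spectran_config()
  m <- spectran_model(cfg, wavelength_grid(), seed = 3L)
  a <- matrix(rnorm(43 * 16), 43)
  out <- a
  for (b in seq_len(cfg$n_blocks)) out <- enhanced_block(out, m, block = b)
  expect_equal(dim(out), c(43L, 16L))
  expect_equal(unname(rowMeans(out)), rep(0, 43), tolerance = 1e-6)
  expect_equal(unname(apply(out, 1, function(r) mean(r^2))), rep(1, 43),
               tolerance = 1e-2) # population variance up to LayerNorm eps
})

test_that("fusion produces three 64-wide paths concatenated to 192", {
  m <- spectran_model(spectran_config(d_model = 32L, n_blocks = 1L,
                                      dropout = 0),
                      wavelength_grid(), seed = 4L)
  b <- matrix(rnorm(43 * 32), 43)
  f <- multi_path_fusion(b, m)
  expect_length(f$f_global, 64L)
  expect_length(f$f_local, 64L)
  expect_length(f$f_sequential, 64L)
  expect_length(f$f_fused, 192L)
  # constant-over-sequence input: global path equals the MLP of any row
  bc <- matrix(rep(rnorm(32), each = 43), 43)
  fc <- multi_path_fusion(bc, m)
  f1 <- multi_path_fusion(bc[c(1, 1), , drop = FALSE][1:2, ], m)
  expect_equal(fc$f_global, f1$f_global, tolerance = 1e-10)
})

test_that("prediction heads blend task and shared outputs convexly", {
  m <- spectran_model(tiny_spectran_config(), wavelength_grid(), seed = 5L)
  f <- rnorm(48) # 3 * path_dim for the tiny config
  h1 <- predict_heads(f, m, alpha = 1)
  expect_equal(h1$y, h1$y_task)
  h0 <- predict_heads(f, m, alpha = 0)
  expect_equal(h0$y, h0$y_shared)
  h5 <- predict_heads(f, m, alpha = 0.5)
  expect_equal(h5$y, (h5$y_task + h5$y_shared) / 2)
  hd <- predict_heads(f, m)
  expect_true(all(hd$y >= pmin(hd$y_task, hd$y_shared) - 1e-12 &
                    hd$y <= pmax(hd$y_task, hd$y_shared) + 1e-12))
})

test_that("evaluation-mode forward is deterministic, batch-consistent and
           survives a checkpoint round-trip", {
  m <- spectran_model(spectran_config(d_model = 16L, n_blocks = 2L,
                                      n_heads = 2L, path_dim = 16L,
                                      head_widths = rep(16L, 4L),
                                      dropout = 0.2), # dropout must not leak
                      wavelength_grid(), seed = 6L)
  X <- matrix(rnorm(5 * 700), 5)
  p1 <- predict(m, X)
  expect_equal(dim(p1), c(5L, 4L))
  expect_identical(p1, predict(m, X)) # pure function in eval mode
  singles <- t(sapply(seq_len(5), function(i) predict(m, X[i, ])))
  expect_equal(unname(p1), unname(singles), tolerance = 1e-5)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_model(m, ck)
  m2 <- load_model(ck)
  expect_identical(predict(m2, X), p1)
  expect_error(predict(m, X[, 1:100]), "channels")
})

test_that("corrupted checkpoints are rejected", {
  m <- spectran_model(tiny_spectran_config(), wavelength_grid(), seed = 7L)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_model(m, ck)
  raw <- readRDS(ck)
  raw$config$n_blocks <- 99L
  saveRDS(raw, ck)
  expect_error(load_model(ck), "hash mismatch")
})

test_that("every parameter group receives gradient on a random batch", {
  ns <- asNamespace("spectran")
  m <- spectran_model(tiny_spectran_config(), wavelength_grid(), seed = 8L)
  set.seed(9)
  X <- matrix(rnorm(3 * 700), 3)
  Y <- matrix(rnorm(12), 3)
  tape <- ns$tape_new(8192L)
  yid <- ns$model_forward(m, X, tape, training = FALSE)
  yl <- ns$tp_leaf(tape, Y)
  ls <- ns$tp_composite_loss(tape, yid, yl, train_config())
  gr <- ns$tape_backward(tape, ls$total)
  grads <- gr[seq_along(m$params)]
  dead <- names(m$params)[vapply(grads, function(g) {
    is.null(g) || all(g == 0)
  }, TRUE)]
  expect_length(dead, 0)
})
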