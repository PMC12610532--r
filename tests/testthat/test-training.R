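test_that("composite loss matches hand arithmetic and brute force", {
  # single sample, residual (1, 0, 0, 0), unit coefficients
  cfg1 <- loss_config(1, 1, 1)
  out <- composite_loss(matrix(c(1, 0, 0, 0), 1), matrix(0, 1, 4), cfg1)
  expect_equal(out$components[["mse"]], 1)
  expect_equal(out$components[["l1"]], 1)
  expect_equal(out$components[["weighted"]], 1.2)
  expect_equal(out$total, 3.2)
  # identical inputs: everything zero
  y <- matrix(rnorm(20), 5)
  z <- composite_loss(y, y)
  expect_equal(z$total, 0)
  expect_equal(unname(z$components), c(0, 0, 0))
  # 100 random instances against the explicit-loop oracle
  set.seed(11)
  for (r in 1:100) {
    n <- sample(1:6, 1)
    yh <- matrix(rnorm(4 * n), n); yt <- matrix(rnorm(4 * n), n)
    a <- runif(1); b <- runif(1); g <- runif(1); w <- runif(4, 0.5, 2)
    got <- composite_loss(yh, yt, loss_config(a, b, g, w))$total
    expect_equal(got, brute_force_loss(yh, yt, a, b, g, w),
                 tolerance = 1e-10)
  }
  expect_error(composite_loss(matrix(0, 2, 4), matrix(0, 3, 4)), "shape")
})

test_that("the loss is linear in its term coefficients", {
  set.seed(12)
  yh <- matrix(rnorm(12), 3); yt <- matrix(rnorm(12), 3)
  l1 <- composite_loss(yh, yt, loss_config(1, 0.2, 0.5))
  l2 <- composite_loss(yh, yt, loss_config(1, 0.2, 1.0))
  expect_equal(l2$total - l1$total, 0.5 * l1$components[["weighted"]],
               tolerance = 1e-12)
})

test_that("the one-cycle schedule ramps, anneals and joins continuously", {
  cfg <- train_config(eta_min = 1e-5, eta_max = 1e-3, warmup_frac = 0.2)
  total <- 101L
  Tw <- floor(0.2 * total) # 20
  expect_equal(one_cycle_lr(0, total, cfg), 1e-5)
  expect_equal(one_cycle_lr(Tw, total, cfg), 1e-3) # end of warmup
  expect_equal(one_cycle_lr(total - 1L, total, cfg), 1e-5,
               tolerance = 1e-12) # final step
  Tann <- total - 1L - Tw # 80
  expect_equal(one_cycle_lr(Tw + Tann / 2, total, cfg),
               (1e-5 + 1e-3) / 2) # annealing midpoint
  lrs <- one_cycle_lr(0:(total - 1L), total, cfg)
  expect_true(all(diff(lrs[1:(Tw + 1L)]) > 0)) # monotone warmup
  expect_true(all(diff(lrs[(Tw + 1L):total]) < 0)) # monotone anneal
  expect_lt(max(abs(diff(lrs[(Tw):(Tw + 2L)]))),
            (1e-3 - 1e-5) / Tw + 1e-9) # no jump at the junction
  expect_error(one_cycle_lr(total, total, cfg))
})

test_that("a frozen model stops after exactly patience + 1 epochs", {
  g <- tiny_grid()
  ds <- tiny_dataset(n = 12L)
  frozen <- functional_model(function(x) c(0, 0, 0, 0), g)
  fit <- train_model(frozen, ds, ds,
                     train_config(max_epochs = 100L, patience = 5L,
                                  batch_size = 12L, seed = 1L))
  expect_equal(fit$stopped_epoch, 6L)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(length(unique(fit$history$val_loss)), 1L)
})

test_that("a NaN loss aborts with the epoch and batch named", {
  g <- tiny_grid()
  ds <- tiny_dataset(n = 8L)
  bad <- functional_model(function(x) c(NaN, 0, 0, 0), g)
  expect_error(train_model(bad, ds, ds, train_config(seed = 1L)),
               "epoch 1, batch 1")
})

test_that("post-clipping gradient norms never exceed the clip threshold", {
  ds <- tiny_dataset(n = 24L, seed = 40L)
  parts <- split_spectra(ds, c(0.7, 0.15, 0.15), seed = 41L)
  m <- spectran_model(tiny_spectran_config(), ds$grid, seed = 42L)
  fit <- train_model(m, parts$train, parts$val,
                     train_config(max_epochs = 4L, patience = 4L,
                                  batch_size = 8L, clip_norm = 1.0,
                                  seed = 43L))
  expect_gt(length(fit$grad_norms), 0)
  expect_true(all(fit$grad_norms <= 1.0 + 1e-6))
  expect_true(any(fit$grad_norms == 1.0)) # clipping actually engaged
})

test_that("identical seeds reproduce training bit for bit", {
  ds <- tiny_dataset(n = 20L, seed = 50L)
  parts <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 51L)
  run <- function() {
    m <- build_baseline(baseline_config("mlp", hidden_widths = c(24L, 12L)),
                        ds$grid, seed = 52L)
    train_model(m, parts$train, parts$val,
                train_config(max_epochs = 6L, patience = 6L, batch_size = 4L,
                             seed = 53L))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$grad_norms, f2$grad_norms)
})

test_that("predictions are de-standardized back to original percent units", {
  ds <- tiny_dataset(n = 24L, seed = 60L)
  parts <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 61L)
  m <- build_baseline(baseline_config("mlp", hidden_widths = c(24L)),
                      ds$grid, seed = 62L)
  fit <- train_model(m, parts$train, parts$val,
                     train_config(max_epochs = 15L, patience = 15L,
                                  batch_size = 8L, seed = 63L))
  p <- predict(fit$model, parts$test)
  # recompute by hand from the standardized forward pass
  ns <- asNamespace("spectran")
  Xs <- ns$scale_inputs(fit$model, parts$test$X)
  tape <- ns$tape_new(4096L)
  raw <- ns$tp_value(tape, ns$model_forward(fit$model, Xs, tape))
  manual <- sweep(sweep(raw, 2L, fit$model$scaler$sd, `*`), 2L,
                  fit$model$scaler$mean, `+`)
  expect_equal(unname(p), manual, tolerance = 1e-12, ignore_attr = TRUE)
  # trained predictions live on the constituent scale, not the z-scale
  expect_true(all(abs(colMeans(p) - colMeans(parts$train$Y)) <
                    10 * apply(parts$train$Y, 2, sd)))
  m2 <- glance(fit)
  expect_equal(m2$epochs, fit$stopped_epoch)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("training on augmented nonlinear data attains positive validation
           R-squared on all four constituents", {
  ds <- tiny_dataset(n = 72L, seed = 70L, mode = "nonlinear", noise_sd = 3e-4)
  parts <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 71L)
  train_aug <- augment_spectra(parts$train, n_new = 4L * nrow(parts$train$X),
                               seed = 72L)
  m <- spectran_model(tiny_spectran_config(), ds$grid, seed = 73L)
  fit <- train_model(m, train_aug, parts$val,
                     train_config(max_epochs = 12L, patience = 12L,
                                  batch_size = 32L, eta_max = 2e-3,
                                  seed = 74L))
  metrics <- evaluate_model(fit, parts$val)
  expect_true(all(metrics$r2 > 0))
})
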