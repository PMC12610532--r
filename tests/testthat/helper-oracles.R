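# Independent oracles and small shared fixtures.

# Classic sinusoidal positional encoding, written directly from its
# textbook definition (independent of the package implementation).
classic_sinusoidal_pe <- function(L, d_model) {
  PE <- matrix(0, L, d_model)
  for (p in 0:(L - 1)) {
    for (i in 0:(d_model / 2 - 1)) {
      ang <- p / 10000^(2 * i / d_model)
      PE[p + 1, 2 * i + 1] <- sin(ang)
      PE[p + 1, 2 * i + 2] <- cos(ang)
    }
  }
  PE
}

# Brute-force composite loss with explicit loops over samples and tasks.
brute_force_loss <- function(y_hat, y, alpha, beta, gamma, w) {
  n <- nrow(y)
  mse <- 0; l1 <- 0; weighted <- 0
  for (i in seq_len(n)) {
    for (j in 1:4) {
      r <- y_hat[i, j] - y[i, j]
      mse <- mse + r^2 / n
      l1 <- l1 + abs(r) / n
      weighted <- weighted + w[j] * r^2 / n
    }
  }
  alpha * mse + beta * l1 + gamma * weighted
}

# Closed-form principal-component regression oracle: regress each
# constituent on the leading PC scores of the (centered) spectra, fit on
# one half, R2 evaluated on the other half.
pcr_oracle_r2 <- function(ds, n_components = 8L) {
  n <- nrow(ds$X)
  tr <- seq_len(n %/% 2)
  te <- setdiff(seq_len(n), tr)
  mu <- colMeans(ds$X[tr, ])
  Xc <- sweep(ds$X[tr, ], 2L, mu)
  sv <- svd(Xc, nu = 0, nv = n_components)
  S_tr <- cbind(1, Xc %*% sv$v)
  S_te <- cbind(1, sweep(ds$X[te, ], 2L, mu) %*% sv$v)
  B <- qr.solve(S_tr, ds$Y[tr, ])
  pred <- S_te %*% B
  sapply(1:4, function(j) {
    1 - sum((pred[, j] - ds$Y[te, j])^2) /
      sum((ds$Y[te, j] - mean(ds$Y[te, j]))^2)
  })
}

# Small-footprint architecture/training configs used across tests.
tiny_spectran_config <- function(...) {
  spectran_config(d_model = 16L, n_blocks = 2L, n_heads = 2L,
                  path_dim = 16L, head_widths = rep(16L, 4L), dropout = 0, ...)
}

tiny_grid <- function() wavelength_grid(n_channels = 96L)

# Bands that fit the 96-channel grid (1100-1290 nm).
tiny_bands <- function() {
  list(moisture = list(band_spec(1130, 8, 0.010)),
       starch = list(band_spec(1170, 8, 0.020)),
       oil = list(band_spec(1210, 8, 0.010)),
       protein = list(band_spec(1260, 8, 0.004)))
}

tiny_dataset <- function(n = 48L, seed = 5L, mode = "linear",
                         noise_sd = 5e-4) {
  generate_spectra(generator_config(n_samples = n, grid = tiny_grid(),
                                    bands = tiny_bands(), noise_sd = noise_sd,
                                    mode = mode, seed = seed))
}

# Interpretability probe fixture: the protein-labelled constituent absorbs
# only in channels ~580-660 of the full grid, other constituents far away,
# with comparable band strengths (so localization is not confounded with
# feature strength) and no channel noise (so importance reflects band
# structure, not sampling noise).
protein_band_config <- function(n = 192L, seed = 21L) {
  generator_config(
    n_samples = n,
    bands = list(moisture = list(band_spec(1400, 30, 0.010)),
                 starch = list(band_spec(1850, 35, 0.020)),
                 oil = list(band_spec(1600, 25, 0.010)),
                 protein = list(band_spec(2340, 25, 0.005))),
    noise_sd = 0, seed = seed)
}

# The test samples in which a constituent's dependence is most visible:
# those deviating most from the training mean on that constituent (the
# perturbation response at a band scales with that deviation).
top_deviant_samples <- function(parts, constituent = 4L, k = 3L) {
  dev <- abs(parts$test$Y[, constituent] -
               mean(parts$train$Y[, constituent]))
  order(dev, decreasing = TRUE)[seq_len(k)]
}
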