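test_that("generator defaults encode the benchmark's study conditions", {
  cfg <- generator_config()
  expect_equal(cfg$n_samples, 80L)
  expect_equal(cfg$grid$n_channels, 700L)
  expect_equal(cfg$constituent_means, c(10.234, 3.498, 8.668, 64.696))
  expect_equal(cfg$constituent_stds, c(0.380, 0.177, 0.499, 0.821))
  expect_named(cfg$bands, constituent_names())
})

test_that("generation is fully reproducible from the seed", {
  a <- generate_spectra(generator_config(n_samples = 10L, seed = 42L))
  b <- generate_spectra(generator_config(n_samples = 10L, seed = 42L))
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)
})

test_that("a single on-grid band peaks at concentration times amplitude", {
  # one absorbing constituent, band centered exactly on channel 151
  bands <- list(moisture = list(band_spec(1400, 30, 0.01)),
                starch = list(band_spec(1200, 10, 0)),
                oil = list(band_spec(1200, 10, 0)),
                protein = list(band_spec(1200, 10, 0)))
  cfg <- generator_config(n_samples = 6L, bands = bands, baseline_offset = 0,
                          baseline_slope = 0, noise_sd = 0, seed = 3L)
  ds <- generate_spectra(cfg)
  ch <- which(wavelengths(cfg$grid) == 1400)
  expect_equal(ds$X[, ch], ds$Y[, 1] * 0.01, tolerance = 1e-12)
  expect_equal(unname(apply(ds$X, 1L, which.max)), rep(ch, 6))
})

test_that("noiseless linear spectra are exactly linear in concentrations", {
  cfg1 <- generator_config(n_samples = 12L, noise_sd = 0, seed = 8L)
  cfg2 <- generator_config(n_samples = 12L, noise_sd = 0, seed = 8L,
                           constituent_means = cfg1$constituent_means * 2,
                           constituent_stds = cfg1$constituent_stds * 2)
  d1 <- generate_spectra(cfg1)
  d2 <- generate_spectra(cfg2)
  expect_equal(d2$Y, 2 * d1$Y, tolerance = 1e-12)
  expect_equal(attr(d2, "concentration_signal"),
               2 * attr(d1, "concentration_signal"), tolerance = 1e-12)
})

test_that("sample moments converge to the configured moments", {
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  cfg <- generator_config(n_samples = 5000L, correlation = R, seed = 13L)
  ds <- generate_spectra(cfg)
  se_mean <- cfg$constituent_stds / sqrt(5000)
  expect_true(all(abs(colMeans(ds$Y) - cfg$constituent_means) < 3 * se_mean))
  sdv <- apply(ds$Y, 2, sd)
  se_sd <- cfg$constituent_stds / sqrt(2 * 4999)
  expect_true(all(abs(sdv - cfg$constituent_stds) < 4 * se_sd))
  cor_emp <- cor(ds$Y)
  expect_true(max(abs(cor_emp - R)) < 0.05)
})

test_that("nonlinear mode degenerates to linear when saturation and
           interaction are off", {
  base <- list(n_samples = 10L, noise_sd = 2e-4, seed = 17L)
  lin <- generate_spectra(do.call(generator_config, c(base, mode = "linear")))
  non <- generate_spectra(do.call(generator_config,
                                  c(base, mode = "nonlinear", s0 = Inf,
                                    interaction_weight = 0)))
  expect_equal(non$X, lin$X, tolerance = 1e-9)
  sat <- generate_spectra(do.call(generator_config,
                                  c(base, mode = "nonlinear", s0 = 0.05)))
  expect_gt(max(abs(sat$X - lin$X)), 1e-6) # saturation actually bends
})

test_that("invalid correlation matrices are rejected", {
  R <- matrix(0.99, 4, 4); R[1, 2] <- R[2, 1] <- -0.99; diag(R) <- 1e-6
  expect_error(generator_config(correlation = R), "positive-definite")
})

test_that("a linear least-squares oracle recovers noiseless concentrations", {
  ds <- generate_spectra(generator_config(n_samples = 200L, noise_sd = 0,
                                          seed = 19L))
  r2 <- pcr_oracle_r2(ds)
  expect_true(all(r2 >= 0.99))
})
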