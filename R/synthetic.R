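# Synthetic corn-like NIR spectra with known ground truth.
#
# Concentrations are drawn from a (truncated) multivariate normal matching
# the benchmark's per-constituent means/sds; each spectrum is a linear
# baseline plus per-constituent Gaussian absorption bands scaled by the
# sample's concentrations, plus i.i.d. channel noise. The band placement is
# chosen so interpretability analyses have a known answer: the
# protein-labelled constituent absorbs in channels 0-100 and 580-660, the
# starch band sits mid-range, mirroring the saliency structure the model is
# expected to recover.

#' Describe one absorption band
#'
#' @param center_nm Band center in nm.
#' @param width_nm Gaussian width (sd) in nm, positive.
#' @param amplitude Peak absorbance contributed per percent concentration.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center_nm, width_nm, amplitude) {
  stopifnot(width_nm > 0)
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "band_spec")
}

default_bands <- function() {
  # channel c sits at 1100 + 2c nm; protein bands at channels ~50 and ~620,
  # starch mid-range (~375), oil high (~620 area edge), moisture low-mid.
  list(
    moisture = list(band_spec(1400, 30, 0.010)),              # channel 150
    starch = list(band_spec(1850, 35, 0.020)),                # channel 375
    oil = list(band_spec(2300, 25, 0.010)),                   # channel 600
    protein = list(band_spec(1200, 25, 0.003),                # channel 50
                   band_spec(2340, 25, 0.003))                # channel 620
  )
}

#' Generator configuration with benchmark-matched defaults
#'
#' Defaults emulate the corn benchmark: 80 samples, 700 channels on a
#' 1100-2498 nm grid, and the four constituents' printed means and
#' standard deviations (moisture 10.234/0.380, starch 3.498/0.177, oil
#' 8.668/0.499, protein 64.696/0.821, all percent).
#'
#' @param n_samples Number of samples to draw.
#' @param grid A [wavelength_grid()].
#' @param constituent_means,constituent_stds Length-4 numeric vectors in
#'   the canonical constituent order.
#' @param bands Named list (per constituent) of lists of [band_spec()]s.
#' @param baseline_offset,baseline_slope Additive baseline: `offset +
#'   slope * (lambda - start) / span`.
#' @param noise_sd I.i.d. Gaussian channel noise sd (absorbance units).
#' @param mode `"linear"` or `"nonlinear"` (saturating map plus one
#'   oil-protein product interaction).
#' @param correlation 4x4 positive-definite correlation matrix for the
#'   concentration draw.
#' @param s0 Saturation scale of the nonlinear map `s -> s0 * tanh(s/s0)`;
#'   `Inf` disables saturation.
#' @param interaction_weight Amplitude of the oil x protein interaction
#'   band (nonlinear mode only).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples = 80L,
                             grid = wavelength_grid(),
                             constituent_means = c(10.234, 3.498, 8.668, 64.696),
                             constituent_stds = c(0.380, 0.177, 0.499, 0.821),
                             bands = default_bands(),
                             baseline_offset = 0.3,
                             baseline_slope = 0.2,
                             noise_sd = 0.001,
                             mode = c("linear", "nonlinear"),
                             correlation = diag(4),
                             s0 = 0.5,
                             interaction_weight = 0.02,
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(constituent_means) == 4L, length(constituent_stds) == 4L,
            all(constituent_stds >= 0), length(bands) == 4L)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      inherits(try(chol(correlation), silent = TRUE), "try-error")) {
    stop("correlation must be a symmetric positive-definite 4x4 matrix",
         call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), grid = grid,
                 constituent_means = constituent_means,
                 constituent_stds = constituent_stds, bands = bands,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 mode = mode, correlation = correlation, s0 = s0,
                 interaction_weight = interaction_weight,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# n x 4 band-shape response matrix: column j is the summed unit-amplitude
# profile of constituent j's bands over the grid.
band_profiles <- function(cfg) {
  wl <- wavelengths(cfg$grid)
  G <- matrix(0, length(wl), 4L)
  for (j in seq_len(4L)) {
    for (b in cfg$bands[[j]]) {
      G[, j] <- G[, j] + b$amplitude * exp(-(wl - b$center_nm)^2 /
                                             (2 * b$width_nm^2))
    }
  }
  G
}

# Truncated-positive multivariate normal by redraw.
draw_concentrations <- function(n, means, stds, correlation) {
  R <- chol(correlation)
  draw <- function(m) {
    Z <- matrix(stats::rnorm(m * 4L), m, 4L) %*% R
    sweep(sweep(Z, 2L, stds, `*`), 2L, means, `+`)
  }
  Y <- draw(n)
  bad <- which(apply(Y, 1L, function(r) any(r <= 0)))
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    Y[bad, ] <- draw(length(bad))
    bad <- bad[apply(Y[bad, , drop = FALSE], 1L, function(r) any(r <= 0))]
    guard <- guard + 1L
  }
  Y
}

#' Generate a synthetic spectra dataset
#'
#' @param cfg A [generator_config()].
#' @return A [spectra_dataset()] whose attributes `concentration_signal`
#'   (the noiseless constituent-attributable part) and `config` expose the
#'   ground truth for testing.
#' @export
generate_spectra <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    wl <- wavelengths(cfg$grid)
    span <- max(wl[length(wl)] - wl[1L], 1)
    base <- cfg$baseline_offset + cfg$baseline_slope * (wl - wl[1L]) / span
    G <- band_profiles(cfg)
    Y <- draw_concentrations(n, cfg$constituent_means, cfg$constituent_stds,
                             cfg$correlation)
    S <- Y %*% t(G) # n x channels linear constituent signal
    if (cfg$mode == "nonlinear") {
      if (is.finite(cfg$s0)) S <- cfg$s0 * tanh(S / cfg$s0)
      if (cfg$interaction_weight != 0) {
        z <- sweep(sweep(Y, 2L, cfg$constituent_means, `-`),
                   2L, pmax(cfg$constituent_stds, 1e-12), `/`)
        inter_profile <- exp(-(wl - 2340)^2 / (2 * 25^2))
        S <- S + cfg$interaction_weight * (z[, 3L] * z[, 4L]) %o% inter_profile
      }
    }
    X <- sweep(S, 2L, base, `+`)
    if (cfg$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = cfg$noise_sd), n)
    }
    ds <- spectra_dataset(X, Y, cfg$grid,
                          sprintf("syn%04d", seq_len(max(n, 0L))))
    attr(ds, "concentration_signal") <- S
    attr(ds, "config") <- cfg
    ds
  })
}
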