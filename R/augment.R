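# Interpolation-based training-set expansion: each synthetic sample is a
# convex combination of two distinct parents in both spectrum and label
# space, x_new = a*x_i + (1-a)*x_j, y_new = a*y_i + (1-a)*y_j with
# a ~ U(0.1, 0.9), growing 80 training samples to 2000 at the defaults.

#' Interpolate one pair of samples
#'
#' @param x_i,x_j Parent spectra (equal length numeric vectors).
#' @param y_i,y_j Parent label vectors (equal length).
#' @param alpha Mixing weight in (0, 1); weight on the *first* parent.
#' @return List with elements `x` and `y`.
#' @examples
#' interpolate_pair(c(0, 2), c(1, 1), c(2, 0), c(3, 3), 0.5)$x # 1 1
#' @export
interpolate_pair <- function(x_i, y_i, x_j, y_j, alpha) {
  if (length(x_i) != length(x_j) || length(y_i) != length(y_j)) {
    stop("parent vectors must have equal lengths", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  list(x = alpha * x_i + (1 - alpha) * x_j,
       y = alpha * y_i + (1 - alpha) * y_j)
}

#' Expand a training set by pairwise interpolation
#'
#' Appends `n_new` synthetic samples to `train` (originals first, order
#' preserved). Each synthetic sample mixes two distinct parents drawn
#' uniformly (pairs may repeat across draws) with a fresh
#' `alpha ~ U(alpha_low, alpha_high)`. Synthetic sample ids record the
#' parent ids and alpha. Apply this to the *training split only*:
#' interpolating across splits would leak evaluation information.
#'
#' @param train A [spectra_dataset()] with at least 2 samples.
#' @param n_new Number of synthetic samples (default 1920, growing 80 to
#'   2000).
#' @param alpha_low,alpha_high Bounds of the mixing-weight distribution.
#' @param seed Integer seed.
#' @return A [spectra_dataset()] with `nrow(train) + n_new` samples.
#' @export
augment_spectra <- function(train, n_new = 1920L, alpha_low = 0.1,
                            alpha_high = 0.9, seed = 1L) {
  stopifnot(inherits(train, "spectra_dataset"), n_new >= 0)
  if (!(alpha_low > 0 && alpha_low < alpha_high && alpha_high < 1)) {
    stop("require 0 < alpha_low < alpha_high < 1", call. = FALSE)
  }
  if (n_new == 0L) return(train)
  n <- nrow(train$X)
  if (n < 2L) stop("need at least 2 training samples to interpolate",
                   call. = FALSE)
  withr::with_seed(seed, {
    Xn <- matrix(0, n_new, ncol(train$X))
    Yn <- matrix(0, n_new, 4L)
    ids <- character(n_new)
    for (m in seq_len(n_new)) {
      pr <- sample.int(n, 2L) # without replacement: distinct parents
      a <- stats::runif(1L, alpha_low, alpha_high)
      Xn[m, ] <- a * train$X[pr[1L], ] + (1 - a) * train$X[pr[2L], ]
      Yn[m, ] <- a * train$Y[pr[1L], ] + (1 - a) * train$Y[pr[2L], ]
      ids[m] <- sprintf("aug%05d|%s|%s|a=%.4f", m, train$sample_ids[pr[1L]],
                        train$sample_ids[pr[2L]], a)
    }
    spectra_dataset(rbind(train$X, Xn), rbind(train$Y, Yn), train$grid,
                    c(train$sample_ids, ids))
  })
}
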