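# Composite multi-task loss, one-cycle learning-rate policy, AdamW with
# global-norm gradient clipping, and early stopping on validation loss.

#' Composite loss configuration
#'
#' `L = alpha * L_MSE + beta * L_L1 + gamma * L_weighted` where `L_MSE` is
#' the mean squared Euclidean norm of the 4-vector residual, `L_L1` the
#' mean L1 norm, and `L_weighted` the task-weighted per-task mean squared
#' error with weights `w = (1.2, 1.0, 1.5, 2.0)` for (moisture, starch,
#' oil, protein).
#'
#' @param alpha,beta,gamma Nonnegative term coefficients (at least one
#'   positive).
#' @param task_weights Positive length-4 task weights.
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha = 1.0, beta = 0.2, gamma = 0.5,
                        task_weights = c(1.2, 1.0, 1.5, 2.0)) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, alpha + beta + gamma > 0,
            length(task_weights) == 4L, all(task_weights > 0))
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 task_weights = task_weights), class = "loss_config")
}

#' Composite multi-task loss
#'
#' @param y_hat,y `N x 4` matrices of predictions and targets.
#' @param cfg A [loss_config()].
#' @return List with `total` and the three `components` (mse, l1, weighted).
#' @examples
#' composite_loss(matrix(c(1, 0, 0, 0), 1), matrix(0, 1, 4))$total # 3.2
#' @export
composite_loss <- function(y_hat, y, cfg = loss_config(1, 1, 1)) {
  y_hat <- as.matrix(y_hat); y <- as.matrix(y)
  if (!all(dim(y_hat) == dim(y))) {
    stop("shape mismatch between predictions and targets", call. = FALSE)
  }
  r <- y_hat - y
  n <- nrow(r)
  mse <- sum(r^2) / n
  l1 <- sum(abs(r)) / n
  weighted <- sum(colSums(r^2) / n * cfg$task_weights)
  list(total = cfg$alpha * mse + cfg$beta * l1 + cfg$gamma * weighted,
       components = c(mse = mse, l1 = l1, weighted = weighted))
}

# Tape version used inside the training loop.
tp_composite_loss <- function(tape, y_hat, y_leaf, cfg) {
  r <- tp_sub(tape, y_hat, y_leaf)
  n <- nrow(tp_value(tape, r))
  mse <- tp_scale(tape, tp_sum(tape, tp_square(tape, r)), 1 / n)
  l1 <- tp_scale(tape, tp_sum(tape, tp_abs(tape, r)), 1 / n)
  wleaf <- tp_leaf(tape, matrix(cfg$loss$task_weights, n, 4L, byrow = TRUE))
  wt <- tp_scale(tape, tp_sum(tape, tp_mul(tape, tp_square(tape, r), wleaf)),
                 1 / n)
  total <- tp_add(tape, tp_scale(tape, mse, cfg$loss$alpha),
                  tp_add(tape, tp_scale(tape, l1, cfg$loss$beta),
                         tp_scale(tape, wt, cfg$loss$gamma)))
  list(total = total, mse = mse, l1 = l1, weighted = wt)
}

#' Training configuration
#'
#' @param max_epochs Epoch budget.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without validation improvement (improvement = best - 1e-6).
#' @param clip_norm Global gradient-norm clip threshold.
#' @param eta_min,eta_max One-cycle learning-rate bounds.
#' @param warmup_frac Fraction of steps in the linear warmup ramp.
#' @param batch_size Minibatch size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param seed Seed controlling init-independent training randomness (data
#'   order, dropout).
#' @param standardize_targets Z-score targets on the training split for
#'   optimization (predictions are de-standardized back to percent units).
#' @param standardize_inputs Center each spectral channel on its
#'   training-split mean and scale all channels by the pooled spectral
#'   standard deviation (stored in the model and applied by `predict()`).
#'   NIR spectra vary by a few milli-absorbance around a large common
#'   baseline, so without this preconditioning gradient training stalls at
#'   the target mean; the pooled (rather than per-channel) scale preserves
#'   the relative intensities of absorption bands instead of amplifying
#'   uninformative channels.
#' @param loss A [loss_config()].
#' @param loss_goal Optional training-loss threshold: stop once the epoch
#'   training loss falls below it (used for overfitting sanity checks).
#' @return A `train_config` object.
#' @export
train_config <- function(max_epochs = 250L, patience = 30L, clip_norm = 1.0,
                         eta_min = 1e-5, eta_max = 1e-3, warmup_frac = 0.2,
                         batch_size = 32L, weight_decay = 1e-4, seed = 1L,
                         standardize_targets = TRUE,
                         standardize_inputs = TRUE, loss = loss_config(),
                         loss_goal = NULL) {
  stopifnot(eta_min < eta_max, warmup_frac > 0, warmup_frac < 1,
            max_epochs >= 1, patience >= 1, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), clip_norm = clip_norm,
                 eta_min = eta_min, eta_max = eta_max,
                 warmup_frac = warmup_frac,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 standardize_targets = standardize_targets,
                 standardize_inputs = standardize_inputs, loss = loss,
                 loss_goal = loss_goal),
            class = "train_config")
}

#' One-cycle learning rate
#'
#' Linear ramp from `eta_min` to `eta_max` over the first `warmup_frac` of
#' steps, then cosine annealing back to `eta_min`:
#' `eta = eta_min + (eta_max - eta_min)/2 * (1 + cos(pi * t'/T))`.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps Total number of optimizer steps.
#' @param cfg A [train_config()].
#' @return Learning rate (vectorized over `step`).
#' @export
one_cycle_lr <- function(step, total_steps, cfg = train_config()) {
  stopifnot(all(step >= 0), all(step < total_steps))
  Tw <- floor(cfg$warmup_frac * total_steps)
  Tann <- max(total_steps - 1L - Tw, 1L)
  ifelse(step <= Tw,
         cfg$eta_min + (cfg$eta_max - cfg$eta_min) *
           (if (Tw > 0) step / Tw else 1),
         cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
           (1 + cos(pi * (step - Tw) / Tann)))
}

# AdamW update in place; returns list(params, m, v).
adamw_step <- function(params, grads, m, v, t, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- 0 * params[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g * g
    mhat <- m[[nm]] / b1t
    vhat <- v[[nm]] / b2t
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, m = m, v = v)
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), 0)))
}

#' Train a model
#'
#' Minibatch AdamW with one-cycle learning-rate scheduling, global
#' gradient-norm clipping, per-epoch validation and early stopping; the
#' parameters from the best validation epoch are restored in the returned
#' model. Fully deterministic given `cfg$seed`. Losses are computed on the
#' standardized target scale when `cfg$standardize_targets` is on.
#'
#' @param model An untrained (or warm) `spectral_model`.
#' @param train_ds,val_ds Training and validation [spectra_dataset()]s.
#' @param cfg A [train_config()].
#' @return A `spectral_fit`: list with the fitted `model` and a per-epoch
#'   `history` tibble (losses, learning rate, post-clip gradient norms).
#' @export
train_model <- function(model, train_ds, val_ds, cfg = train_config()) {
  stopifnot(inherits(model, "spectral_model"),
            inherits(train_ds, "spectra_dataset"),
            inherits(val_ds, "spectra_dataset"))
  if (nrow(train_ds$X) == 0 || nrow(val_ds$X) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  check_channels(model, train_ds$X)
  n <- nrow(train_ds$X)
  if (cfg$standardize_targets) {
    mu <- colMeans(train_ds$Y)
    sdv <- pmax(apply(train_ds$Y, 2L, stats::sd), 1e-12)
  } else {
    mu <- rep(0, 4L); sdv <- rep(1, 4L)
  }
  model$scaler <- list(mean = mu, sd = sdv)
  Ytr <- sweep(sweep(train_ds$Y, 2L, mu, `-`), 2L, sdv, `/`)
  Yva <- sweep(sweep(val_ds$Y, 2L, mu, `-`), 2L, sdv, `/`)
  if (cfg$standardize_inputs) {
    xm <- colMeans(train_ds$X)
    pooled <- sqrt(mean(apply(train_ds$X, 2L, stats::var)))
    if (!is.finite(pooled) || pooled < 1e-12) pooled <- 1
    model$x_scaler <- list(mean = xm, sd = rep(pooled, ncol(train_ds$X)))
  }
  Xtr <- scale_inputs(model, train_ds$X)
  Xva <- scale_inputs(model, val_ds$X)

  steps_per_epoch <- ceiling(n / cfg$batch_size)
  total_steps <- cfg$max_epochs * steps_per_epoch
  m <- lapply(model$params, function(p) 0 * p)
  v <- m
  best <- Inf; best_params <- model$params
  best_buffers <- as.list(model$buffers)
  best_epoch <- 0L; bad_epochs <- 0L; t_step <- 0L
  hist <- vector("list", cfg$max_epochs)
  grad_norms <- numeric(0)

  eval_loss <- function(X, Y) {
    tape <- tape_new(4096L)
    yid <- model_forward(model, X, tape, training = FALSE)
    composite_loss(tp_value(tape, yid), Y, cfg$loss)
  }

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      ep_tot <- ep_mse <- ep_l1 <- ep_wt <- 0
      for (s in seq_len(steps_per_epoch)) {
        idx <- perm[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n)]
        tape <- tape_new(8192L)
        yid <- model_forward(model, Xtr[idx, , drop = FALSE], tape,
                             training = TRUE)
        yleaf <- tp_leaf(tape, Ytr[idx, , drop = FALSE])
        ls <- tp_composite_loss(tape, yid, yleaf, cfg)
        tot <- tp_value(tape, ls$total)[1L]
        if (!is.finite(tot)) {
          stop(sprintf("non-finite training loss at epoch %d, batch %d",
                       epoch, s), call. = FALSE)
        }
        w <- length(idx) / n
        ep_tot <- ep_tot + w * tot
        ep_mse <- ep_mse + w * tp_value(tape, ls$mse)[1L]
        ep_l1 <- ep_l1 + w * tp_value(tape, ls$l1)[1L]
        ep_wt <- ep_wt + w * tp_value(tape, ls$weighted)[1L]
        grads_all <- tape_backward(tape, ls$total)
        # collect parameter gradients by leaf position (params are pushed
        # first, in order, by every model_forward method)
        grads <- stats::setNames(grads_all[seq_along(model$params)],
                                 names(model$params))
        gn <- global_grad_norm(grads)
        if (gn > cfg$clip_norm && gn > 0) {
          sc <- cfg$clip_norm / gn
          grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * sc)
          gn <- cfg$clip_norm
        }
        grad_norms <- c(grad_norms, gn)
        t_step <- t_step + 1L
        lr <- one_cycle_lr(t_step - 1L, total_steps, cfg)
        upd <- adamw_step(model$params, grads, m, v, t_step, lr,
                          cfg$weight_decay)
        model$params <- upd$params; m <- upd$m; v <- upd$v
      }
      val <- eval_loss(Xva, Yva)$total
      if (val < best - 1e-6) {
        best <- val; best_params <- model$params
        best_buffers <- as.list(model$buffers)
        best_epoch <- epoch; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_tot, val_loss = val,
        lr = one_cycle_lr(t_step - 1L, total_steps, cfg),
        mse = ep_mse, l1 = ep_l1, weighted = ep_wt)
      if (bad_epochs >= cfg$patience) break
      if (!is.null(cfg$loss_goal) && ep_mse < cfg$loss_goal) break
    }
  })

  model$params <- best_params
  for (nm in names(best_buffers)) model$buffers[[nm]] <- best_buffers[[nm]]
  history <- dplyr::bind_rows(hist[!vapply(hist, is.null, TRUE)])
  model$meta$epochs_seen <- nrow(history)
  model$meta$best_val_loss <- best
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 stopped_epoch = nrow(history), grad_norms = grad_norms,
                 config = cfg),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(paste0("<spectral_fit> %s: %d epochs (best %d), ",
                     "best val loss %.4g\n"),
              x$model$kind, x$stopped_epoch, x$best_epoch,
              x$model$meta$best_val_loss))
  invisible(x)
}
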