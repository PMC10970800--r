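# Patch-based training: L1 objective on [0,1]-scaled intensities, Adam
# updates, exponential step decay of the learning rate, seeded per-epoch
# shuffling, last incomplete batch dropped.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with beta1 = 0.9,
#' beta2 = 0.999, epsilon = 1e-8; initial learning rate 2e-4 decayed by a
#' factor of 0.1 every 120 epochs; batch size 32. The total epoch count is
#' not part of the recipe and defaults to 300.
#'
#' @param lr0 Initial learning rate.
#' @param decay_factor Multiplicative decay, in (0, 1].
#' @param decay_every Epochs between decays.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size Patches per update step.
#' @param n_epochs Number of passes over the patch set.
#' @param seed Seed for the per-epoch shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 2e-4, decay_factor = 0.1, decay_every = 120L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         batch_size = 32L, n_epochs = 300L, seed = 1L) {
  if (decay_factor <= 0 || decay_factor > 1) {
    stopf("`decay_factor` must lie in (0, 1]")
  }
  if (batch_size < 1L) stopf("`batch_size` must be >= 1")
  if (n_epochs < 1L) stopf("`n_epochs` must be >= 1")
  structure(list(lr0 = lr0, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Mean absolute (L1) difference between two image batches
#'
#' @param pred,target Numeric arrays of identical shape (single images,
#'   matrices, or batched 4-D arrays).
#' @return Mean absolute difference over all pixels.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target)) {
    stopf("`pred` and `target` must have identical shapes")
  }
  mean(abs(pred - target))
}

#' Learning rate at a given (0-based) epoch
#'
#' `lr0 * decay_factor^floor(epoch / decay_every)`: piecewise constant with
#' breaks exactly at multiples of `decay_every`.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(epoch, cfg) {
  if (any(epoch < 0)) stopf("`epoch` must be >= 0")
  cfg$lr0 * cfg$decay_factor^floor(epoch / cfg$decay_every)
}

# Walk params/grads/moment trees in lockstep and apply one Adam update.
adam_update <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (k in keys) {
      r <- adam_update(p[[k]], g[[k]], m[[k]], v[[k]], lr, b1, b2, eps, t)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    p <- p - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, m = m, v = v)
}

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

#' Train a super-resolution model on LR/HR patch pairs
#'
#' Patches are scaled to \[0, 1\] for optimization; the recorded per-epoch
#' loss is converted back to intensity units (0-255 scale). Shuffling,
#' initialization and updates are all seeded, so a rerun with identical
#' seeds reproduces the fit exactly (same platform and op order).
#'
#' @param model A [model_config()] (a fresh model is built from it) or an
#'   existing `sr_model` to continue training.
#' @param pairs List of patch pairs from [extract_patch_pairs()]; every
#'   pair's HR side must be `scale` times its LR side, matching the model.
#' @param cfg_train A [train_config()]. At least one full batch of pairs is
#'   required (the last incomplete batch is dropped).
#' @return List with `model` (the trained `sr_model`) and `history`, a
#'   data frame with per-epoch mean L1 loss (intensity units) and learning
#'   rate.
#' @export
train_sr <- function(model, pairs, cfg_train) {
  if (inherits(model, "sr_config")) model <- build_sr_model(model)
  if (!inherits(model, "sr_model")) {
    stopf("`model` must be a model_config() or sr_model")
  }
  if (!inherits(cfg_train, "train_config")) {
    stopf("`cfg_train` must come from train_config()")
  }
  cfg <- model$config
  a <- cfg$scale
  n <- length(pairs)
  p <- nrow(pairs[[1L]]$lr)
  ok <- vapply(pairs, function(pr) {
    all(dim(pr$lr) == p) && all(dim(pr$hr) == a * p)
  }, logical(1))
  if (!all(ok)) {
    stopf("patch pair(s) %s do not match the model scale x%d (LR %dx%d -> HR %dx%d expected)",
          paste(utils::head(which(!ok), 3L), collapse = ", "), a, p, p,
          a * p, a * p)
  }
  bs <- cfg_train$batch_size
  n_batches <- n %/% bs
  if (n_batches < 1L) {
    stopf("%d pairs make no complete batch of %d", n, bs)
  }
  X <- array(0, c(p, p, n, 1L))
  Y <- array(0, c(a * p, a * p, n, 1L))
  for (i in seq_len(n)) {
    X[, , i, 1L] <- pairs[[i]]$lr / 255
    Y[, , i, 1L] <- pairs[[i]]$hr / 255
  }
  params <- model$params
  m <- tree_zero(params)
  v <- tree_zero(params)
  t <- 0L
  loss_hist <- numeric(cfg_train$n_epochs)
  lr_hist <- numeric(cfg_train$n_epochs)
  for (epoch in seq_len(cfg_train$n_epochs)) {
    lr_e <- lr_at_epoch(epoch - 1L, cfg_train)
    perm <- with_seed(cfg_train$seed + epoch, sample.int(n))
    eloss <- 0
    for (b in seq_len(n_batches)) {
      ii <- perm[((b - 1L) * bs + 1L):(b * bs)]
      xb <- X[, , ii, , drop = FALSE]
      yb <- Y[, , ii, , drop = FALSE]
      fw <- net_forward(params, cfg, xb)
      diff <- fw$out - yb
      eloss <- eloss + mean(abs(diff))
      dout <- sign(diff) / length(diff)
      grads <- net_backward(dout, fw$cache, params, cfg)
      t <- t + 1L
      st <- adam_update(params, grads, m, v, lr_e,
                        cfg_train$beta1, cfg_train$beta2,
                        cfg_train$epsilon, t)
      params <- st$p; m <- st$m; v <- st$v
    }
    loss_hist[epoch] <- eloss / n_batches * 255
    lr_hist[epoch] <- lr_e
  }
  model$params <- params
  list(model = model,
       history = data.frame(epoch = seq_len(cfg_train$n_epochs),
                            loss = loss_hist, lr = lr_hist))
}
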