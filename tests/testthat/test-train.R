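test_that("l1_loss is the mean absolute difference", {
  a <- matrix(0, 4, 4); b <- matrix(255, 4, 4)
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(a, b), 255)
  set.seed(1)
  p <- matrix(runif(4, 0, 255), 2); q <- matrix(runif(4, 0, 255), 2)
  expect_equal(l1_loss(p, q),
               (abs(p[1, 1] - q[1, 1]) + abs(p[2, 1] - q[2, 1]) +
                  abs(p[1, 2] - q[1, 2]) + abs(p[2, 2] - q[2, 2])) / 4)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("the learning-rate schedule is a step-decayed exponential", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 2e-4)
  expect_equal(lr_at_epoch(119, cfg), 2e-4)
  expect_equal(lr_at_epoch(120, cfg), 2e-5)
  expect_equal(lr_at_epoch(240, cfg), 2e-6)
  flat <- train_config(decay_factor = 1)
  expect_equal(lr_at_epoch(c(0, 500, 5000), flat), rep(2e-4, 3))
  expect_error(lr_at_epoch(-1, cfg), ">= 0")
  # non-increasing, piecewise constant, breaks exactly at multiples of 120
  lrs <- lr_at_epoch(0:360, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_identical(which(diff(lrs) < 0), c(120L, 240L, 360L))
})

test_that("training runs the stated number of updates and is reproducible", {
  spec <- degradation_spec(2, seed = 1)
  pairs <- phantom_pairs(1, 32, spec, seed_base = 1)
  cfg <- tiny_cfg(seed = 2)
  tc <- train_config(n_epochs = 1, seed = 3)
  fit <- train_sr(cfg, pairs, tc)
  expect_equal(nrow(fit$history), 1L)   # 32 pairs / batch 32 = 1 update
  expect_named(fit$history, c("epoch", "loss", "lr"))
  refit <- train_sr(cfg, pairs, tc)
  expect_identical(fit$history$loss, refit$history$loss)
  expect_identical(fit$model$params, refit$model$params)
  # pairs at the wrong scale are rejected against the model
  cfg4 <- model_config(1, 1, 8, scale = 4, ca_reduction = 4)
  expect_error(train_sr(cfg4, pairs, tc), "scale")
  expect_error(train_sr(cfg, pairs[1:10], tc), "batch")
})

test_that("a short run reduces the training loss", {
  spec <- degradation_spec(2, seed = 1)
  pairs <- phantom_pairs(2, 48, spec, seed_base = 5)
  fit <- train_sr(tiny_cfg(seed = 1), pairs,
                  train_config(n_epochs = 6, seed = 1))
  expect_lt(fit$history$loss[6], fit$history$loss[1])
  expect_equal(fit$history$lr, rep(2e-4, 6))
})

test_that("a single clean patch is memorized within 500 steps", {
  ph <- generate_phantom(phantom_spec(seed = 5, texture_sigma = 0))
  spec <- degradation_spec(2, seed = 1)
  pair <- extract_patch_pairs(ph, spec, lr_patch = 16, stride = 7,
                              max_pairs = 1, seed = 2)
  # desk-scale rate (see vignette): 500 single-patch updates, not the
  # reference run's hundred-thousand
  fit <- train_sr(tiny_cfg(seed = 1), pair,
                  train_config(lr0 = 1e-3, batch_size = 1, n_epochs = 500,
                               seed = 1))
  expect_lt(min(fit$history$loss), 1)
})

test_that("analytic gradient of a three-parameter toy layer passes a central difference check", {
  set.seed(9)
  x <- array(runif(5 * 5 * 2), c(5, 5, 1, 2))   # two input channels
  w <- array(rnorm(2, 0, 0.3), c(1, 1, 2, 1))
  b <- 0.1
  tg <- array(runif(5 * 5), c(5, 5, 1, 1))
  loss <- function(w, b) {
    mean(abs(rirsr:::.conv2d_fwd(x, w, b, FALSE) - tg))
  }
  pred <- rirsr:::.conv2d_fwd(x, w, b, FALSE)
  dout <- sign(pred - tg) / length(pred)
  g <- rirsr:::.conv2d_bwd(x, w, dout, FALSE, FALSE)
  h <- 1e-7
  for (i in 1:2) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    num <- (loss(wp, b) - loss(wm, b)) / (2 * h)
    expect_lt(abs(num - g$dw[i]) / max(abs(num), abs(g$dw[i])), 1e-4)
  }
  num_b <- (loss(w, b + h) - loss(w, b - h)) / (2 * h)
  expect_lt(abs(num_b - g$db) / max(abs(num_b), abs(g$db)), 1e-4)
})

test_that("checkpoints round-trip bit-identically and validate their contents", {
  m <- build_sr_model(tiny_cfg(use_channel_attention = TRUE, seed = 4))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  img <- matrix(runif(16 * 16, 0, 255), 16)
  expect_identical(sr_forward(m, img), sr_forward(m2, img))
  expect_equal(m2$n_parameters, count_parameters(m2$config))
  expect_error(load_checkpoint(path, expected_scale = 4), "scale")
  expect_error(load_checkpoint(file.path(tempdir(), "nope.ckpt")), "exist")
  writeLines("not a checkpoint", path2 <- withr::local_tempfile())
  expect_error(load_checkpoint(path2), "header")
  # truncated tensor data is caught
  lines <- readLines(path)
  ti <- grep("^tensor ", lines)[1]
  lines[ti + 1] <- "1 2 3"
  writeLines(lines, path3 <- withr::local_tempfile())
  expect_error(load_checkpoint(path3), "corrupt")
})
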