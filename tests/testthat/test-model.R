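test_that("conv kernels agree with a plain-loop convolution", {
  set.seed(42)
  x <- array(rnorm(6 * 5 * 2 * 3), c(6, 5, 2, 3))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  ref <- oracle_conv(x, w, b)
  expect_equal(rirsr:::.conv2d_fwd(x, w, b, FALSE), ref, tolerance = 1e-12)
  expect_equal(rirsr:::.conv2d_fwd(x, w, b, TRUE), ref, tolerance = 1e-4)
  w1 <- array(rnorm(1 * 1 * 3 * 2), c(1, 1, 3, 2))
  expect_equal(rirsr:::.conv2d_fwd(x, w1, numeric(2), FALSE),
               oracle_conv(x, w1, numeric(2)), tolerance = 1e-12)
})

test_that("forward honors the scale contract at x2, x4 and x8", {
  img16 <- matrix(runif(16 * 16, 0, 255), 16)
  img32 <- matrix(runif(32 * 32, 0, 255), 32)
  m4 <- build_sr_model(model_config(2, 2, 8, scale = 4, ca_reduction = 4, seed = 1))
  expect_equal(dim(sr_forward(m4, img16)), c(64L, 64L))
  m2 <- build_sr_model(tiny_cfg(seed = 1))
  expect_equal(dim(sr_forward(m2, img32)), c(64L, 64L))
  m8 <- build_sr_model(model_config(1, 1, 8, scale = 8, ca_reduction = 4, seed = 1))
  expect_equal(dim(sr_forward(m8, img16)), c(128L, 128L))
  # fully convolutional: an odd input size also works
  expect_equal(dim(sr_forward(m4, matrix(runif(21 * 17, 0, 255), 21, 17))),
               c(84L, 68L))
  out1 <- sr_forward(m4, img16)
  expect_identical(out1, sr_forward(m4, img16))
  expect_true(all(out1 >= 0 & out1 <= 255))
})

test_that("zero weights reduce the network to its skip pathways", {
  cfg <- tiny_cfg(seed = 1)
  m <- build_sr_model(cfg)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  # zero residual block on zero input with the skip connection is zero
  bp0 <- zero_params(m$params$groups[[1]]$blocks[[1]])
  z <- array(0, c(8, 8, 2, 8))
  expect_equal(residual_block(z, bp0, cfg), z)
  # with a zeroed trunk, deep features + LSC equal the shallow map exactly
  p <- m$params
  p$groups <- zero_params(p$groups)
  p$trunk_fuse <- zero_params(p$trunk_fuse)
  fw <- rirsr:::net_forward(p, cfg, x)
  zsf <- rirsr:::cv_fwd(x, p$sf, TRUE)
  up_in <- fw$cache$up_in[[1]]
  expect_equal(up_in, zsf, tolerance = 1e-12)
  # an entirely zero network outputs exactly zero
  fw0 <- rirsr:::net_forward(zero_params(m$params), cfg, x)
  expect_true(all(fw0$out == 0))
})

test_that("fusion widths match the reference configuration", {
  cfg <- model_config()   # 4 groups x 4 blocks, f = 64
  m <- build_sr_model(cfg)
  expect_equal(dim(m$params$groups[[1]]$fuse$w)[3], 320L)  # (4+1)*64
  expect_equal(dim(m$params$trunk_fuse$w)[3], 256L)        # 4*64
  expect_equal(dim(m$params$groups[[2]]$blocks[[3]]$fuse$w)[3], 192L)  # 3*64
})

test_that("count_parameters matches hand enumeration and flag monotonicity", {
  cfg <- tiny_cfg(use_channel_attention = FALSE, use_concat_fusion = TRUE)
  f <- 8
  hand <- (9 * 1 + 1) * f +                     # shallow 3x3, 1 -> f
    ((1 * f + 1) * f + (9 * f + 1) * f + (25 * f + 1) * f +  # branches
       (3 * f + 1) * f) +                       # block fusion 3f -> f
    ((2 * f) + 1) * f +                         # group fusion (1+1)f -> f
    (f + 1) * f +                               # trunk fusion 1*f -> f
    (9 * f + 1) * (4 * f) +                     # pre-shuffle conv, x2
    (9 * f + 1) * 1                             # output conv
  expect_equal(count_parameters(cfg), hand)
  expect_equal(build_sr_model(cfg)$n_parameters, hand)
  ca_on <- tiny_cfg(use_channel_attention = TRUE)
  expect_equal(count_parameters(ca_on) - count_parameters(cfg),
               2 * f^2 / 4 + f + f / 4)
  no_cc <- tiny_cfg(use_concat_fusion = FALSE)
  expect_equal(count_parameters(cfg) - count_parameters(no_cc),
               (3 * f + 1) * f)
  # Table-style variant ordering where containment holds
  n <- function(ca, cc) count_parameters(tiny_cfg(use_channel_attention = ca,
                                                  use_concat_fusion = cc))
  expect_true(n(TRUE, TRUE) > n(FALSE, TRUE))
  expect_true(n(FALSE, TRUE) > n(FALSE, FALSE))
  expect_true(n(TRUE, FALSE) > n(FALSE, FALSE))
})

test_that("channel attention gates constant inputs by a (0,1) scalar per channel", {
  set.seed(3)
  f <- 8
  cp <- rirsr:::with_seed(5, rirsr:::init_ca(f, 4, 0.2))
  x <- array(rep(1:f, each = 6 * 6), c(6, 6, f))   # constant per channel
  out <- channel_attention(x, cp)
  ratio <- out / x
  per_ch <- apply(ratio, 3, function(m) diff(range(m)))
  expect_lt(max(per_ch), 1e-12)
  g <- apply(ratio, 3, mean)
  expect_true(all(g > 0 & g < 1))
  # zero weights: logistic(0) = 0.5 exactly
  cp0 <- zero_params(cp)
  expect_equal(channel_attention(x, cp0), x * 0.5, tolerance = 1e-15)
  expect_error(channel_attention(array(1, c(4, 4, 3)), cp), "channels")
})

test_that("pixel shuffle rearranges and inverts exactly", {
  x <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16 * 2))
  y <- pixel_shuffle(x, 4)
  expect_equal(dim(y), c(64L, 64L, 2L))
  expect_equal(pixel_unshuffle(y, 4), x)
  expect_error(pixel_shuffle(array(1, c(4, 4, 6)), 2), "divisible")
  # shuffle places channel c = dc + s*dr + s^2*m at HR offset (dr, dc)
  z <- array(0, c(2, 2, 4))
  z[1, 1, ] <- 1:4
  s <- pixel_shuffle(z, 2)
  expect_equal(s[1:2, 1:2, 1], matrix(c(1, 3, 2, 4), 2))
})

test_that("weight initialization is seed-deterministic and count-consistent", {
  a <- build_sr_model(tiny_cfg(seed = 11))
  b <- build_sr_model(tiny_cfg(seed = 11))
  expect_identical(a$params, b$params)
  c <- build_sr_model(tiny_cfg(seed = 12))
  expect_false(identical(a$params, c$params))
  expect_error(residual_block(array(1, c(8, 8, 1, 4)),
                              a$params$groups[[1]]$blocks[[1]],
                              a$config), "channels")
  expect_error(model_config(n_filters = 10, use_channel_attention = TRUE,
                            ca_reduction = 4), "divisible")
})

test_that("analytic gradients match finite differences through every variant", {
  variants <- list(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE),
                   c(FALSE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
  for (v in variants) {
    cfg <- model_config(1, 2, 4, scale = 2, use_channel_attention = v[1],
                        use_concat_fusion = v[2], use_skip = v[3],
                        ca_reduction = 2, precision = "double", seed = 3)
    m <- build_sr_model(cfg)
    set.seed(7)
    xin <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
    tg <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
    fw <- rirsr:::net_forward(m$params, cfg, xin)
    dout <- sign(fw$out - tg) / length(fw$out)
    gr <- rirsr:::net_backward(dout, fw$cache, m$params, cfg)
    fg <- rirsr:::flatten_params(gr)
    fp <- rirsr:::flatten_params(m$params)
    h <- 1e-6
    for (trial in 1:12) {
      nm <- sample(names(fp), 1)
      idx <- sample(length(fp[[nm]]), 1)
      path <- strsplit(nm, ".", fixed = TRUE)[[1]]
      lossat <- function(delta) {
        q <- fp[[nm]]; q[idx] <- q[idx] + delta
        p2 <- rirsr:::assign_path(m$params, path, as.vector(q))
        mean(abs(rirsr:::net_forward(p2, cfg, xin)$out - tg))
      }
      num <- (lossat(h) - lossat(-h)) / (2 * h)
      ana <- fg[[nm]][idx]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("the exposed network stages compose to the full forward pass", {
  m <- build_sr_model(model_config(2, 2, 8, scale = 4, ca_reduction = 4,
                                   seed = 6))
  img <- matrix(runif(16 * 16, 0, 255), 16)
  sf <- shallow_extract(m, img)
  expect_equal(dim(sf), c(16L, 16L, 8L))
  g1 <- residual_group(sf, m$params$groups[[1]], m$config)
  expect_equal(dim(g1), dim(sf))
  deep <- rir_forward(m, sf)
  expect_equal(dim(deep), dim(sf))
  out <- upscale_features(m, deep)
  expect_identical(out, sr_forward(m, img))
  expect_error(rir_forward(m, array(1, c(8, 8, 3))), "channels")
})
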