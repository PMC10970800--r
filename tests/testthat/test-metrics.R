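test_that("mse and psnr satisfy their analytic cases", {
  z <- matrix(0, 8, 8); f <- matrix(255, 8, 8)
  expect_equal(mse(z, z), 0)
  expect_equal(mse(z, f), 65025)
  m <- matrix(c(1, 2, 3, 4), 2); n <- matrix(c(2, 0, 6, 1), 2)
  expect_equal(mse(m, n), (1 + 4 + 9 + 9) / 4)
  expect_equal(psnr(z, f), 0)
  expect_identical(psnr(m, m), Inf)
  one_diff <- matrix(0, 2, 2); one_diff[1, 1] <- 255
  expect_equal(mse(matrix(0, 2, 2), one_diff), 16256.25)
  expect_equal(psnr(matrix(0, 2, 2), one_diff), 20 * log10(2), tolerance = 1e-10)
  expect_error(mse(z, matrix(0, 8, 9)), "shape")
})

test_that("ssim matches its closed forms and the brute-force oracle", {
  set.seed(10)
  x <- matrix(runif(16 * 16, 0, 255), 16)
  expect_equal(ssim(x, x), 1)
  # constant images: variance terms vanish, contrast factor cancels
  p <- ssim_params()
  c1v <- matrix(40, 16, 16); c2v <- matrix(90, 16, 16)
  expect_equal(ssim(c1v, c2v),
               (2 * 40 * 90 + p$c1) / (40^2 + 90^2 + p$c1), tolerance = 1e-12)
  for (w in c("gaussian", "uniform")) {
    pw <- ssim_params(window = w, window_size = if (w == "gaussian") 11L else 8L)
    for (i in 1:5) {
      a <- matrix(runif(16 * 16, 0, 255), 16)
      b <- pmin(pmax(a + rnorm(256, 0, 20), 0), 255)
      expect_equal(ssim(a, b, pw), oracle_ssim(a, b, pw), tolerance = 1e-8)
      expect_equal(ssim(a, b, pw), ssim(b, a, pw))
    }
  }
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("msim composes per-scale ssim as a weighted geometric mean", {
  set.seed(11)
  x <- matrix(runif(64 * 64, 0, 255), 64)
  y <- pmin(pmax(x + rnorm(64 * 64, 0, 15), 0), 255)
  p2 <- ssim_params(n_scales = 2)
  expect_equal(msim(x, x, p2), 1)
  p1 <- ssim_params(n_scales = 1, scale_weights = 1)
  expect_equal(msim(x, y, p1), ssim(x, y, p1))
  expect_equal(msim(x, y, p2), oracle_msim(x, y, p2), tolerance = 1e-10)
  pw <- ssim_params(n_scales = 2, scale_weights = c(2, 0.5))
  expect_equal(msim(x, y, pw), oracle_msim(x, y, pw), tolerance = 1e-10)
  expect_error(msim(x, y, ssim_params(n_scales = 4)), "scales")
  expect_error(ssim_params(n_scales = 3, scale_weights = c(1, 1)), "length")
})

test_that("psnr decreases monotonically with added noise amplitude", {
  x <- generate_phantom(phantom_spec(seed = 6))
  noise <- rirsr:::with_seed(8, matrix(rnorm(length(x)), nrow(x)))
  vals <- vapply(c(1, 3, 7, 15), function(a) psnr(x, rirsr:::clip255(x + a * noise)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("evaluation reports paired model and bicubic rows with means", {
  hrs <- generate_set(3, phantom_spec(64, 64, seed = 2))
  spec <- degradation_spec(4, seed = 1)
  p <- ssim_params(n_scales = 2)
  m1 <- build_sr_model(model_config(1, 1, 8, scale = 4, ca_reduction = 4, seed = 1))
  m2 <- build_sr_model(model_config(1, 1, 8, scale = 4, ca_reduction = 4, seed = 99))
  e1 <- evaluate_sr(m1, hrs, spec, p)
  e2 <- evaluate_sr(m2, hrs, spec, p)
  # baseline rows are model-independent
  expect_identical(e1$baseline, e2$baseline)
  expect_false(identical(e1$model, e2$model))
  expect_equal(nrow(e1$model), 3L)
  expect_equal(e1$summary$psnr[1], mean(e1$model$psnr))
  expect_equal(e1$summary$msim[2], mean(e1$baseline$msim))
  expect_true(all(is.finite(unlist(e1$summary[-1]))))
  expect_error(evaluate_sr(build_sr_model(tiny_cfg()), hrs, spec, p), "scale")
})
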