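test_that("bicubic shrink has the stated fixed points and sizes", {
  img <- matrix(runif(64 * 64, 0, 255), 64)
  expect_equal(dim(bicubic_resize(img, 1 / 4)), c(16L, 16L))
  expect_identical(bicubic_resize(img, 1), img)
  cimg <- matrix(100, 48, 40)
  for (s in c(1 / 4, 1 / 2, 2, 3)) {
    expect_equal(bicubic_resize(cimg, s),
                 matrix(100, round(48 * s), round(40 * s)), tolerance = 1e-12)
  }
  expect_error(bicubic_resize(img, 0), "positive")
  expect_error(bicubic_resize(img, -2), "positive")
})

test_that("antialiased shrink of a ramp matches per-site kernel evaluation", {
  ramp <- matrix(rep(seq(0, 255, length.out = 64), each = 64), 64, 64)
  out <- bicubic_resize(ramp, 1 / 4, antialias = TRUE)
  expected <- oracle_resample_1d(seq(0, 255, length.out = 64), 1 / 4)
  expect_equal(as.vector(out[8, ]), expected, tolerance = 1e-8)
  # interior columns of the shrunk ramp sit within 1 unit of the
  # subsampled ramp itself
  u <- (1:16) * 4 - 1.5
  ideal <- (u - 1) * 255 / 63
  expect_lt(max(abs(out[8, 3:14] - ideal[3:14])), 1)
  # antialias widening actually changes the result on textured content
  tex <- rirsr:::with_seed(2, matrix(runif(64 * 64, 0, 255), 64))
  expect_false(identical(bicubic_resize(tex, 1 / 4, TRUE),
                         bicubic_resize(tex, 1 / 4, FALSE)))
})

test_that("salt-and-pepper corruption follows its Bernoulli model", {
  img <- matrix(128, 100, 100)
  expect_identical(add_salt_pepper(img, 0, seed = 1), img)
  all_c <- add_salt_pepper(img, 1, seed = 1)
  expect_true(all(all_c %in% c(0, 255)))
  for (d in c(0.005, 0.01, 0.02)) {
    out <- add_salt_pepper(img, d, seed = 42)
    n_corrupt <- sum(out != 128)
    expect_gte(n_corrupt, qbinom(0.0005, 1e4, d))
    expect_lte(n_corrupt, qbinom(0.9995, 1e4, d))
  }
  expect_identical(add_salt_pepper(img, 0.01, seed = 9),
                   add_salt_pepper(img, 0.01, seed = 9))
  expect_error(add_salt_pepper(img, 1.5), "\\[0, 1\\]")
})

test_that("make_lr composes shrink and corruption in the stated order", {
  hr <- generate_phantom(phantom_spec(64, 64, seed = 2))
  clean <- make_lr(hr, degradation_spec(4, 0, seed = 1))
  expect_identical(clean, bicubic_resize(hr, 1 / 4))
  expect_equal(dim(make_lr(generate_phantom(phantom_spec(128, 128, seed = 2)),
                           degradation_spec(8))), c(16L, 16L))
  spec <- degradation_spec(4, 0.01, seed = 3)
  expect_identical(make_lr(hr, spec), make_lr(hr, spec))
  # noise lands on the LR image only, after downsampling
  noisy <- make_lr(hr, spec)
  hits <- noisy != clean
  expect_true(all(noisy[hits] %in% c(0, 255)))
  expect_error(make_lr(hr[1:63, ], degradation_spec(4)), "divisible")
  expect_error(degradation_spec(3), "2, 4, 8")
  expect_error(degradation_spec(4, -0.1), "\\[0, 1\\]")
})

test_that("patch pairs enumerate, subsample and align exactly", {
  hr <- generate_phantom(phantom_spec(128, 128, seed = 4))
  spec <- degradation_spec(4, seed = 1)
  expect_error(extract_patch_pairs(hr[1:70, 1:70], spec), "divisible")
  all_pairs <- extract_patch_pairs(hr, spec, lr_patch = 16, stride = 1,
                                   max_pairs = 1e6)
  expect_length(all_pairs, (32 - 16 + 1)^2)
  capped <- extract_patch_pairs(hr, spec, lr_patch = 16, stride = 1,
                                max_pairs = 100, seed = 7)
  expect_length(capped, 100)
  expect_identical(capped,
                   extract_patch_pairs(hr, spec, lr_patch = 16, stride = 1,
                                       max_pairs = 100, seed = 7))
  lr <- make_lr(hr, spec)
  for (pr in capped) {
    expect_equal(dim(pr$lr), c(16L, 16L))
    expect_equal(dim(pr$hr), c(64L, 64L))
    o <- pr$origin
    expect_identical((o - 1L) %% 4L, c(row = 0L, col = 0L))
    lo <- (o - 1L) / 4L + 1L
    expect_identical(pr$hr, hr[o["row"]:(o["row"] + 63L),
                               o["col"]:(o["col"] + 63L)])
    expect_identical(pr$lr, lr[lo["row"]:(lo["row"] + 15L),
                               lo["col"]:(lo["col"] + 15L)])
  }
  expect_error(extract_patch_pairs(hr, spec, lr_patch = 64), "exceeds")
})
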