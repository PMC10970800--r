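# Fidelity metrics on the 0-255 intensity scale: MSE, PSNR, windowed SSIM
# and a multi-scale SSIM combination (weighted geometric mean across dyadic
# scales).

#' Parameters for the structural-similarity family of metrics
#'
#' `C1 = (k1 * L)^2` and `C2 = (k2 * L)^2` stabilize the SSIM ratios when
#' the denominators approach zero. Local statistics use an 11x11 Gaussian
#' window (sigma 1.5), the standard SSIM practice; a uniform window is
#' available as an option. The multi-scale variant combines per-scale SSIM
#' values as `(prod_i SSIM_i^alpha_i)^(1/N)` over `n_scales` dyadic scales
#' with equal unit weights by default.
#'
#' @param dynamic_range Peak intensity `L` (255 for 8-bit images).
#' @param k1,k2 SSIM stabilization constants (0.01, 0.03).
#' @param window `"gaussian"` or `"uniform"`.
#' @param window_size Window side (11 for Gaussian, 8 is the usual uniform
#'   choice).
#' @param window_sigma Gaussian window sigma.
#' @param n_scales Number of dyadic scales `N` for [msim()].
#' @param scale_weights Per-scale exponents `alpha_i`; length `n_scales`.
#' @return An object of class `ssim_params`.
#' @export
ssim_params <- function(dynamic_range = 255, k1 = 0.01, k2 = 0.03,
                        window = c("gaussian", "uniform"),
                        window_size = 11L, window_sigma = 1.5,
                        n_scales = 5L, scale_weights = rep(1, n_scales)) {
  window <- match.arg(window)
  n_scales <- as.integer(n_scales)
  if (length(scale_weights) != n_scales) {
    stopf("`scale_weights` must have length n_scales = %d", n_scales)
  }
  if (k1 <= 0 || k2 <= 0) stopf("`k1` and `k2` must be positive")
  structure(list(dynamic_range = dynamic_range, k1 = k1, k2 = k2,
                 c1 = (k1 * dynamic_range)^2, c2 = (k2 * dynamic_range)^2,
                 window = window, window_size = as.integer(window_size),
                 window_sigma = window_sigma, n_scales = n_scales,
                 scale_weights = as.numeric(scale_weights)),
            class = "ssim_params")
}

#' Mean squared error between two images
#'
#' @param x,y Numeric matrices of equal shape, 0-255 scale.
#' @return Mean of squared pixel differences.
#' @export
mse <- function(x, y) {
  check_gray(x, "x"); check_gray(y, "y")
  if (!identical(dim(x), dim(y))) stopf("`x` and `y` must have equal shapes")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX` the dynamic range (255). Identical
#' images (MSE = 0) return `Inf`, the sentinel for perfect reconstruction.
#'
#' @param x,y Numeric matrices of equal shape.
#' @param params An [ssim_params()] (supplies the dynamic range).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, params = ssim_params()) {
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(params$dynamic_range^2 / m)
}

window_vector <- function(params) {
  s <- params$window_size
  if (params$window == "gaussian") {
    t <- seq_len(s) - (s + 1) / 2
    k <- exp(-t^2 / (2 * params$window_sigma^2))
  } else {
    k <- rep(1, s)
  }
  k / sum(k)
}

# Valid-mode separable filtering: (n_out x n_in) banded matrix per axis.
filter_matrix <- function(n, kern) {
  s <- length(kern)
  m <- matrix(0, n - s + 1L, n)
  for (i in seq_len(n - s + 1L)) m[i, i:(i + s - 1L)] <- kern
  m
}

#' Structural similarity index (SSIM)
#'
#' Local means, variances and covariance are computed at every valid window
#' position with the configured window; the SSIM ratio is evaluated per
#' position and averaged. The result lies in \[-1, 1\], 1 meaning identical
#' images.
#'
#' @param x,y Numeric matrices of equal shape, at least the window size.
#' @param params An [ssim_params()].
#' @return Mean SSIM over window positions.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  check_gray(x, "x"); check_gray(y, "y")
  if (!identical(dim(x), dim(y))) stopf("`x` and `y` must have equal shapes")
  s <- params$window_size
  if (nrow(x) < s || ncol(x) < s) {
    stopf("image %dx%d is smaller than the %dx%d window",
          nrow(x), ncol(x), s, s)
  }
  kern <- window_vector(params)
  fr <- filter_matrix(nrow(x), kern)
  fc <- t(filter_matrix(ncol(x), kern))
  filt <- function(m) fr %*% m %*% fc
  mx <- filt(x); my <- filt(y)
  sxx <- filt(x * x) - mx * mx
  syy <- filt(y * y) - my * my
  sxy <- filt(x * y) - mx * my
  num <- (2 * mx * my + params$c1) * (2 * sxy + params$c2)
  den <- (mx * mx + my * my + params$c1) * (sxx + syy + params$c2)
  mean(num / den)
}

# 2x2 mean pooling (odd trailing row/column cropped).
dyadic_downsample <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  0.25 * (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
          m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
          m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
          m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)])
}

#' Multi-scale structural similarity (MSIM)
#'
#' SSIM is evaluated on the image pair and on `n_scales - 1` successive
#' 2x-downsampled versions (2x2 mean pooling); the per-scale values are
#' combined as the weighted geometric mean
#' `(prod_i SSIM_i^alpha_i)^(1/N)`. With `n_scales = 1` and unit weight it
#' reduces to plain SSIM. Higher is better.
#'
#' @param x,y Numeric matrices of equal shape, large enough to survive
#'   `n_scales - 1` halvings above the window size.
#' @param params An [ssim_params()].
#' @return The multi-scale similarity value.
#' @export
msim <- function(x, y, params = ssim_params()) {
  check_gray(x, "x"); check_gray(y, "y")
  if (!identical(dim(x), dim(y))) stopf("`x` and `y` must have equal shapes")
  n <- params$n_scales
  smallest <- floor(min(dim(x)) / 2^(n - 1))
  if (smallest < params$window_size) {
    stopf("image %dx%d cannot support %d dyadic scales with a %d-pixel window",
          nrow(x), ncol(x), n, params$window_size)
  }
  vals <- numeric(n)
  for (i in seq_len(n)) {
    vals[i] <- ssim(x, y, params)
    if (i < n) {
      x <- dyadic_downsample(x)
      y <- dyadic_downsample(y)
    }
  }
  prod(vals^params$scale_weights)^(1 / n)
}
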