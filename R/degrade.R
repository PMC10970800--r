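# HR -> LR forward model: antialiased bicubic shrink by a power-of-two
# factor, then optional salt-and-pepper corruption of the LR image (the HR
# ground truth is never corrupted), plus aligned LR/HR patch-pair
# extraction for training.

#' Specification of the HR-to-LR degradation
#'
#' @param scale Downsampling factor, one of 2, 4, 8.
#' @param noise_density Salt-and-pepper density `d` in \[0, 1\]; each LR
#'   pixel is independently corrupted with probability `d` and set to 0 or
#'   255 with equal probability. The reference noise levels are 0, 0.005,
#'   0.01 and 0.02.
#' @param seed Integer seed driving the noise draw.
#' @param antialias Use the widened (antialiased) bicubic kernel on shrink.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(scale, noise_density = 0, seed = 1L,
                             antialias = TRUE) {
  scale <- as.integer(scale)
  if (!scale %in% c(2L, 4L, 8L)) {
    stopf("`scale` must be one of 2, 4, 8 (powers of two); got %s", scale)
  }
  if (noise_density < 0 || noise_density > 1) {
    stopf("`noise_density` must lie in [0, 1]")
  }
  structure(list(scale = scale, noise_density = as.numeric(noise_density),
                 seed = as.integer(seed), antialias = isTRUE(antialias)),
            class = "degradation_spec")
}

#' Add salt-and-pepper noise
#'
#' Each pixel is independently corrupted with probability `density`; a
#' corrupted pixel becomes 0 (pepper) or 255 (salt) with equal probability.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @param density Corruption probability in \[0, 1\].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Corrupted copy of `img`.
#' @export
add_salt_pepper <- function(img, density, seed = 1L) {
  check_gray(img)
  if (!is.numeric(density) || length(density) != 1L ||
      density < 0 || density > 1) {
    stopf("`density` must be a single value in [0, 1]")
  }
  if (density == 0) return(img)
  with_seed(seed, {
    hit <- runif(length(img)) < density
    val <- ifelse(runif(length(img)) < 0.5, 0, 255)
    out <- img
    out[hit] <- val[hit]
    out
  })
}

#' Apply the full degradation forward model
#'
#' Bicubic shrink by `1/scale` (antialiased when `spec$antialias` is set), then
#' salt-and-pepper noise at the configured density (skipped when 0). Noise
#' is applied after downsampling, to the LR image only.
#'
#' @param hr Numeric HR matrix; both dimensions must be divisible by
#'   `spec$scale`.
#' @param spec A [degradation_spec()].
#' @return The LR numeric matrix, `dim(hr) / scale`.
#' @export
make_lr <- function(hr, spec) {
  check_gray(hr, "hr")
  if (!inherits(spec, "degradation_spec")) {
    stopf("`spec` must be a degradation_spec")
  }
  if (any(dim(hr) %% spec$scale != 0L)) {
    stopf("HR dimensions %dx%d are not divisible by scale %d",
          nrow(hr), ncol(hr), spec$scale)
  }
  lr <- bicubic_resize(hr, 1 / spec$scale, antialias = spec$antialias)
  if (spec$noise_density > 0) {
    lr <- add_salt_pepper(lr, spec$noise_density, spec$seed)
  }
  lr
}

#' Extract aligned LR/HR patch pairs for training
#'
#' The LR image is computed once with [make_lr()]; candidate LR origins are
#' enumerated on a `stride` grid and each pair carries the aligned
#' `scale*p x scale*p` HR patch. If the enumeration exceeds `max_pairs`, a
#' seeded uniform subsample of exactly `max_pairs` pairs is returned.
#'
#' @param hr Numeric HR matrix, divisible by `spec$scale`.
#' @param spec A [degradation_spec()].
#' @param lr_patch LR patch side `p` (the reference setup uses 16, giving
#'   64x64 ground-truth patches at x4).
#' @param stride Enumeration stride on the LR grid (reference setup: 1).
#' @param max_pairs Cap on returned pairs (reference setup: 102400).
#' @param seed Seed for the subsample draw.
#' @return List of pairs; each has elements `lr` (p x p), `hr`
#'   (scale*p x scale*p) and `origin`, the 1-based `(row, col)` of the HR
#'   patch's top-left corner (so the LR origin is `(origin - 1)/scale + 1`).
#' @export
extract_patch_pairs <- function(hr, spec, lr_patch = 16L, stride = 1L,
                                max_pairs = 102400L, seed = 1L) {
  check_gray(hr, "hr")
  lr_patch <- as.integer(lr_patch); stride <- as.integer(stride)
  if (lr_patch < 1L || stride < 1L) stopf("`lr_patch` and `stride` must be >= 1")
  lr <- make_lr(hr, spec)   # also validates divisibility
  a <- spec$scale
  if (lr_patch > min(dim(lr))) {
    stopf("lr_patch %d exceeds the %dx%d LR image", lr_patch,
          nrow(lr), ncol(lr))
  }
  rr <- seq.int(1L, nrow(lr) - lr_patch + 1L, by = stride)
  cc <- seq.int(1L, ncol(lr) - lr_patch + 1L, by = stride)
  origins <- expand.grid(row = rr, col = cc, KEEP.OUT.ATTRS = FALSE)
  if (nrow(origins) > max_pairs) {
    keep <- with_seed(seed, sample.int(nrow(origins), max_pairs))
    origins <- origins[sort(keep), , drop = FALSE]
  }
  lapply(seq_len(nrow(origins)), function(i) {
    r <- origins$row[i]; c <- origins$col[i]
    hr_r <- (r - 1L) * a + 1L; hr_c <- (c - 1L) * a + 1L
    list(lr = lr[r:(r + lr_patch - 1L), c:(c + lr_patch - 1L)],
         hr = hr[hr_r:(hr_r + a * lr_patch - 1L),
                 hr_c:(hr_c + a * lr_patch - 1L)],
         origin = c(row = hr_r, col = hr_c))
  })
}
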