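# Seeded synthetic radiograph-like phantoms.
#
# Real chest radiographs are dominated by smooth low-frequency anatomy with
# periodic rib-like bands, occasional compact bright opacities and fine
# grain. The phantom reproduces those statistics cheaply: a sum of a few
# broad Gaussians (anatomy), a gently warped sinusoid (bands), small
# Gaussian bumps (lesion-like blobs) and zero-mean white texture, clipped
# to the 8-bit range. Everything is deterministic in the seed.

#' Specification of a synthetic radiograph-like phantom
#'
#' @param height,width Image size in pixels; each must be at least 64 and
#'   divisible by 8 so that x2/x4/x8 degradation is exact.
#' @param seed Integer seed; identical specs give pixel-identical phantoms.
#' @param n_bands Number of rib-like periodic bands (0 disables).
#' @param n_blobs Number of bright lesion-like spots (0 disables).
#' @param texture_sigma Standard deviation of the fine-grain texture, in
#'   intensity units (>= 0; 0 disables).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, seed = 1L,
                         n_bands = 8L, n_blobs = 6L, texture_sigma = 2) {
  height <- as.integer(height); width <- as.integer(width)
  for (nm in c("height", "width")) {
    v <- get(nm)
    if (is.na(v) || v < 64L || v %% 8L != 0L) {
      stopf("`%s` must be >= 64 and divisible by 8 (so x2/x4/x8 downsampling is exact); got %s",
            nm, v)
    }
  }
  if (texture_sigma < 0) stopf("`texture_sigma` must be >= 0")
  if (n_bands < 0 || n_blobs < 0) stopf("`n_bands` and `n_blobs` must be >= 0")
  structure(list(height = height, width = width, seed = as.integer(seed),
                 n_bands = as.integer(n_bands), n_blobs = as.integer(n_blobs),
                 texture_sigma = as.numeric(texture_sigma)),
            class = "phantom_spec")
}

#' Generate a synthetic radiograph-like phantom
#'
#' Composition: smooth low-frequency field (sum of a few broad Gaussians
#' over a constant base) + periodic slightly-warped bands + sparse bright
#' blobs + zero-mean fine texture, clipped to \[0, 255\]. The result is kept
#' in floating point; quantization to 8 bits happens only in
#' [write_gray_png()].
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix `height x width` with values in \[0, 255\].
#' @export
#' @examples
#' img <- generate_phantom(phantom_spec(128, 128, seed = 7))
#' range(img)
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  h <- spec$height; w <- spec$width
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  with_seed(spec$seed, {
    img <- matrix(20, h, w)
    for (i in 1:3) {   # broad anatomy-like bumps
      cy <- runif(1, 0.25, 0.75) * h
      cx <- runif(1, 0.25, 0.75) * w
      sg <- runif(1, 0.25, 0.45) * min(h, w)
      amp <- runif(1, 50, 90)
      img <- img + amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
    }
    # thorax-like region with a sharp boundary: real radiographs are full
    # of crisp anatomical edges, which is precisely the content plain
    # interpolation cannot recover
    ecy <- runif(1, 0.45, 0.55) * h
    ecx <- runif(1, 0.45, 0.55) * w
    ea <- runif(1, 0.30, 0.40) * h
    eb <- runif(1, 0.26, 0.36) * w
    img <- img + 60 * (((yy - ecy) / ea)^2 + ((xx - ecx) / eb)^2 <= 1)
    if (spec$n_bands > 0L) {
      phase <- runif(1, 0, 2 * pi)
      # quasi-square band profile: sharp rib-like transitions, not a pure
      # sinusoid, so the bands carry genuine high-frequency structure
      img <- img + 20 * tanh(2.5 * sin(2 * pi * spec$n_bands * yy / h +
                                         phase + 0.5 * sin(2 * pi * xx / w)))
    }
    if (spec$n_blobs > 0L) {
      for (i in seq_len(spec$n_blobs)) {
        cy <- runif(1, 0.1, 0.9) * h
        cx <- runif(1, 0.1, 0.9) * w
        sg <- runif(1, 2, 5)
        amp <- runif(1, 30, 50)   # lesion-like peak ~40 intensity units
        img <- img + amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
      }
    }
    if (spec$texture_sigma > 0) {
      img <- img + matrix(rnorm(h * w, 0, spec$texture_sigma), h, w)
    }
    clip255(img)
  })
}

#' Generate a deterministic set of phantoms
#'
#' Image `i` uses the derived seed `seed + i - 1`, so `generate_set(1, spec,
#' seed = s)` reproduces `generate_phantom()` at seed `s` exactly.
#'
#' @param n Number of images (>= 1).
#' @param spec_template A [phantom_spec()] whose seed field is overridden
#'   per image.
#' @param seed Base seed for the set; defaults to the template's seed.
#' @return List of `n` numeric matrices.
#' @export
generate_set <- function(n, spec_template, seed = spec_template$seed) {
  if (!inherits(spec_template, "phantom_spec")) {
    stopf("`spec_template` must be a phantom_spec")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stopf("`n` must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- spec_template
    s$seed <- as.integer(seed + i - 1L)
    generate_phantom(s)
  })
}
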