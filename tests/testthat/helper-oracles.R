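# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package's vectorized implementations.

# Keys cubic (a = -0.5), written out again independently
oracle_cubic <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# direct per-site resampling of a vector with the (widened) cubic kernel,
# symmetric boundary, normalized weights
oracle_resample_1d <- function(v, scale, antialias = TRUE) {
  n_in <- length(v)
  n_out <- round(n_in * scale)
  kscale <- if (antialias && scale < 1) scale else 1
  supp <- 2 / kscale
  aux <- c(seq_len(n_in), rev(seq_len(n_in)))
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    u <- i / scale + 0.5 * (1 - 1 / scale)
    taps <- floor(u - supp):ceiling(u + supp)
    w <- kscale * oracle_cubic(kscale * (u - taps))
    idx <- aux[((taps - 1) %% (2 * n_in)) + 1]
    out[i] <- sum(w * v[idx]) / sum(w)
  }
  out
}

oracle_window <- function(params) {
  s <- params$window_size
  if (params$window == "gaussian") {
    t <- seq_len(s) - (s + 1) / 2
    g <- exp(-t^2 / (2 * params$window_sigma^2))
    g <- g / sum(g)
    outer(g, g)
  } else {
    matrix(1 / s^2, s, s)
  }
}

# windowed SSIM via an explicit double loop over window positions
oracle_ssim <- function(x, y, params) {
  s <- params$window_size
  wm <- oracle_window(params)
  c1 <- (params$k1 * params$dynamic_range)^2
  c2 <- (params$k2 * params$dynamic_range)^2
  nr <- nrow(x) - s + 1
  nc <- ncol(x) - s + 1
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      xs <- x[i:(i + s - 1), j:(j + s - 1)]
      ys <- y[i:(i + s - 1), j:(j + s - 1)]
      mx <- sum(wm * xs); my <- sum(wm * ys)
      vx <- sum(wm * xs * xs) - mx^2
      vy <- sum(wm * ys * ys) - my^2
      cxy <- sum(wm * xs * ys) - mx * my
      vals[i, j] <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
        ((mx^2 + my^2 + c1) * (vx + vy + c2))
    }
  }
  mean(vals)
}

# 2x2 mean pooling, loop form
oracle_pool2 <- function(m) {
  h <- nrow(m) %/% 2; w <- ncol(m) %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    }
  }
  out
}

oracle_msim <- function(x, y, params) {
  vals <- numeric(params$n_scales)
  for (i in seq_len(params$n_scales)) {
    vals[i] <- oracle_ssim(x, y, params)
    if (i < params$n_scales) {
      x <- oracle_pool2(x)
      y <- oracle_pool2(y)
    }
  }
  prod(vals^params$scale_weights)^(1 / params$n_scales)
}

# plain-loop same-padded convolution on an (h, w, n, ci) batch
oracle_conv <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; pad <- (k - 1) / 2; co <- dim(w)[4]
  y <- array(0, c(d[1], d[2], d[3], co))
  for (n in seq_len(d[3])) for (o in seq_len(co)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- b[o]
      for (c in seq_len(d[4])) for (dr in seq_len(k)) for (dc in seq_len(k)) {
        ii <- i + dr - 1 - pad; jj <- j + dc - 1 - pad
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
          s <- s + x[ii, jj, n, c] * w[dr, dc, c, o]
        }
      }
      y[i, j, n, o] <- s
    }
  }
  y
}

# patch pairs pooled from several phantoms (training fixture)
phantom_pairs <- function(n_phantoms, per_phantom, spec, seed_base,
                         lr_patch = 16, phantom_seed_base = 100) {
  unlist(lapply(seq_len(n_phantoms), function(i) {
    ph <- generate_phantom(phantom_spec(seed = phantom_seed_base + i - 1))
    extract_patch_pairs(ph, spec, lr_patch = lr_patch, stride = 1,
                        max_pairs = per_phantom, seed = seed_base + i)
  }), recursive = FALSE)
}

tiny_cfg <- function(...) {
  model_config(n_groups = 1L, n_blocks = 1L, n_filters = 8L, scale = 2L,
               ca_reduction = 4L, ...)
}

zero_params <- function(p) rapply(p, function(x) x * 0, how = "replace")
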