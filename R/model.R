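# Residual-in-residual super-resolution network.
#
# Architecture: a single 3x3 shallow-feature convolution; a trunk of
# `n_groups` residual groups, each a chain of `n_blocks` inception-style
# residual blocks (parallel 1x1 / 3x3 / 5x5 convolutions, each followed by
# LeakyReLU, fused by concatenation + 1x1 convolution) with dense feature
# fusion at group level (block outputs plus group input concatenated, 1x1
# fused); group outputs concatenated and 1x1-fused, then a long skip
# connection adds the shallow features; finally a pixel-shuffle upscaler
# (3x3 conv to scale^2 * f channels, sub-pixel rearrangement, 3x3 conv to
# one channel).
#
# Forward and backward passes are written explicitly (no autodiff); the
# convolutions run through the im2col/GEMM kernels in src/conv_ops.cpp.
# Feature maps are 4-D arrays (h, w, batch, channels).

#' Network architecture configuration
#'
#' The reference configuration is 4 residual groups of 4 residual blocks at
#' 64 filters. The three ablation flags reproduce the block variants of the
#' ablation study; the default (attention off, concatenation fusion on,
#' skip connection on) is the proposed model.
#'
#' @param n_groups Number of residual groups (reference: 4).
#' @param n_blocks Residual blocks per group (reference: 4).
#' @param n_filters Feature channels `f` (reference: 64).
#' @param scale Super-resolution factor, one of 2, 4, 8.
#' @param leaky_slope Negative slope of every LeakyReLU (default 0.2, a
#'   common super-resolution choice).
#' @param use_channel_attention Gate each block's fused features with a
#'   squeeze-excitation-style channel attention unit.
#' @param use_concat_fusion Fuse the three parallel branches by
#'   concatenation + 1x1 convolution (`TRUE`) or by summation (`FALSE`).
#' @param use_skip Add the block input back onto the fused features.
#' @param ca_reduction Channel-reduction ratio of the attention bottleneck;
#'   must divide `n_filters` when attention is on.
#' @param upscale_mode `"single"`: one conv to `scale^2 * f` channels and
#'   one shuffle; `"cascade"`: repeated x2 conv+shuffle stages.
#' @param precision `"single"` runs the convolution GEMMs in float32 (the
#'   usual deep-learning arithmetic, about twice as fast); `"double"` keeps
#'   everything in float64 (useful for finite-difference checks).
#' @param seed Seed for the He-style weight initialization.
#' @return An object of class `sr_config`.
#' @export
model_config <- function(n_groups = 4L, n_blocks = 4L, n_filters = 64L,
                         scale = 4L, leaky_slope = 0.2,
                         use_channel_attention = FALSE,
                         use_concat_fusion = TRUE, use_skip = TRUE,
                         ca_reduction = 16L,
                         upscale_mode = c("single", "cascade"),
                         precision = c("single", "double"),
                         seed = 1L) {
  scale <- as.integer(scale)
  if (!scale %in% c(2L, 4L, 8L)) stopf("`scale` must be one of 2, 4, 8")
  n_groups <- as.integer(n_groups); n_blocks <- as.integer(n_blocks)
  n_filters <- as.integer(n_filters); ca_reduction <- as.integer(ca_reduction)
  if (n_groups < 1L || n_blocks < 1L || n_filters < 1L) {
    stopf("`n_groups`, `n_blocks`, `n_filters` must all be >= 1")
  }
  if (isTRUE(use_channel_attention) && n_filters %% ca_reduction != 0L) {
    stopf("`n_filters` (%d) must be divisible by `ca_reduction` (%d) when attention is on",
          n_filters, ca_reduction)
  }
  structure(list(n_groups = n_groups, n_blocks = n_blocks,
                 n_filters = n_filters, scale = scale,
                 leaky_slope = as.numeric(leaky_slope),
                 use_channel_attention = isTRUE(use_channel_attention),
                 use_concat_fusion = isTRUE(use_concat_fusion),
                 use_skip = isTRUE(use_skip),
                 ca_reduction = ca_reduction,
                 upscale_mode = match.arg(upscale_mode),
                 precision = match.arg(precision),
                 seed = as.integer(seed)),
            class = "sr_config")
}

upscale_stage_factors <- function(cfg) {
  if (cfg$upscale_mode == "single") cfg$scale else
    rep(2L, as.integer(log2(cfg$scale)))
}

# ---- parameter initialization -------------------------------------------

RESIDUAL_INIT_SCALE <- 0.1   # block residual branches start small
SURFACE_INIT_SCALE <- 0.01   # trunk fusion / output perturbations start tiny

# He-style fan-in init; `gain` follows the layer's role: sqrt(2/(1+s^2))
# before a LeakyReLU, 1 for purely linear layers (fusions, upscaler,
# output) so repeated linear stages neither inflate nor shrink variance.
init_conv <- function(k, ci, co, slope = NULL, scale = 1) {
  gain <- if (is.null(slope)) 1 else sqrt(2 / (1 + slope^2))
  sd <- scale * gain / sqrt(k * k * ci)
  list(w = array(rnorm(k * k * ci * co, 0, sd), c(k, k, ci, co)),
       b = numeric(co))
}

init_ca <- function(f, r, slope) {
  gain <- sqrt(2 / (1 + slope^2))
  list(w1 = matrix(rnorm(f / r * f, 0, gain / sqrt(f)), f / r, f),
       b1 = numeric(f / r),
       w2 = matrix(rnorm(f * f / r, 0, gain / sqrt(f / r)), f, f / r),
       b2 = numeric(f))
}

# Interpolating 3x3 kernel for sub-pixel phase (dr, dc) of an x`s`
# shuffle: after the pixel shuffle, the channel holding this kernel's
# output lands on HR position (s*i + dr, s*j + dc), whose center sits at
# LR coordinate i + u with u = (dr + 0.5)/s - 0.5 and |u| < 1/2, so the
# three-tap Lagrange (quadratic) interpolation weights per axis are
# exact on locally quadratic intensity profiles.
interp_phase_kernel <- function(dr, dc, s) {
  axis <- function(d) {
    u <- (d + 0.5) / s - 0.5
    c(u * (u - 1) / 2, 1 - u^2, u * (u + 1) / 2)
  }
  outer(axis(dr), axis(dc))
}

init_params <- function(cfg) {
  f <- cfg$n_filters; sl <- cfg$leaky_slope
  with_seed(cfg$seed, {
    p <- list(sf = init_conv(3L, 1L, f))
    # feature channel 1 starts as the raw image (identity tap), giving the
    # interpolating initialization below a clean signal to upsample
    p$sf$w[, , 1L, 1L] <- 0
    p$sf$w[2L, 2L, 1L, 1L] <- 1
    # each block starts near the identity (its residual branch is scaled
    # down), the standard batchnorm-free stabilization for deep residual
    # super-resolution trunks: without it the repeated skip additions and
    # dense fusions inflate activation variance and the first epochs are
    # spent recovering from a wild output scale
    rs <- RESIDUAL_INIT_SCALE
    ss <- SURFACE_INIT_SCALE
    p$groups <- lapply(seq_len(cfg$n_groups), function(g) {
      blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
        bs <- if (cfg$use_concat_fusion) 1 else rs
        bp <- list(c1 = init_conv(1L, f, f, sl, bs),
                   c3 = init_conv(3L, f, f, sl, bs),
                   c5 = init_conv(5L, f, f, sl, bs))
        if (cfg$use_concat_fusion) bp$fuse <- init_conv(1L, 3L * f, f, scale = rs)
        if (cfg$use_channel_attention) {
          bp$ca <- init_ca(f, cfg$ca_reduction, sl)
        }
        bp
      })
      list(blocks = blocks,
           fuse = init_conv(1L, (cfg$n_blocks + 1L) * f, f))
    })
    # the trunk starts as a small perturbation on top of the long skip
    # connection, so the initial deep-feature output is ~ the shallow map
    p$trunk_fuse <- init_conv(1L, cfg$n_groups * f, f, scale = ss)
    # Upscaler initialization, the classical deconvolution-as-interpolation
    # scheme: every feature channel is upsampled depthwise with the exact
    # quadratic sub-pixel phase kernels, and channels beyond the image
    # channel additionally carry an ICNR-style random component (one base
    # filter bank shared by all s^2 shuffle positions, checkerboard-free).
    # Composed with the identity taps in `sf` and `out`, the untrained
    # network therefore already implements a quadratic interpolator that
    # training refines, instead of having to discover upsampling from
    # random weights.
    p$up <- lapply(upscale_stage_factors(cfg), function(s) {
      w <- array(0, c(3L, 3L, f, s^2 * f))
      icnr <- init_conv(3L, f, f)$w
      for (mm in seq_len(f)) {
        for (dr in 0:(s - 1L)) {
          for (dc in 0:(s - 1L)) {
            ch <- dc + s * dr + (mm - 1L) * s^2 + 1L
            w[, , mm, ch] <- interp_phase_kernel(dr, dc, s)
            if (mm > 1L) w[, , , ch] <- w[, , , ch] + icnr[, , , mm]
          }
        }
      }
      list(w = w, b = numeric(s^2 * f))
    })
    p$out <- init_conv(3L, f, 1L, scale = ss)
    p$out$w[, , 1L, 1L] <- 0
    p$out$w[2L, 2L, 1L, 1L] <- 1
    p
  })
}

#' Instantiate a super-resolution model with seeded weights
#'
#' Convolutions use He-style fan-in scaling with the gain matched to each
#' layer's role (LeakyReLU branches vs linear fusions); residual branches
#' start scaled down, and the upscaler starts as an exact quadratic
#' sub-pixel interpolator (see the package vignette for the full
#' initialization scheme). Biases start at zero. The draw is
#' deterministic in `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return An object of class `sr_model` with elements `config`, `params`
#'   and `n_parameters`.
#' @export
build_sr_model <- function(cfg) {
  if (!inherits(cfg, "sr_config")) stopf("`cfg` must come from model_config()")
  params <- init_params(cfg)
  m <- structure(list(config = cfg, params = params), class = "sr_model")
  m$n_parameters <- sum(vapply(flatten_params(params), length, integer(1)))
  stopifnot(m$n_parameters == count_parameters(cfg))
  m
}

#' @export
print.sr_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sr_model> x%d | %d groups x %d blocks, f = %d | CA %s, concat %s, skip %s | %s parameters\n",
    cfg$scale, cfg$n_groups, cfg$n_blocks, cfg$n_filters,
    if (cfg$use_channel_attention) "on" else "off",
    if (cfg$use_concat_fusion) "on" else "off",
    if (cfg$use_skip) "on" else "off",
    format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# Flatten a nested parameter list into a flat named list of numeric leaves.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    v <- p[[nm]]
    if (is.list(v)) {
      if (is.null(names(v))) names(v) <- as.character(seq_along(v))
      out <- c(out, flatten_params(v, key))
    } else {
      out[[key]] <- v
    }
  }
  out
}

#' Closed-form parameter count for a configuration
#'
#' Computed from layer shapes alone; [build_sr_model()] asserts that the
#' instantiated weights match this count.
#'
#' @param cfg A [model_config()].
#' @return Integer-valued count.
#' @export
count_parameters <- function(cfg) {
  f <- cfg$n_filters
  conv_n <- function(k, ci, co) (k * k * ci + 1) * co
  block <- conv_n(1, f, f) + conv_n(3, f, f) + conv_n(5, f, f)
  if (cfg$use_concat_fusion) block <- block + conv_n(1, 3 * f, f)
  if (cfg$use_channel_attention) {
    r <- cfg$ca_reduction
    block <- block + 2 * f^2 / r + f + f / r
  }
  group <- cfg$n_blocks * block + conv_n(1, (cfg$n_blocks + 1) * f, f)
  total <- conv_n(3, 1, f) +                      # shallow extraction
    cfg$n_groups * group +
    conv_n(1, cfg$n_groups * f, f) +              # trunk fusion
    sum(vapply(upscale_stage_factors(cfg),
               function(s) conv_n(3, f, s^2 * f), numeric(1))) +
    conv_n(3, f, 1)                               # output projection
  as.numeric(total)
}

# ---- primitive layers ----------------------------------------------------
# Feature arrays are (h, w, n, c): batch third, channels outermost, so the
# GEMM-based convolutions and channel concatenation are copy-free.

cv_fwd <- function(x, p, single = FALSE) .conv2d_fwd(x, p$w, p$b, single)
cv_bwd <- function(x, p, dy, need_dx = TRUE, single = FALSE) {
  .conv2d_bwd(x, p$w, dy, need_dx, single)
}

lrelu <- function(z, slope) .lrelu_fwd(z, slope)
# dy * d/dz LeakyReLU(z)
lrelu_dmul <- function(dy, z, slope) .lrelu_bwd(dy, z, slope)

#' Sub-pixel (pixel-shuffle) rearrangement
#'
#' Rearranges an `(h, w, scale^2 * m)` feature map into
#' `(scale*h, scale*w, m)`; the inverse (`pixel_unshuffle`) performs the
#' space-to-depth rearrangement and exactly undoes it.
#'
#' @param x 3-D array `(h, w, c)` with `c` divisible by `scale^2`.
#' @param scale Integer upscaling factor.
#' @return The rearranged 3-D array.
#' @export
pixel_shuffle <- function(x, scale) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] %% scale^2 != 0L) {
    stopf("`x` must be (h, w, c) with c divisible by scale^2")
  }
  dim(x) <- c(d[1L], d[2L], 1L, d[3L])   # same memory order, batch of 1
  y <- ps_fwd(x, scale)
  dy <- dim(y)
  array(y, dy[c(1L, 2L, 4L)])
}

#' @rdname pixel_shuffle
#' @export
pixel_unshuffle <- function(x, scale) {
  d <- dim(x)
  if (length(d) != 3L || any(d[1:2] %% scale != 0L)) {
    stopf("`x` must be (h, w, c) with h, w divisible by scale")
  }
  dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  y <- ps_bwd(x, scale)
  dy <- dim(y)
  array(y, dy[c(1L, 2L, 4L)])
}

# (h, w, n, a^2*m) -> (a*h, a*w, n, m) and its exact inverse (C++).
ps_fwd <- function(x, a) .ps_fwd(x, as.integer(a))
ps_bwd <- function(y, a) .ps_bwd(y, as.integer(a))

#' Channel attention gate
#'
#' Squeeze-excitation-style gating: global spatial average per channel, a
#' bottleneck 1x1 projection to `c / reduction` units with LeakyReLU, a 1x1
#' projection back to `c` units, a logistic gate in (0, 1), and channel-wise
#' rescaling of the input.
#'
#' @param x 3-D `(h, w, c)` or 4-D `(h, w, n, c)` feature array.
#' @param params List with `w1` (`c/r x c`), `b1`, `w2` (`c x c/r`), `b2`.
#' @param leaky_slope Negative slope of the bottleneck activation.
#' @return Gated array, same shape as `x`.
#' @export
channel_attention <- function(x, params, leaky_slope = 0.2) {
  d3 <- length(dim(x)) == 3L
  if (d3) {
    d <- dim(x)
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])   # batch of one, same memory order
  }
  if (ncol(params$w1) != dim(x)[4L]) {
    stopf("attention weights expect %d channels, input has %d",
          ncol(params$w1), dim(x)[4L])
  }
  out <- ca_fwd(x, params, leaky_slope)$out
  if (d3) {
    dy <- dim(out)
    dim(out) <- dy[c(1L, 2L, 4L)]
  }
  out
}

# Gate matrices are (channels x batch); features are (h, w, n, c), so
# broadcasting runs over the (n, c)-ordered transpose.
ca_fwd <- function(x, cp, slope) {
  d <- dim(x); hw <- d[1L] * d[2L]
  z <- t(matrix(colMeans(matrix(x, hw, d[3L] * d[4L])), d[3L], d[4L]))
  d1 <- cp$w1 %*% z + cp$b1
  a1 <- lrelu(d1, slope)
  d2 <- cp$w2 %*% a1 + cp$b2
  g <- 1 / (1 + exp(-d2))
  ga <- array(rep(as.vector(t(g)), each = hw), d)
  list(out = x * ga, z = z, d1 = d1, a1 = a1, g = g, ga = ga)
}

ca_bwd <- function(dy, x, cache, cp, slope) {
  d <- dim(x); hw <- d[1L] * d[2L]
  dx <- dy * cache$ga
  dg <- t(matrix(colSums(matrix(dy * x, hw, d[3L] * d[4L])), d[3L], d[4L]))
  dd2 <- dg * cache$g * (1 - cache$g)
  gw2 <- dd2 %*% t(cache$a1)
  gb2 <- rowSums(dd2)
  da1 <- crossprod(cp$w2, dd2)
  dd1 <- lrelu_dmul(da1, cache$d1, slope)
  gw1 <- dd1 %*% t(cache$z)
  gb1 <- rowSums(dd1)
  dz <- crossprod(cp$w1, dd1)
  dx <- dx + array(rep(as.vector(t(dz)), each = hw), d) / hw
  list(dx = dx, grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}

# ---- residual block ------------------------------------------------------

block_fwd <- function(x, bp, cfg) {
  sl <- cfg$leaky_slope; sg <- cfg$precision == "single"
  z1 <- cv_fwd(x, bp$c1, sg); t1 <- lrelu(z1, sl)
  z3 <- cv_fwd(x, bp$c3, sg); t3 <- lrelu(z3, sl)
  z5 <- cv_fwd(x, bp$c5, sg); t5 <- lrelu(z5, sl)
  cache <- list(x = x, z1 = z1, z3 = z3, z5 = z5)
  if (cfg$use_concat_fusion) {
    cache$catm <- cat_ch(t1, t3, t5)
    e <- cv_fwd(cache$catm, bp$fuse, sg)
  } else {
    e <- t1 + t3 + t5
  }
  if (cfg$use_channel_attention) {
    cache$e <- e
    cache$ca <- ca_fwd(e, bp$ca, sl)
    e <- cache$ca$out
  }
  s <- if (cfg$use_skip) x + e else e
  cache$s <- s
  list(out = lrelu(s, sl), cache = cache)
}

block_bwd <- function(dy, cache, bp, cfg) {
  sl <- cfg$leaky_slope; f <- cfg$n_filters; sg <- cfg$precision == "single"
  ds <- lrelu_dmul(dy, cache$s, sl)
  de <- ds
  grads <- list()
  if (cfg$use_channel_attention) {
    cb <- ca_bwd(de, cache$e, cache$ca, bp$ca, sl)
    de <- cb$dx
    grads$ca <- cb$grads
  }
  if (cfg$use_concat_fusion) {
    fb <- cv_bwd(cache$catm, bp$fuse, de, single = sg)
    grads$fuse <- list(w = fb$dw, b = fb$db)
    dt1 <- slice_ch(fb$dx, 1L, f)
    dt3 <- slice_ch(fb$dx, f + 1L, 2L * f)
    dt5 <- slice_ch(fb$dx, 2L * f + 1L, 3L * f)
  } else {
    dt1 <- dt3 <- dt5 <- de
  }
  b1 <- cv_bwd(cache$x, bp$c1, lrelu_dmul(dt1, cache$z1, sl), single = sg)
  b3 <- cv_bwd(cache$x, bp$c3, lrelu_dmul(dt3, cache$z3, sl), single = sg)
  b5 <- cv_bwd(cache$x, bp$c5, lrelu_dmul(dt5, cache$z5, sl), single = sg)
  dx <- b1$dx + b3$dx + b5$dx
  if (cfg$use_skip) dx <- dx + ds
  grads$c1 <- list(w = b1$dw, b = b1$db)
  grads$c3 <- list(w = b3$dw, b = b3$db)
  grads$c5 <- list(w = b5$dw, b = b5$db)
  list(dx = dx, grads = grads)
}

#' Apply one residual block
#'
#' Exposed mainly for inspection and testing; [sr_forward()] is the
#' user-facing entry point.
#'
#' @param x 4-D feature array `(h, w, n, n_filters)` (batch third,
#'   channels last).
#' @param block_params One element of `model$params$groups[[g]]$blocks`.
#' @param cfg The model's [model_config()].
#' @return Feature array of the same shape.
#' @export
residual_block <- function(x, block_params, cfg) {
  if (dim(x)[4L] != cfg$n_filters) {
    stopf("input has %d channels; config expects %d", dim(x)[4L], cfg$n_filters)
  }
  block_fwd(x, block_params, cfg)$out
}

# ---- residual group ------------------------------------------------------

group_fwd <- function(x, gp, cfg) {
  sg <- cfg$precision == "single"
  bl <- vector("list", cfg$n_blocks)
  outs <- vector("list", cfg$n_blocks)
  cur <- x
  for (b in seq_len(cfg$n_blocks)) {
    r <- block_fwd(cur, gp$blocks[[b]], cfg)
    bl[[b]] <- r$cache
    outs[[b]] <- r$out
    cur <- r$out
  }
  catg <- do.call(cat_ch, c(outs, list(x)))
  list(out = cv_fwd(catg, gp$fuse, sg),
       cache = list(blocks = bl, catg = catg))
}

group_bwd <- function(dy, cache, gp, cfg) {
  f <- cfg$n_filters; nb <- cfg$n_blocks
  fb <- cv_bwd(cache$catg, gp$fuse, dy, single = cfg$precision == "single")
  grads <- list(fuse = list(w = fb$dw, b = fb$db))
  douts <- lapply(seq_len(nb), function(b) {
    slice_ch(fb$dx, (b - 1L) * f + 1L, b * f)
  })
  dxin <- slice_ch(fb$dx, nb * f + 1L, (nb + 1L) * f)
  gblocks <- vector("list", nb)
  dcur <- douts[[nb]]
  for (b in rev(seq_len(nb))) {
    r <- block_bwd(dcur, cache$blocks[[b]], gp$blocks[[b]], cfg)
    gblocks[[b]] <- r$grads
    dcur <- if (b > 1L) r$dx + douts[[b - 1L]] else r$dx
  }
  grads$blocks <- gblocks
  list(dx = dcur + dxin, grads = grads)
}

# ---- full network --------------------------------------------------------

net_forward <- function(params, cfg, x) {
  sg <- cfg$precision == "single"
  zsf <- cv_fwd(x, params$sf, sg)
  gcaches <- vector("list", cfg$n_groups)
  gouts <- vector("list", cfg$n_groups)
  cur <- zsf
  for (g in seq_len(cfg$n_groups)) {
    r <- group_fwd(cur, params$groups[[g]], cfg)
    gcaches[[g]] <- r$cache
    gouts[[g]] <- r$out
    cur <- r$out
  }
  cat_t <- do.call(cat_ch, gouts)
  fd <- cv_fwd(cat_t, params$trunk_fuse, sg)
  y <- fd + zsf                        # long skip connection
  up_in <- vector("list", length(params$up))
  cur <- y
  facs <- upscale_stage_factors(cfg)
  for (i in seq_along(params$up)) {
    up_in[[i]] <- cur
    cur <- ps_fwd(cv_fwd(cur, params$up[[i]], sg), facs[i])
  }
  out <- cv_fwd(cur, params$out, sg)
  list(out = out,
       cache = list(x = x, zsf = zsf, groups = gcaches, cat_t = cat_t,
                    up_in = up_in, out_in = cur))
}

net_backward <- function(dout, cache, params, cfg) {
  sg <- cfg$precision == "single"
  grads <- list()
  ob <- cv_bwd(cache$out_in, params$out, dout, single = sg)
  grads$out <- list(w = ob$dw, b = ob$db)
  dcur <- ob$dx
  facs <- upscale_stage_factors(cfg)
  grads$up <- vector("list", length(params$up))
  for (i in rev(seq_along(params$up))) {
    dz <- ps_bwd(dcur, facs[i])
    ub <- cv_bwd(cache$up_in[[i]], params$up[[i]], dz, single = sg)
    grads$up[[i]] <- list(w = ub$dw, b = ub$db)
    dcur <- ub$dx
  }
  dy <- dcur                            # gradient at trunk output
  dzsf <- dy                            # long skip connection path
  tb <- cv_bwd(cache$cat_t, params$trunk_fuse, dy, single = sg)
  grads$trunk_fuse <- list(w = tb$dw, b = tb$db)
  f <- cfg$n_filters
  dgouts <- lapply(seq_len(cfg$n_groups), function(g) {
    slice_ch(tb$dx, (g - 1L) * f + 1L, g * f)
  })
  grads$groups <- vector("list", cfg$n_groups)
  dcur <- dgouts[[cfg$n_groups]]
  for (g in rev(seq_len(cfg$n_groups))) {
    r <- group_bwd(dcur, cache$groups[[g]], params$groups[[g]], cfg)
    grads$groups[[g]] <- r$grads
    dcur <- if (g > 1L) r$dx + dgouts[[g - 1L]] else r$dx
  }
  dzsf <- dzsf + dcur
  sb <- cv_bwd(cache$x, params$sf, dzsf, need_dx = FALSE, single = sg)
  grads$sf <- list(w = sb$dw, b = sb$db)
  # reorder to match the parameter list layout
  grads[names(params)]
}

as_feature4 <- function(x, f, what) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  if (length(dim(x)) != 4L || dim(x)[4L] != f) {
    stopf("`%s` must be an (h, w, channels) feature map with %d channels",
          what, f)
  }
  x
}

as_feature3 <- function(x) {
  d <- dim(x)
  dim(x) <- d[c(1L, 2L, 4L)]
  x
}

#' Network stages, individually
#'
#' The four stages of the network, exposed for inspection and testing:
#' `shallow_extract()` applies the single 3x3 shallow-feature convolution
#' to a grayscale image; `residual_group()` applies one residual group
#' (block chain plus dense feature fusion); `rir_forward()` runs the full
#' residual-in-residual trunk on a shallow feature map and adds the long
#' skip connection; `upscale_features()` applies the sub-pixel upscaler
#' and output projection, returning a grayscale image clipped to
#' \[0, 255\]. [sr_forward()] composes exactly these stages (on the
#' \[0, 1\] internal intensity scale).
#'
#' @param model An `sr_model`.
#' @param img Single-channel numeric matrix.
#' @param x A feature map, `(h, w, n_filters)` (or 4-D with batch third).
#' @param group_params One element of `model$params$groups`.
#' @param cfg The model's [model_config()].
#' @return `shallow_extract`, `residual_group` and `rir_forward` return
#'   feature maps of the input's spatial size with `n_filters` channels;
#'   `upscale_features` returns a `scale`-times-larger matrix.
#' @export
shallow_extract <- function(model, img) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  check_gray(img)
  x <- array(img / 255, c(nrow(img), ncol(img), 1L, 1L))
  as_feature3(cv_fwd(x, model$params$sf, model$config$precision == "single"))
}

#' @rdname shallow_extract
#' @export
residual_group <- function(x, group_params, cfg) {
  x <- as_feature4(x, cfg$n_filters, "x")
  as_feature3(group_fwd(x, group_params, cfg)$out)
}

#' @rdname shallow_extract
#' @export
rir_forward <- function(model, x) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  cfg <- model$config
  x <- as_feature4(x, cfg$n_filters, "x")
  cur <- x
  gouts <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    cur <- group_fwd(cur, model$params$groups[[g]], cfg)$out
    gouts[[g]] <- cur
  }
  fd <- cv_fwd(do.call(cat_ch, gouts), model$params$trunk_fuse,
               cfg$precision == "single")
  as_feature3(fd + x)    # long skip connection
}

#' @rdname shallow_extract
#' @export
upscale_features <- function(model, x) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  cfg <- model$config
  x <- as_feature4(x, cfg$n_filters, "x")
  sg <- cfg$precision == "single"
  facs <- upscale_stage_factors(cfg)
  for (i in seq_along(model$params$up)) {
    x <- ps_fwd(cv_fwd(x, model$params$up[[i]], sg), facs[i])
  }
  out <- cv_fwd(x, model$params$out, sg)
  clip255(matrix(out, dim(out)[1L], dim(out)[2L]) * 255)
}

#' Super-resolve a grayscale image
#'
#' Runs the full network on a 0-255 grayscale matrix. Internally the image
#' is scaled to \[0, 1\]; the output is rescaled and clipped back to the
#' 8-bit range. The network is fully convolutional, so any input size at
#' least as large as the 5x5 block kernel works; the output is always
#' `scale` times the input.
#'
#' @param model An `sr_model` from [build_sr_model()] or [train_sr()].
#' @param img Numeric LR matrix on the 0-255 scale.
#' @return Numeric matrix of size `scale * dim(img)` in \[0, 255\].
#' @export
sr_forward <- function(model, img) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  check_gray(img)
  x <- array(img / 255, c(nrow(img), ncol(img), 1L, 1L))
  out <- net_forward(model$params, model$config, x)$out
  clip255(matrix(out, dim(out)[1L], dim(out)[2L]) * 255)
}

#' @export
predict.sr_model <- function(object, newdata, ...) sr_forward(object, newdata)
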