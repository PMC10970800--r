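# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stopf("`%s` must be a numeric matrix (2-D grayscale image)", arg)
  }
  invisible(img)
}

# Concatenate 4-D feature arrays (h, w, n, c) along the channel axis.
# Channels are the outermost dimension, so this is a plain value splice.
cat_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[4L], integer(1))
  out <- unlist(xs, use.names = FALSE)
  dim(out) <- c(d[1L], d[2L], d[3L], sum(cs))
  out
}

# Slice channels lo..hi from a 4-D feature array, keeping dims. Channels
# are outermost, so this is one contiguous block copy.
slice_ch <- function(x, lo, hi) .slice4(x, as.integer(lo), as.integer(hi))
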