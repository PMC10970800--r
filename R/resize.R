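# Bicubic resampling compatible with the classic MATLAB-style imresize:
# Keys cubic kernel (a = -0.5), separable application, kernel support widened
# by 1/scale on antialiased shrink, symmetric (reflect) boundary handling,
# per-site weight normalization.

keys_cubic <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1,
         (1.5 * ax - 2.5) * ax * ax + 1,
         ifelse(ax < 2, ((-0.5 * ax + 2.5) * ax - 4) * ax + 2, 0))
}

# Dense (n_out x n_in) resampling matrix for one axis.
resample_matrix <- function(n_in, n_out, scale, antialias) {
  kscale <- if (antialias && scale < 1) scale else 1
  support <- 2 / kscale
  u <- (seq_len(n_out)) / scale + 0.5 * (1 - 1 / scale)
  p <- ceiling(2 * support) + 2L
  left <- floor(u - support)
  idx <- outer(left, seq_len(p), `+`)                # n_out x p
  wts <- kscale * keys_cubic(kscale * (u - idx))
  wts <- wts / rowSums(wts)
  # symmetric (reflect-with-repeat) boundary: ... 2 1 | 1 2 ... n | n n-1 ...
  aux <- c(seq_len(n_in), rev(seq_len(n_in)))
  mapped <- matrix(aux[((idx - 1) %% (2 * n_in)) + 1], n_out, p)
  m <- matrix(0, n_out, n_in)
  for (j in seq_len(p)) {
    m[cbind(seq_len(n_out), mapped[, j])] <-
      m[cbind(seq_len(n_out), mapped[, j])] + wts[, j]
  }
  m
}

#' Bicubic image resizing (imresize-compatible)
#'
#' Separable resampling with the Keys cubic kernel (a = -0.5). When
#' shrinking (`scale_factor < 1`) with `antialias = TRUE` the kernel is
#' stretched by `1/scale_factor`, which is the documented antialiasing
#' behavior of the MATLAB-style `imresize` routine commonly used to
#' synthesize low-resolution inputs in super-resolution work. Boundaries
#' are handled by symmetric reflection and the output is clipped to the
#' 8-bit range.
#'
#' @param img Numeric matrix on the 0-255 scale.
#' @param scale_factor Positive scale; output size is
#'   `round(dim(img) * scale_factor)`.
#' @param antialias Widen the kernel on shrink (ignored on enlargement).
#' @return Resized numeric matrix, clipped to \[0, 255\].
#' @export
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64)
#' dim(bicubic_resize(img, 1 / 4))  # 16 x 16
bicubic_resize <- function(img, scale_factor, antialias = TRUE) {
  check_gray(img)
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0) {
    stopf("`scale_factor` must be a single positive number")
  }
  h <- nrow(img); w <- ncol(img)
  ho <- as.integer(round(h * scale_factor))
  wo <- as.integer(round(w * scale_factor))
  if (ho < 1L || wo < 1L) {
    stopf("scale_factor %g collapses a %dx%d image below 1 pixel",
          scale_factor, h, w)
  }
  if (scale_factor == 1) return(img)
  wr <- resample_matrix(h, ho, scale_factor, antialias)
  wc <- resample_matrix(w, wo, scale_factor, antialias)
  clip255(wr %*% img %*% t(wc))
}
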