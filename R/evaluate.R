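# Paired evaluation protocol: degrade each HR test image, super-resolve
# the LR with the model, score against the clean HR, and report the
# bicubic-upscaling baseline on the exact same LR inputs.

#' Evaluate a model against the bicubic baseline on a test set
#'
#' For each HR image `i`: `lr = make_lr(hr, spec_i)` (the noise seed is
#' offset per image so corruption draws are independent across the set),
#' `sr = sr_forward(model, lr)`, and PSNR/SSIM/MSIM of `sr` vs the clean
#' `hr`. The baseline row uses bicubic upscaling of the same `lr` and is
#' therefore model-independent.
#'
#' @param model An `sr_model` whose scale matches `spec$scale`.
#' @param test_hr List of HR matrices, each divisible by `spec$scale`.
#' @param spec A [degradation_spec()].
#' @param params An [ssim_params()]; its `n_scales` must fit the image size.
#' @return An object of class `sr_eval`: list with data frames `model` and
#'   `baseline` (columns `image`, `psnr`, `ssim`, `msim`) and a `summary`
#'   data frame of means per method.
#' @export
evaluate_sr <- function(model, test_hr, spec, params = ssim_params()) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  if (!inherits(spec, "degradation_spec")) {
    stopf("`spec` must be a degradation_spec")
  }
  if (model$config$scale != spec$scale) {
    stopf("model scale x%d does not match degradation scale x%d",
          model$config$scale, spec$scale)
  }
  score <- function(sr, hr) {
    c(psnr = psnr(sr, hr, params), ssim = ssim(sr, hr, params),
      msim = msim(sr, hr, params))
  }
  n <- length(test_hr)
  mrows <- brows <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    hr <- test_hr[[i]]
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    lr <- make_lr(hr, spec_i)
    mrows[i, ] <- score(sr_forward(model, lr), hr)
    brows[i, ] <- score(bicubic_resize(lr, spec$scale), hr)
  }
  as_report <- function(m, label) {
    data.frame(image = seq_len(n), method = label,
               psnr = m[, 1L], ssim = m[, 2L], msim = m[, 3L])
  }
  rep_m <- as_report(mrows, "model")
  rep_b <- as_report(brows, "bicubic")
  summary <- data.frame(
    method = c("model", "bicubic"),
    psnr = c(mean(mrows[, 1L]), mean(brows[, 1L])),
    ssim = c(mean(mrows[, 2L]), mean(brows[, 2L])),
    msim = c(mean(mrows[, 3L]), mean(brows[, 3L])))
  structure(list(model = rep_m, baseline = rep_b, summary = summary),
            class = "sr_eval")
}

#' @export
print.sr_eval <- function(x, ...) {
  cat("Paired evaluation over", nrow(x$model), "images (means):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
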