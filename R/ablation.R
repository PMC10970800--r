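# End-to-end ablation over the residual-block variants: channel attention
# on/off, concatenation fusion vs branch summation, skip connection.

#' The four standard block-variant rows
#'
#' Row 2 (attention off, concatenation on, skip on) is the proposed
#' configuration.
#'
#' @return Data frame with logical columns `ca`, `concat`, `skip`.
#' @export
ablation_variants <- function() {
  data.frame(ca     = c(TRUE, FALSE, FALSE, TRUE),
             concat = c(TRUE, TRUE, FALSE, FALSE),
             skip   = c(TRUE, TRUE, TRUE, TRUE))
}

#' Train and evaluate a grid of block variants
#'
#' Every variant is trained from the same weight-initialization seed on the
#' same patch pairs and evaluated on the same held-out set, so rows differ
#' only in architecture. Duplicate variants are collapsed with a warning.
#'
#' @param base_cfg A [model_config()] providing everything except the three
#'   ablation flags.
#' @param cfg_train A [train_config()].
#' @param pairs Training patch pairs (see [extract_patch_pairs()]).
#' @param test_hr List of held-out HR images.
#' @param spec A [degradation_spec()] matching `base_cfg$scale`.
#' @param variants Data frame with logical columns `ca`, `concat`, `skip`;
#'   defaults to [ablation_variants()].
#' @param params An [ssim_params()] for the evaluation metrics.
#' @return Data frame with one row per variant: the three flags, the
#'   parameter count, and mean PSNR/SSIM/MSIM on the held-out set.
#' @export
run_ablation <- function(base_cfg, cfg_train, pairs, test_hr, spec,
                         variants = ablation_variants(),
                         params = ssim_params()) {
  if (!all(c("ca", "concat", "skip") %in% names(variants))) {
    stopf("`variants` needs logical columns ca, concat, skip")
  }
  key <- do.call(paste, variants[c("ca", "concat", "skip")])
  if (anyDuplicated(key)) {
    warning("duplicate ablation variants collapsed", call. = FALSE)
    variants <- variants[!duplicated(key), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    cfg <- base_cfg
    cfg$use_channel_attention <- variants$ca[i]
    cfg$use_concat_fusion <- variants$concat[i]
    cfg$use_skip <- variants$skip[i]
    fit <- train_sr(cfg, pairs, cfg_train)
    ev <- evaluate_sr(fit$model, test_hr, spec, params)
    data.frame(ca = variants$ca[i], concat = variants$concat[i],
               skip = variants$skip[i],
               n_parameters = fit$model$n_parameters,
               psnr = ev$summary$psnr[1L], ssim = ev$summary$ssim[1L],
               msim = ev$summary$msim[1L])
  })
  do.call(rbind, rows)
}
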