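# Single-file plain-text checkpoints: a header, the configuration as
# key/value lines, then each named weight tensor with its shape and values
# at 17 significant digits (which round-trips IEEE doubles exactly, so a
# reloaded model's forward pass is bit-identical).

CKPT_HEADER <- "rirsr-checkpoint 1"

#' Save a model checkpoint
#'
#' @param model An `sr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "sr_model")) stopf("`model` must be an sr_model")
  cfg <- model$config
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  lines <- c(CKPT_HEADER,
             vapply(names(cfg), function(nm) {
               paste("config", nm, fmt(cfg[[nm]]))
             }, character(1)))
  flat <- flatten_params(model$params)
  for (nm in names(flat)) {
    v <- flat[[nm]]
    d <- if (is.null(dim(v))) length(v) else dim(v)
    lines <- c(lines,
               paste("tensor", nm, length(d), paste(d, collapse = " ")),
               paste(sprintf("%.17g", as.vector(v)), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

assign_path <- function(lst, path, value) {
  key <- path[1L]
  idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
  if (is.character(idx) && (is.null(names(lst)) || !idx %in% names(lst))) {
    stopf("corrupt checkpoint: unknown tensor path component '%s'", key)
  }
  if (length(path) == 1L) {
    if (length(lst[[idx]]) != length(value)) {
      stopf("corrupt checkpoint: tensor '%s' has wrong size", key)
    }
    dim(value) <- dim(lst[[idx]])
    lst[[idx]] <- value
  } else {
    lst[[idx]] <- assign_path(lst[[idx]], path[-1L], value)
  }
  lst
}

#' Load a model checkpoint
#'
#' Restores the configuration and every weight tensor exactly; the loaded
#' model's forward outputs are bit-identical to the saved model's.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @param expected_scale Optional scale the caller requires; a checkpoint
#'   declaring a different scale is rejected.
#' @return An `sr_model`.
#' @export
load_checkpoint <- function(path, expected_scale = NULL) {
  if (!file.exists(path)) stopf("checkpoint file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1L] != CKPT_HEADER) {
    stopf("'%s' is not a rirsr checkpoint (bad header)", path)
  }
  cfg_lines <- grep("^config ", lines, value = TRUE)
  kv <- strsplit(sub("^config ", "", cfg_lines), " ", fixed = TRUE)
  cfg_args <- list()
  numf <- c("n_groups", "n_blocks", "n_filters", "scale", "leaky_slope",
            "ca_reduction", "seed")
  logf <- c("use_channel_attention", "use_concat_fusion", "use_skip")
  for (p in kv) {
    val <- p[2L]
    cfg_args[[p[1L]]] <-
      if (p[1L] %in% numf) as.numeric(val)
      else if (p[1L] %in% logf) as.logical(val)
      else val
  }
  cfg <- do.call(model_config, cfg_args)
  if (!is.null(expected_scale) && cfg$scale != as.integer(expected_scale)) {
    stopf("checkpoint declares scale x%d but x%d was requested",
          cfg$scale, as.integer(expected_scale))
  }
  model <- build_sr_model(cfg)
  ti <- grep("^tensor ", lines)
  seen <- character(0)
  for (i in ti) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    nm <- hdr[2L]
    nd <- as.integer(hdr[3L])
    dims <- as.integer(hdr[4:(3L + nd)])
    vals <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]])
    if (length(vals) != prod(dims) || anyNA(vals)) {
      stopf("corrupt checkpoint: tensor '%s' data does not match its shape", nm)
    }
    model$params <- assign_path(model$params,
                                strsplit(nm, ".", fixed = TRUE)[[1L]], vals)
    seen <- c(seen, nm)
  }
  expected <- names(flatten_params(model$params))
  if (!setequal(seen, expected)) {
    stopf("corrupt checkpoint: tensor set does not match the declared config")
  }
  model
}
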