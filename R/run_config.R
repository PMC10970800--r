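# Plain-text run configuration: every hyperparameter of a run (phantom
# generation, degradation, architecture, optimization, metrics, patch
# extraction, run sizes) under an explicit dotted key, one `key = value`
# per line. Unknown keys are errors, not warnings, so a config never
# silently drifts; writing and re-reading a config round-trips exactly.

run_config_defaults <- function() {
  list(seed = 1L,
       phantom = phantom_spec(),
       degrade = degradation_spec(scale = 4L),
       model = model_config(),
       train = train_config(),
       metrics = ssim_params(),
       patch = list(lr_patch = 16L, stride = 1L, max_pairs = 102400L),
       run = list(n_train_images = 4L, n_test_images = 4L))
}

#' Build a run configuration
#'
#' @param ... Named overrides among `seed`, `phantom`, `degrade`, `model`,
#'   `train`, `metrics`, `patch`, `run` (each a component object or list).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown run_config component(s): %s",
          paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$model$scale != cfg$degrade$scale) {
    stopf("model scale x%d and degradation scale x%d disagree",
          cfg$model$scale, cfg$degrade$scale)
  }
  structure(cfg, class = "run_config")
}

fmt_cfg_value <- function(v) {
  if (is.logical(v)) as.character(v)
  else if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
  else as.character(v)
}

#' Write a run configuration to a plain-text file
#'
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  lines <- c(paste("seed =", fmt_cfg_value(cfg$seed)))
  for (sec in setdiff(names(cfg), "seed")) {
    comp <- cfg[[sec]]
    for (nm in names(comp)) {
      if (nm %in% c("c1", "c2")) next   # derived, not free parameters
      lines <- c(lines, sprintf("%s.%s = %s", sec, nm,
                                fmt_cfg_value(comp[[nm]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration from a plain-text file
#'
#' Lines are `key = value`; `#` starts a comment. Every key must be one the
#' package knows; unknown keys raise an error.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_.0-9]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stopf("malformed config line: '%s'", lines[which(bad)[1L]])
  defaults <- run_config_defaults()
  char_keys <- c("model.upscale_mode", "model.precision", "metrics.window")
  log_keys <- c("degrade.antialias", "model.use_channel_attention",
                "model.use_concat_fusion", "model.use_skip")
  int_keys <- c("seed", "phantom.height", "phantom.width", "phantom.seed",
                "phantom.n_bands", "phantom.n_blobs", "degrade.scale",
                "degrade.seed", "model.n_groups", "model.n_blocks",
                "model.n_filters", "model.scale", "model.ca_reduction",
                "model.seed", "train.decay_every", "train.batch_size",
                "train.n_epochs", "train.seed", "metrics.window_size",
                "metrics.n_scales", "patch.lr_patch", "patch.stride",
                "patch.max_pairs", "run.n_train_images", "run.n_test_images")
  overrides <- list()
  seed <- defaults$seed
  for (m in kv) {
    key <- m[2L]; val <- m[3L]
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    known <- if (length(parts) == 1L) {
      identical(key, "seed")
    } else {
      length(parts) == 2L && parts[1L] %in% names(defaults) &&
        parts[2L] %in% setdiff(names(defaults[[parts[1L]]]), c("c1", "c2"))
    }
    if (!known) stopf("unknown config key: '%s'", key)
    parsed <-
      if (key %in% char_keys) val
      else if (key %in% log_keys) as.logical(val)
      else if (key %in% int_keys) as.integer(val)
      else as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]])
    if (anyNA(parsed)) stopf("cannot parse value for config key '%s'", key)
    if (length(parts) == 1L) seed <- parsed
    else overrides[[parts[1L]]][[parts[2L]]] <- parsed
  }
  # rebuild every component through its constructor so all invariants are
  # re-validated on load
  build <- function(ctor, sec) do.call(ctor, as.list(overrides[[sec]]))
  run_config(
    seed = seed,
    phantom = build(phantom_spec, "phantom"),
    degrade = if (is.null(overrides$degrade$scale)) {
      do.call(degradation_spec,
              c(list(scale = defaults$degrade$scale),
                as.list(overrides$degrade)))
    } else build(degradation_spec, "degrade"),
    model = build(model_config, "model"),
    train = build(train_config, "train"),
    metrics = build(ssim_params, "metrics"),
    patch = modifyList(defaults$patch, as.list(overrides$patch %||% list())),
    run = modifyList(defaults$run, as.list(overrides$run %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
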