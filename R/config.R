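# Run configuration: one YAML document bundling network, loss, optimizer
# and trainer settings plus paths; unknown keys are rejected so typos fail
# loudly, and every run archives its resolved configuration.

run_config_defaults <- function() {
  list(
    seed = 1L,
    shape = c(24L, 24L, 24L),
    network = list(preset = "desk", embed_dim = NULL, window = NULL,
                   depths = NULL, heads = NULL, mlp_ratio = NULL,
                   stem_channels = NULL, head_channels = NULL,
                   dense_skips = TRUE, norm = "group"),
    snake = list(points_per_kernel = 9L, max_step = 1, fusion = "mean"),
    loss = list(ncc_window = 9L, lambda_reg = 0.02, ssim_weight = 0,
                epsilon = 1e-5),
    optimize = list(iterations = 10L, lr = 0.1, beta1 = 0.9,
                    beta2 = 0.999),
    train = list(epochs = 30L, lr = 1e-4, augment = TRUE, oss = TRUE,
                 gate_threshold = 0, checkpoint_every = 0L),
    data = list(n_cases = 20L, n_val = 4L, amplitude = 2, smoothness = 4,
                n_structures = 4L, noise_sd = 0.02, smooth_sd = 0.5),
    paths = list(out_dir = "snakereg_run")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop(sprintf("unknown configuration key: %s%s", path, k))
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("configuration key %s%s must be a mapping", path, k))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Unspecified keys fall back to the defaults; unknown keys raise an
#' error.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return a validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

# materialize component configs from the run config
build_configs <- function(cfg) {
  shape <- as.integer(rep_len(cfg$shape, 3L))
  snake <- snake_kernel_spec(cfg$snake$points_per_kernel,
                             cfg$snake$max_step, cfg$snake$fusion)
  net_cfg <- if (identical(cfg$network$preset, "desk") &&
                 is.null(cfg$network$embed_dim)) {
    network_config_desk(shape, snake)
  } else {
    network_config(
      shape = shape,
      swin = swin_config(
        embed_dim = cfg$network$embed_dim %||% 48L,
        window = cfg$network$window %||% c(2L, 4L, 4L),
        depths = cfg$network$depths %||% c(2L, 2L, 4L, 2L),
        heads = cfg$network$heads %||% c(4L, 4L, 8L, 8L),
        mlp_ratio = cfg$network$mlp_ratio %||% 2),
      snake = snake,
      stem_channels = cfg$network$stem_channels %||% 16L,
      head_channels = cfg$network$head_channels %||% 16L,
      dense_skips = cfg$network$dense_skips,
      norm = cfg$network$norm)
  }
  lcfg <- loss_config(cfg$loss$ncc_window, cfg$loss$lambda_reg,
                      cfg$loss$ssim_weight, cfg$loss$epsilon)
  ocfg <- opt_stage_config(cfg$optimize$iterations, cfg$optimize$lr,
                           cfg$optimize$beta1, cfg$optimize$beta2, lcfg)
  tcfg <- train_config(cfg$train$epochs, cfg$train$lr, cfg$seed,
                       cfg$train$augment, cfg$train$oss,
                       cfg$train$gate_threshold,
                       cfg$train$checkpoint_every)
  list(net = net_cfg, loss = lcfg, opt = ocfg, train = tcfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
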