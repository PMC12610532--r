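# End-to-end experiment orchestration from a YAML config:
# generate/load -> split -> augment (training split only) -> train ->
# evaluate -> explain, with every seed and the config hash recorded in a
# manifest for reproducibility.

#' Run a full experiment from a YAML config
#'
#' The config names the data source (synthetic, or a pair of files), the
#' model kinds to train, training settings and a master seed. Recognized
#' top-level keys: `seed`, `out_dir`, `data` (`source`, `spectra`/`labels`
#' paths or `generator` overrides, `split` fractions), `augment` (`n_new`,
#' `alpha_low`, `alpha_high`), `models` (list of
#' `spectran`/`mlp`/`cnn`/`transformer`/`lsttn`), `model_overrides`
#' (per-kind constructor arguments), `train` ([train_config()] arguments),
#' and `explain` (`enabled`, `window`, `stride`, `sample`).
#'
#' Per model it writes `metrics_<kind>.csv`, `history_<kind>.csv` and (when
#' enabled) `importance_<kind>.csv`, plus `manifest.yaml`. Reruns with an
#' identical config reproduce identical metric files.
#'
#' @param config_path Path to the YAML config, or an equivalent named list.
#' @param out_dir Output directory overriding the config's `out_dir`.
#' @return The output directory, invisibly; the parsed results are
#'   attached as attribute `results`.
#' @export
run_experiment <- function(config_path, out_dir = NULL) {
  cfg <- if (is.character(config_path)) yaml::read_yaml(config_path)
    else config_path
  validate_experiment_config(cfg)
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("config must name out_dir",
                                                call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- if (identical(cfg$data$source, "synthetic")) {
    gen_args <- cfg$data$generator %||% list()
    gen_args$seed <- gen_args$seed %||% seed
    if (!is.null(gen_args$mode)) gen_args$mode <- as.character(gen_args$mode)
    generate_spectra(do.call(generator_config, gen_args))
  } else {
    read_spectra_dataset(cfg$data$spectra, cfg$data$labels)
  }
  fractions <- as.numeric(cfg$data$split %||% c(0.6, 0.2, 0.2))
  parts <- split_spectra(ds, fractions, seed = seed)

  aug <- cfg$augment %||% list()
  train_ds <- if ((aug$n_new %||% 0) > 0) {
    augment_spectra(parts$train, n_new = aug$n_new,
                    alpha_low = aug$alpha_low %||% 0.1,
                    alpha_high = aug$alpha_high %||% 0.9, seed = seed + 1L)
  } else {
    parts$train
  }

  tr_args <- cfg$train %||% list()
  tr_args$seed <- tr_args$seed %||% (seed + 2L)
  tcfg <- do.call(train_config, tr_args)

  results <- list()
  for (kind in unlist(cfg$models %||% list("spectran"))) {
    ov <- (cfg$model_overrides %||% list())[[kind]] %||% list()
    model <- if (kind == "spectran") {
      spectran_model(do.call(spectran_config, ov), ds$grid, seed = seed + 3L)
    } else {
      ov$kind <- kind
      build_baseline(do.call(baseline_config, ov), ds$grid, seed = seed + 3L)
    }
    fit <- train_model(model, train_ds, parts$val, tcfg)
    metrics <- evaluate_model(fit, parts$test)
    utils::write.csv(cbind(metrics, metrics_summary(metrics)),
                     file.path(out_dir, paste0("metrics_", kind, ".csv")),
                     row.names = FALSE)
    utils::write.csv(fit$history,
                     file.path(out_dir, paste0("history_", kind, ".csv")),
                     row.names = FALSE)
    res <- list(fit = fit, metrics = metrics)
    ex <- cfg$explain %||% list()
    if (isTRUE(ex$enabled)) {
      i <- ex$sample %||% 1L
      prof <- perturbation_importance(
        fit$model, parts$test$X[i, ],
        reference = colMeans(train_ds$X),
        window = ex$window %||% 10L, stride = ex$stride %||% 5L)
      utils::write.csv(tibble::as_tibble(prof),
                       file.path(out_dir, paste0("importance_", kind, ".csv")),
                       row.names = FALSE)
      res$importance <- prof
    }
    results[[kind]] <- res
  }

  manifest <- list(
    seed = seed,
    split_seed = seed, augment_seed = seed + 1L,
    train_seed = tcfg$seed, init_seed = seed + 3L,
    config_hash = rlang::hash(cfg),
    n_samples = nrow(ds$X), n_train = nrow(train_ds$X),
    models = unlist(cfg$models %||% list("spectran")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(invisible(out_dir), results = results)
}

validate_experiment_config <- function(cfg) {
  if (!is.list(cfg)) stop("experiment config must be a list", call. = FALSE)
  if (is.null(cfg$data$source)) {
    stop("config must declare data$source ('synthetic' or 'files')",
         call. = FALSE)
  }
  if (!cfg$data$source %in% c("synthetic", "files")) {
    stop("unknown data source: ", cfg$data$source, call. = FALSE)
  }
  if (cfg$data$source == "files" &&
      (is.null(cfg$data$spectra) || is.null(cfg$data$labels))) {
    stop("file data source needs data$spectra and data$labels paths",
         call. = FALSE)
  }
  kinds <- unlist(cfg$models %||% list("spectran"))
  bad <- setdiff(kinds, c("spectran", "mlp", "cnn", "transformer", "lsttn"))
  if (length(bad) > 0) {
    stop("unknown model kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
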