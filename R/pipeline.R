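#' Assemble a run configuration
#'
#' A fully serializable description of a pipeline run: either synthetic
#' generation parameters or input recording paths, the preprocessing and
#' model parameters, the fold scheme, and the master seed. A run is
#' reconstructible from its persisted configuration alone.
#'
#' @param results_dir Directory for cached stage outputs and the summary.
#' @param input Character vector of recording paths, or `NULL` to simulate.
#' @param synth Named list of [synth_spec()] arguments (used when `input` is
#'   `NULL`).
#' @param window_s,step_s Windowing parameters.
#' @param model Named list of [model_config()] arguments.
#' @param scheme,k Fold scheme (`"kfold"` with `k` folds, or `"loso"`).
#' @param epochs,batch_size,lr Training parameters.
#' @param seed Master seed.
#' @param verbose Verbosity flag.
#' @return Object of class `run_config`.
#' @export
run_config <- function(results_dir = "eegemo-results",
                       input = NULL,
                       synth = list(),
                       window_s = 1, step_s = 1,
                       model = list(),
                       scheme = "kfold", k = 5L,
                       epochs = 10L, batch_size = 128L, lr = 1e-3,
                       seed = 1L, verbose = FALSE) {
  cfg <- list(results_dir = results_dir, input = input, synth = synth,
              window_s = window_s, step_s = step_s, model = model,
              scheme = scheme, k = as.integer(k), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = lr,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  # validate eagerly so bad configs fail before any compute
  do.call(synth_spec, c(cfg$synth, list(seed = cfg$seed)))
  do.call(model_config, cfg$model)
  if (!scheme %in% c("kfold", "loso")) stop("scheme must be 'kfold' or 'loso'")
  structure(cfg, class = "run_config")
}

config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Serialize / parse a run configuration
#'
#' The JSON round trip is byte-identical: `write_run_config` then
#' `read_run_config` then `write_run_config` reproduces the file exactly.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(config_json(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  raw$input <- if (length(raw$input)) unlist(raw$input) else NULL
  do.call(run_config, raw)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(config_json(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' simulate (or ingest) -> featurize -> cross-validate -> report. Stage
#' outputs are cached under `results_dir/run-<confighash>/`; re-running with
#' an identical configuration skips completed stages. The summary JSON embeds
#' the configuration hash, package version and seed.
#'
#' @param cfg A [run_config()].
#' @return List with the `cv_result` and the path of the summary file.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  run_dir <- file.path(cfg$results_dir, paste0("run-", substr(hash, 1, 12)))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(stage, fmt, ...) {
    if (cfg$verbose)
      message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                      stage, sprintf(fmt, ...)))
  }
  stage <- function(name, output, producer) {
    if (file.exists(output)) {
      log_msg(name, "cached (%s)", basename(output))
      return(output)
    }
    t0 <- Sys.time()
    tryCatch(producer(output),
             error = function(e) stop(sprintf("stage '%s' failed: %s",
                                              name, conditionMessage(e)),
                                      call. = FALSE))
    log_msg(name, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
    output
  }

  # stage 1: recordings
  rec_paths <- if (is.null(cfg$input)) {
    spec <- do.call(synth_spec, c(cfg$synth, list(seed = cfg$seed)))
    paths <- file.path(run_dir, sprintf("subject%02d.eegr",
                                        seq_len(spec$n_subjects)))
    if (!all(file.exists(paths))) {
      study <- generate_recording(spec)
      if (inherits(study, "eeg_recording")) study <- list(study)
      for (i in seq_along(study))
        stage("simulate", paths[i],
              function(out) write_recording(study[[i]], out))
    } else log_msg("simulate", "cached (%d subjects)", length(paths))
    paths
  } else cfg$input

  # stage 2: features
  feat_path <- file.path(run_dir, "features.txt")
  stage("featurize", feat_path, function(out) {
    tensors <- lapply(rec_paths, function(p)
      featurize_recording(read_recording(p), cfg$window_s, cfg$step_s))
    merged <- merge_tensors(tensors)
    write_feature_tensors(merged, out)
  })

  # stage 3: cross-validation + report
  res_path <- file.path(run_dir, "summary.json")
  if (file.exists(res_path)) {
    log_msg("crossval", "cached (summary.json)")
    return(list(cv = NULL, summary_path = res_path, run_dir = run_dir))
  }
  ft <- read_feature_tensors(feat_path)
  labels <- ft$meta$label
  n_classes <- length(unique(labels))
  mcfg <- do.call(model_config,
                  utils::modifyList(cfg$model,
                                    list(n_classes = max(2L, n_classes),
                                         seed = cfg$seed)))
  plan <- if (cfg$scheme == "loso")
    make_folds(scheme = "loso", subjects = ft$meta$subject, seed = cfg$seed)
  else
    make_folds(length(labels), "kfold", cfg$k, labels = labels, seed = cfg$seed)
  cv <- train_and_evaluate(ft, labels, mcfg, plan, epochs = cfg$epochs,
                           batch_size = cfg$batch_size, lr = cfg$lr,
                           seed = cfg$seed, verbose = cfg$verbose)
  summary <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("eegemo")),
    seed = cfg$seed,
    scheme = cfg$scheme,
    n_folds = plan$n_folds,
    metrics_mean = as.list(cv$mean),
    metrics_sd = as.list(cv$sd),
    per_fold_accuracy = vapply(cv$folds, function(r) r$accuracy, 1)
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), res_path)
  log_msg("report", "summary written to %s", res_path)
  list(cv = cv, summary_path = res_path, run_dir = run_dir)
}

#' Concatenate feature-tensor batches
#'
#' @param tensors List of `de_tensors` objects sharing grid shape and mask.
#' @return A single merged `de_tensors`.
#' @export
merge_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  if (length(tensors) == 1L) return(tensors[[1]])
  d1 <- dim(tensors[[1]]$grid)
  ns <- vapply(tensors, function(t) dim(t$grid)[1], 1)
  grid <- array(0, dim = c(sum(ns), d1[2], d1[3], d1[4]))
  off <- 0L
  for (t in tensors) {
    if (!identical(dim(t$grid)[-1], d1[-1]) || !identical(t$mask, tensors[[1]]$mask))
      stop("cannot merge feature tensors with different grids")
    n <- dim(t$grid)[1]
    grid[off + seq_len(n), , , ] <- t$grid
    off <- off + n
  }
  structure(list(grid = grid, mask = tensors[[1]]$mask,
                 meta = do.call(rbind, lapply(tensors, `[[`, "meta")),
                 band_names = tensors[[1]]$band_names),
            class = "de_tensors")
}
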