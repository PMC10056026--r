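#' Class-stratified dataset split specification
#'
#' @param fractions train/validation/test fractions; positive, summing to 1
#'   within 1e-9 (default 0.6/0.2/0.2).
#' @param stratify split within each target class (default `TRUE`).
#' @param seed integer seed for the shuffles.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.6, 0.2, 0.2), stratify = TRUE, seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    abort_input("`fractions` must be 3 positive values summing to 1")
  structure(list(fractions = fractions, stratify = isTRUE(stratify),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split samples into train / validation / test partitions
#'
#' Target-class samples are partitioned class-by-class (when stratified)
#' with largest-remainder rounding, so the partition sizes are exact and
#' deterministic given the seed. Unrelated samples are never placed in the
#' training or validation partitions: they all go to the test partition.
#'
#' @param labels class label per sample.
#' @param is_unrelated logical per sample.
#' @param spec a [split_spec()].
#' @param min_per_class minimum target-class size (default 5); smaller
#'   classes raise an error naming the class.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, is_unrelated, spec = split_spec(),
                          min_per_class = 5L) {
  labels <- as.character(labels)
  is_unrelated <- as.logical(is_unrelated)
  if (length(labels) != length(is_unrelated))
    abort_input("`labels` and `is_unrelated` lengths differ")
  withr::local_seed(spec$seed)
  target_idx <- which(!is_unrelated)
  groups <- if (spec$stratify) split(target_idx, labels[target_idx])
            else list(all = target_idx)
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) < min_per_class)
      abort_input(sprintf("class '%s' has %d samples; at least %d are required",
                          nm, length(g), min_per_class))
    g <- g[sample.int(length(g))]
    sizes <- largest_remainder(length(g), spec$fractions)
    ends <- cumsum(sizes)
    parts$train <- c(parts$train, g[seq_len(sizes[1])])
    parts$validation <- c(parts$validation, g[seq.int(ends[1] + 1L, length.out = sizes[2])])
    parts$test <- c(parts$test, g[seq.int(ends[2] + 1L, length.out = sizes[3])])
  }
  parts$test <- c(parts$test, which(is_unrelated))
  lapply(parts, sort)
}

#' End-to-end pipeline configuration
#'
#' Nested configuration for the full workflow with the canonical defaults:
#' 8-channel recordings at 200 Hz, 5 s repetitions + 3 s rest, 6 repetitions
#' of the 12 default movements; 250/100 ms windows stacked 53 deep;
#' 60/20/20 class-stratified split; CNN trained 200 epochs (Adam, lr 1e-4,
#' batch 32) under the joint loss with lambda 0.00025; autoencoder trained
#' 1000 epochs; per-class thresholds calibrated at recall 0.9. Any element
#' can be overridden by passing a partial list.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param simulation,preprocess,split,cnn,ae,rejector partial lists merged
#'   over the defaults of each stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, simulation = list(), preprocess = list(),
                            split = list(), cnn = list(), ae = list(),
                            rejector = list()) {
  check_number(seed, "seed", integerish = TRUE)
  defaults <- list(
    simulation = list(similarity = c(0.5, 0.95), sampling_rate = 200,
                      repetition_s = 5, rest_s = 3, repetitions = 6L,
                      noise_sd = 0.02),
    preprocess = list(window_ms = 250, step_ms = 100, stack = 53L),
    split = list(fractions = c(0.6, 0.2, 0.2)),
    cnn = list(lambda = 0.00025, alpha = 0.5, learning_rate = 1e-4,
               batch_size = 32L, epochs = 200L, standardize = FALSE),
    ae = list(widths = c(512L, 256L, 128L, 64L, 128L, 256L, 512L),
              epochs = 1000L, learning_rate = 1e-4, batch_size = 32L),
    rejector = list(recall = 0.9, mode = "per_class")
  )
  cfg <- list(seed = as.integer(seed),
              simulation = utils::modifyList(defaults$simulation, simulation),
              preprocess = utils::modifyList(defaults$preprocess, preprocess),
              split = utils::modifyList(defaults$split, split),
              cnn = utils::modifyList(defaults$cnn, cnn),
              ae = utils::modifyList(defaults$ae, ae),
              rejector = utils::modifyList(defaults$rejector, rejector))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file.
#' @param config a [pipeline_config()].
#' @return the parsed `pipeline_config`, or `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[intersect(names(x),
    c("seed", "simulation", "preprocess", "split", "cnn", "ae", "rejector"))])
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full open-set recognition pipeline
#'
#' Simulate a recording, preprocess it into feature images, split (unrelated
#' samples test-only), train the feature network, train the autoencoder on
#' the training-set target features, calibrate the rejection thresholds on
#' the validation features, and evaluate open-set performance on the test
#' partition. Every stage is seeded from `config$seed`, so a rerun with the
#' same configuration reproduces all metric values exactly.
#'
#' When `out_dir` is given, each stage artifact is persisted there and
#' reused on rerun if its configuration hash still matches (use
#' `force = TRUE` to recompute), and a manifest listing config, seeds, file
#' hashes and stage timings is written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @param force recompute cached stage artifacts.
#' @param quiet suppress progress lines.
#' @return an object of class `osemg_run` with the trained models, the
#'   decisions, the `open_set_report`, and the run manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         force = FALSE, quiet = TRUE) {
  if (!inherits(config, "pipeline_config"))
    abort_input("`config` must be a pipeline_config")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  timings <- list()
  files <- character(0)

  stage <- function(name, cfg_part, compute) {
    t0 <- proc.time()[["elapsed"]]
    key <- object_md5(list(name = name, cfg = cfg_part, seed = config$seed))
    path <- if (!is.null(out_dir)) file.path(out_dir, paste0(name, ".rds")) else NULL
    out <- NULL
    if (!is.null(path) && !force && file.exists(path)) {
      cached <- readRDS(path)
      if (identical(cached$key, key)) out <- cached$value
    }
    if (is.null(out)) {
      out <- compute()
      if (!is.null(path)) saveRDS(list(key = key, value = out), path)
    }
    if (!is.null(path)) files[[name]] <<- path
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    if (!quiet)
      message(sprintf("[osemg] %-12s %6.1fs (seed %d)", name,
                      timings[[name]], config$seed))
    out
  }

  sim <- config$simulation
  rec <- stage("recording", sim, function() {
    movs <- default_movement_set(sim$similarity)
    generate_recording(simulation_config(
      movs, sim$sampling_rate, sim$repetition_s, sim$rest_s,
      sim$repetitions, sim$noise_sd, seed = config$seed))
  })

  pp <- stage("features", config[c("simulation", "preprocess")], function()
    preprocess_recording(rec, config$preprocess$window_ms,
                         config$preprocess$step_ms, config$preprocess$stack))
  images <- pp$images
  is_unrel <- images$kind == "unrelated"

  parts <- stage("split", config[c("simulation", "preprocess", "split")], function()
    split_dataset(images$label, is_unrel,
                  split_spec(config$split$fractions, seed = config$seed + 3000L)))

  cnn <- stage("cnn", config[c("simulation", "preprocess", "split", "cnn")], function()
    train_cnn(images[parts$train],
              train_config(lambda = config$cnn$lambda, alpha = config$cnn$alpha,
                           learning_rate = config$cnn$learning_rate,
                           batch_size = config$cnn$batch_size,
                           epochs = config$cnn$epochs,
                           seed = config$seed + 1000L,
                           standardize = config$cnn$standardize)))

  feats <- stage("deep_features", config[c("simulation", "preprocess", "split", "cnn")],
                 function() list(train = extract_features(cnn, images[parts$train]),
                                 validation = extract_features(cnn, images[parts$validation]),
                                 test = extract_features(cnn, images[parts$test])))

  ae <- stage("ae", config[setdiff(names(config), "rejector")], function()
    train_autoencoder(feats$train$features,
                      autoencoder_spec(config$ae$widths),
                      epochs = config$ae$epochs,
                      learning_rate = config$ae$learning_rate,
                      batch_size = config$ae$batch_size,
                      seed = config$seed + 2000L,
                      cnn_fingerprint = cnn$fingerprint))

  rejection <- stage("rejection", unclass(config), function()
    calibrate_thresholds(ae, feats$validation$features,
                         images$label[parts$validation],
                         recall_factor = config$rejector$recall,
                         mode = config$rejector$mode))

  decisions <- cbind(data.frame(pred = as.character(feats$test$pred)),
                     decide(rejection, feats$test$features, feats$test$pred))
  report <- evaluate_open_set(images$label[parts$test], is_unrel[parts$test],
                              decisions, classes = cnn$classes)

  manifest <- list(
    package_version = as.character(utils::packageVersion("osemg")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seed = config$seed,
    stage_seeds = list(simulation = config$seed, cnn = config$seed + 1000L,
                       ae = config$seed + 2000L, split = config$seed + 3000L),
    config = unclass(config),
    timings_s = timings,
    files = if (length(files)) {
      stopifnot(all(file.exists(unlist(files))))
      lapply(files, function(f) list(path = f, md5 = unname(tools::md5sum(f))))
    } else NULL
  )
  if (!is.null(out_dir)) {
    write_report_json(report, file.path(out_dir, "report.json"))
    write_training_log(cnn, file.path(out_dir, "training_log.jsonl"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  }

  structure(list(config = config, recording = rec, images = images,
                 split = parts, cnn = cnn, features = feats, ae = ae,
                 rejection = rejection, decisions = decisions,
                 report = report, manifest = manifest),
            class = "osemg_run")
}

#' @export
print.osemg_run <- function(x, ...) {
  cat(sprintf("osemg pipeline run (seed %d): %d train / %d validation / %d test images\n",
              x$config$seed, length(x$split$train), length(x$split$validation),
              length(x$split$test)))
  print(x$report)
  invisible(x)
}

#' Recalibrate and re-evaluate over a set of recall factors
#'
#' Reuses a finished run's trained models: for each recall factor the
#' thresholds are recalibrated on the validation features and the test
#' partition is re-evaluated. Mirrors the trade-off that raising the recall
#' factor raises thresholds, accepts more targets, and rejects fewer
#' unrelated movements.
#'
#' @param run an [run_pipeline()] result.
#' @param recalls recall factors to evaluate (default 0.8, 0.85, 0.9).
#' @return data frame with one row per recall factor.
#' @export
sweep_recall <- function(run, recalls = c(0.8, 0.85, 0.9)) {
  is_unrel <- run$images$kind[run$split$test] == "unrelated"
  truth <- run$images$label[run$split$test]
  do.call(rbind, lapply(recalls, function(r) {
    rej <- calibrate_thresholds(run$ae, run$features$validation$features,
                                run$images$label[run$split$validation],
                                recall_factor = r, mode = run$config$rejector$mode)
    dec <- cbind(data.frame(pred = as.character(run$features$test$pred)),
                 decide(rej, run$features$test$features, run$features$test$pred))
    rep <- evaluate_open_set(truth, is_unrel, dec, classes = run$cnn$classes)
    data.frame(recall = r,
               mean_threshold = mean(rej$thresholds),
               target_accuracy = rep$target_accuracy,
               closed_set_accuracy = rep$closed_set_accuracy %||% NA_real_,
               rejection_rate = rep$rejection_rate,
               macro_fscore = rep$macro_fscore,
               auc = rep$auc %||% NA_real_)
  }))
}

#' Within-class scatter of deep features
#'
#' Mean squared Euclidean distance of each feature vector to its class
#' centroid, averaged over samples and divided by the feature
#' dimensionality: the quantity the center loss shrinks.
#'
#' @param features `[n x d]` matrix.
#' @param labels class label per row.
#' @return scalar.
#' @export
within_class_variance <- function(features, labels) {
  features <- rbind(features)
  labels <- as.character(labels)
  tot <- 0
  for (cl in unique(labels)) {
    rows <- features[labels == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    tot <- tot + sum(sweep(rows, 2, ctr)^2)
  }
  tot / (nrow(features) * ncol(features))
}

#' Sweep the center-loss weight
#'
#' Trains the full pipeline at each `lambda` (optionally over several
#' seeds) and tabulates the within-class deep-feature scatter on the
#' training set together with the open-set test metrics.
#'
#' @param config a [pipeline_config()]; its `cnn$lambda` is overridden.
#' @param lambdas center-loss weights to evaluate.
#' @param seeds master seeds to average over (default: the config's seed).
#' @return data frame with one row per (lambda, seed).
#' @export
sweep_lambda <- function(config = pipeline_config(),
                         lambdas = c(0, 0.00025), seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed
  grid <- expand.grid(lambda = lambdas, seed = seeds)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cfg <- pipeline_config(seed = grid$seed[i],
                           simulation = config$simulation,
                           preprocess = config$preprocess,
                           split = config$split,
                           cnn = utils::modifyList(config$cnn,
                                                   list(lambda = grid$lambda[i])),
                           ae = config$ae, rejector = config$rejector)
    run <- run_pipeline(cfg)
    tf <- run$features$train
    data.frame(lambda = grid$lambda[i], seed = grid$seed[i],
               within_class_variance =
                 within_class_variance(tf$features,
                                       run$images$label[run$split$train]),
               closed_set_accuracy = run$report$closed_set_accuracy %||% NA_real_,
               target_accuracy = run$report$target_accuracy,
               rejection_rate = run$report$rejection_rate,
               macro_fscore = run$report$macro_fscore,
               auc = run$report$auc %||% NA_real_)
  }))
}
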