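# Run configuration and the end-to-end pipeline driver (the programmatic
# core behind the command-line wrapper in inst/cli/flockcall.R).

.RUN_CONFIG_DEFAULTS <- list(
  seed = 1L,
  out_dir = "flock_run",
  # feature extraction
  scale_family = "greenwood", f_min = 500, f_max = 6000, k = 0.88,
  n_filters = 20L, filter_shape = "hamming", n_coeffs = 21L,
  frame_len = NULL, hop = NULL, rms_floor = NULL,
  # selection + classifier
  d_target = 6L, grid_min = -10L, grid_max = 10L, grid_step = 1L,
  folds = 5L, tune_max_sequences = Inf,
  # evaluation
  protocol = "both", k_folds = 5L,
  # input: synthetic benchmark or a directory of WAV + label tables
  synth = TRUE, uniform_behaviour = FALSE, snr_db = 10, audio_dir = NULL
)

#' Default run configuration
#'
#' The flat key-value configuration understood by [runPipeline()]. Keys
#' cover every tunable of the pipeline: frequency warping (family, band,
#' k), filter bank (count, shape), framing, selection size, the
#' hyperparameter grid (`2^grid_min ... 2^grid_max` stepped by
#' `grid_step`), CV folds, evaluation protocol (`"A"` day split, `"B"`
#' mixed k-fold, or `"both"`), and the input source (synthetic benchmark
#' or `audio_dir` with `*.wav` plus `*.labels.tsv` files).
#'
#' @return named list of defaults.
#' @seealso [readRunConfig()], [runPipeline()]
#' @export
defaultRunConfig <- function() .RUN_CONFIG_DEFAULTS

#' Validate a run configuration
#'
#' Fills unset keys with defaults and rejects unknown keys and malformed
#' values, naming the offending key.
#'
#' @param config named list of overrides.
#' @return the completed configuration list.
#' @export
validateRunConfig <- function(config = list()) {
  unknown <- setdiff(names(config), names(.RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(.RUN_CONFIG_DEFAULTS, config, keep.null = TRUE)
  if (!cfg$scale_family %in% c("greenwood", "mel"))
    stop("config scale_family must be 'greenwood' or 'mel'")
  if (!cfg$protocol %in% c("A", "B", "both"))
    stop("config protocol must be 'A', 'B' or 'both'")
  if (!(cfg$f_min > 0 && cfg$f_max > cfg$f_min))
    stop("config needs 0 < f_min < f_max")
  if (cfg$grid_step < 1) stop("config grid_step must be >= 1")
  if (!cfg$synth && is.null(cfg$audio_dir))
    stop("config audio_dir is required when synth is false")
  cfg
}

#' Read / write a run configuration file (YAML)
#'
#' Flat YAML key-value files round-trip losslessly; unknown keys are
#' rejected on read.
#'
#' @param path YAML file path.
#' @return [readRunConfig()]: the validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validateRunConfig(raw)
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- validateRunConfig(config)
  cfg <- cfg[!vapply(cfg, is.null, NA)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# md5 of a character vector, via a temp file (no digest dependency).
.md5Lines <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

.logStage <- function(stage, ..., verbose = TRUE) {
  if (verbose)
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Load clips + label tables from a directory of <base>.wav and
# <base>.labels.tsv files; a "dayN" token in the file name sets the day
# tag (default day1).
.loadAudioDir <- function(dir) {
  wavs <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (!length(wavs)) stop("no .wav files found in ", dir)
  clips <- list(); labels <- list()
  for (w in wavs) {
    lab <- sub("\\.wav$", ".labels.tsv", w)
    if (!file.exists(lab)) stop("missing label table for ", w)
    day <- regmatches(basename(w), regexpr("day[0-9]+", basename(w)))
    clips[[length(clips) + 1L]] <-
      readWav(w, dayTag = if (length(day)) day else "day1")
    labels[[length(labels) + 1L]] <- readLabelTable(lab)
  }
  list(clips = clips, labels = labels)
}

#' Run the full behaviour-recognition pipeline
#'
#' Chains the stages: obtain audio (synthetic benchmark or `audio_dir`),
#' extract GFCC features, report the selected coefficient subset, run the
#' configured evaluation protocol(s), and write tab-separated reports
#' (features, selection, confusion matrix and metrics per protocol) plus
#' a run report carrying the configuration hash.
#'
#' @param config configuration list (see [defaultRunConfig()]); validated
#'   with [validateRunConfig()].
#' @param verbose emit timestamped stage logs to stderr.
#' @return invisibly, a list with `features`, `selection`, `results` (per
#'   protocol) and `configHash`.
#' @export
runPipeline <- function(config = list(), verbose = TRUE) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfgHash <- .md5Lines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "="))

  .logStage("input", "config hash ", cfgHash, verbose = verbose)
  if (cfg$synth) {
    bench <- makeBenchmark(seed = cfg$seed,
                           sceneOverrides = list(snrDb = cfg$snr_db),
                           uniformBehaviour = cfg$uniform_behaviour)
    clips <- bench$clips; labels <- bench$labels
    writeLines(bench$manifest, file.path(cfg$out_dir, "manifest.txt"))
  } else {
    audio <- .loadAudioDir(cfg$audio_dir)
    clips <- audio$clips; labels <- audio$labels
  }
  .logStage("input", length(clips), " labeled clips", verbose = verbose)

  scale <- if (cfg$scale_family == "greenwood")
    greenwoodScale(cfg$f_min, cfg$f_max, cfg$k)
  else melScale(cfg$f_min, cfg$f_max)
  feats <- extractFeatures(clips, labels, scale = scale,
                           nFilters = cfg$n_filters,
                           shape = cfg$filter_shape,
                           frameLen = cfg$frame_len, hop = cfg$hop,
                           nCoeffs = cfg$n_coeffs,
                           rmsFloor = cfg$rms_floor)
  if (ncol(feats) == 0L) stop("no labeled frames were extracted")
  .logStage("extract", ncol(feats), " frames / ",
            length(unique(sequenceId(feats))), " sequences",
            verbose = verbose)
  featDf <- cbind(as.data.frame(SummarizedExperiment::colData(feats)),
                  t(cepstra(feats)))
  .writeTsv(featDf, file.path(cfg$out_dir, "features.tsv"))

  # selection report on the full raw cepstra (protocols re-select inside
  # their own training partitions)
  X <- t(cepstra(feats))
  keep0 <- which(apply(X, 2L, sd) > 0) - 1L
  Xk <- X[, keep0 + 1L, drop = FALSE]
  selAll <- branchAndBoundSelect(Xk, as.character(behaviour(feats)),
                                 dTarget = cfg$d_target)
  selIdx <- keep0[selectedIndices(selAll) + 1L]
  contrib <- numeric(ncol(X))
  contrib[keep0 + 1L] <- separabilityContributions(
    Xk, as.character(behaviour(feats)))
  .writeTsv(data.frame(coefficient = paste0("c", seq_len(ncol(X)) - 1L),
                       contribution = contrib,
                       selected = (seq_len(ncol(X)) - 1L) %in% selIdx),
            file.path(cfg$out_dir, "selection.tsv"))
  .logStage("select", "coefficients {",
            paste(selIdx, collapse = ", "), "}", verbose = verbose)

  gridExp <- seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step)
  protos <- switch(cfg$protocol, A = "day_split", B = "mixed_kfold",
                   both = c("day_split", "mixed_kfold"))
  results <- list()
  for (pp in protos) {
    tag <- if (pp == "day_split") "A" else "B"
    .logStage("evaluate", "protocol ", tag, " (", pp, ")",
              verbose = verbose)
    res <- runProtocol(feats, protocol = pp, k = cfg$k_folds,
                       seed = cfg$seed, dTarget = cfg$d_target,
                       gridExponents = gridExp, folds = cfg$folds,
                       tuneMaxSequences = cfg$tune_max_sequences)
    cmDf <- data.frame(observed = rownames(res$confusion), res$confusion)
    .writeTsv(cmDf, file.path(cfg$out_dir,
                              paste0("confusion_", tag, ".tsv")))
    met <- res$metrics
    met[-1] <- lapply(met[-1], roundHalfUp)
    .writeTsv(met, file.path(cfg$out_dir, paste0("metrics_", tag, ".tsv")))
    results[[tag]] <- res
  }

  outFiles <- sort(list.files(cfg$out_dir, pattern = "\\.tsv$",
                              full.names = TRUE))
  report <- c(paste0("config_hash: ", cfgHash),
              vapply(outFiles, function(f)
                paste0(basename(f), ": ", unname(tools::md5sum(f))), ""))
  writeLines(report, file.path(cfg$out_dir, "report.txt"))
  .logStage("done", "reports in ", cfg$out_dir, verbose = verbose)
  invisible(list(features = feats, selection = selIdx, results = results,
                 configHash = cfgHash))
}

#' Persist / restore a trained model set
#'
#' A single versioned archive holding the three pairwise models, the
#' normalisation statistics, the selected coefficients and the tuning
#' results.
#'
#' @param models a [TrainedModelSet-class].
#' @param path archive path (`.rds`).
#' @export
saveModelSet <- function(models, path) {
  stopifnot(is(models, "TrainedModelSet"))
  saveRDS(list(schema = "flockBehaviour-models-v1", models = models), path)
  invisible(path)
}

#' @rdname saveModelSet
#' @export
loadModelSet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "flockBehaviour-models-v1"))
    stop("not a flockBehaviour model archive: ", path)
  obj$models
}
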