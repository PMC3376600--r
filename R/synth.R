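# Synthetic flock-call scene generation: seeded, harmonic, behaviour-
# conditioned audio that exercises the full pipeline in the absence of
# field recordings.

#' Per-behaviour scene generation defaults
#'
#' Caricatured but acoustically motivated settings: flushing is a dense
#' chorus of many overlapping, pitch-raised calls; landing is nearly as
#' dense with moderate overlap; foraging is sparse contact calling. Call
#' duration is `overlap / callRate`, so `overlap` is the mean number of
#' simultaneous callers (Poisson-process coverage); the densities are
#' chosen so flushing/landing windows almost always contain a call while
#' many foraging windows are background only. All spectral energy sits in
#' the 500-6000 Hz band.
#'
#' @param behaviour one of `"flushing"`, `"landing"`, `"foraging"`.
#' @return list of scene parameters (see [sceneConfig()]).
#' @export
behaviourDefaults <- function(behaviour) {
  .checkBehaviour(behaviour)
  switch(behaviour,
    flushing = list(callRate = 10, overlap = 3.5, f0Range = c(1100, 1500)),
    landing  = list(callRate = 6,  overlap = 2.4, f0Range = c(800, 1150)),
    foraging = list(callRate = 2,  overlap = 0.6, f0Range = c(550, 900))
  )
}

#' Scene configuration for one behaviour recording
#'
#' @param behaviour behaviour label of the scene.
#' @param durationS scene duration in seconds.
#' @param callRate mean calls per second (Poisson).
#' @param overlap mean number of simultaneous callers; call duration is
#'   `overlap / callRate` seconds.
#' @param f0Range fundamental-frequency interval in Hz.
#' @param nHarmonics harmonics per call (capped at the band top).
#' @param band energy band in Hz (default 500-6000).
#' @param snrDb signal-to-noise ratio of the added white noise in dB;
#'   `Inf` disables noise.
#' @param sampleRate sampling rate in Hz (default 44100).
#' @param seed RNG seed for the scene.
#' @return list of class `sceneConfig`. Parameters omitted fall back to
#'   [behaviourDefaults()].
#' @export
sceneConfig <- function(behaviour, durationS, callRate = NULL,
                        overlap = NULL, f0Range = NULL, nHarmonics = 6L,
                        band = c(500, 6000), snrDb = 10,
                        sampleRate = 44100, seed = 1L) {
  .checkBehaviour(behaviour)
  .assertScalarNumeric(durationS, "durationS")
  def <- behaviourDefaults(behaviour)
  cfg <- list(
    behaviour = behaviour, durationS = durationS,
    callRate = if (is.null(callRate)) def$callRate else callRate,
    overlap = if (is.null(overlap)) def$overlap else overlap,
    f0Range = if (is.null(f0Range)) def$f0Range else f0Range,
    nHarmonics = as.integer(nHarmonics), band = band, snrDb = snrDb,
    sampleRate = sampleRate, seed = as.integer(seed)
  )
  if (cfg$callRate <= 0) stop("callRate must be positive")
  if (cfg$band[1] <= 0 || cfg$band[2] >= sampleRate / 2)
    stop("band must lie within (0, Nyquist)")
  structure(cfg, class = "sceneConfig")
}

#' Synthesise one harmonic call
#'
#' A stack of harmonics of a jittered fundamental, with random per-
#' harmonic amplitudes decaying with harmonic number, a slow vibrato and
#' an attack-decay amplitude envelope. Harmonics falling outside the band
#' (or above Nyquist) are dropped, so call power is concentrated inside
#' the band. Uses the current RNG stream; seed at the caller (as
#' [synthScene()] does) for reproducibility.
#'
#' @param f0 fundamental frequency in Hz (must lie below Nyquist).
#' @param durationS call duration in seconds.
#' @param nHarmonics number of harmonics attempted.
#' @param band allowed frequency band in Hz.
#' @param sampleRate sampling rate in Hz.
#' @return numeric amplitude vector (peak-normalised to 1).
#' @export
synthCall <- function(f0, durationS = 0.3, nHarmonics = 6L,
                      band = c(500, 6000), sampleRate = 44100) {
  if (f0 >= sampleRate / 2) stop("f0 must lie below the Nyquist frequency")
  if (f0 <= 0) stop("f0 must be positive")
  n <- max(8L, round(durationS * sampleRate))
  t <- (seq_len(n) - 1L) / sampleRate
  harm <- seq_len(nHarmonics)
  freqs <- harm * f0
  keep <- freqs <= min(band[2], sampleRate / 2 * 0.95)
  if (!any(keep)) keep[1] <- TRUE             # always keep the fundamental
  freqs <- freqs[keep]

  amps <- runif(length(freqs), 0.5, 1) / seq_along(freqs)
  vibRate <- runif(1, 2, 6)
  vibDepth <- 0.01
  vibPhase <- runif(1, 0, 2 * pi)
  phases <- runif(length(freqs), 0, 2 * pi)
  # common multiplicative jitter keeps harmonics harmonically related
  jitter <- 1 + vibDepth * sin(2 * pi * vibRate * t + vibPhase)
  x <- numeric(n)
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * cumsum(jitter) / sampleRate +
                           phases[i])
  }
  attack <- 0.15
  env <- pmin(t / (attack * durationS), 1) *
    exp(-3 * pmax(t - attack * durationS, 0) / durationS)
  x <- x * env
  x / max(abs(x))
}

#' Synthesise a labeled behaviour scene
#'
#' Places a Poisson number of calls (`callRate * durationS` expected)
#' uniformly over the scene, each synthesised by [synthCall()] with an
#' f0 drawn from the behaviour's range, adds white Gaussian noise at the
#' configured SNR and peak-normalises to 0.9. The whole scene carries the
#' behaviour's label.
#'
#' @param config a [sceneConfig()] list.
#' @param sourceId,dayTag identifiers for the resulting clip.
#' @return list with `clip` (an [AudioClip-class]), `labels` (a label
#'   table covering the scene) and `events` (one row per placed call:
#'   start time, f0, duration).
#' @export
synthScene <- function(config, sourceId = NULL, dayTag = "day1") {
  stopifnot(inherits(config, "sceneConfig"))
  fs <- config$sampleRate
  n <- round(config$durationS * fs)
  callDur <- config$overlap / config$callRate

  gen <- withSeed(config$seed, {
    sig <- numeric(n)
    nCalls <- rpois(1L, config$callRate * config$durationS)
    starts <- sort(runif(nCalls, 0, config$durationS))
    ev <- data.frame(start_s = numeric(), f0 = numeric(),
                     duration_s = numeric())
    for (s in starts) {
      f0 <- runif(1, config$f0Range[1], config$f0Range[2])
      dur <- callDur * runif(1, 0.7, 1.3)
      call <- synthCall(f0, dur, config$nHarmonics, config$band, fs) *
        runif(1, 0.4, 1)
      i0 <- round(s * fs)
      idx <- i0 + seq_along(call)
      idx <- idx[idx <= n]
      sig[idx] <- sig[idx] + call[seq_along(idx)]
      ev <- rbind(ev, data.frame(start_s = s, f0 = f0, duration_s = dur))
    }
    if (is.finite(config$snrDb)) {
      pSig <- mean(sig^2)
      if (pSig == 0) pSig <- 1e-6              # silent scene: noise floor
      noiseSd <- sqrt(pSig / 10^(config$snrDb / 10))
      sig <- sig + rnorm(n, sd = noiseSd)
    }
    list(sig = sig, events = ev)
  })
  x <- gen$sig
  x <- 0.9 * x / max(abs(x))
  if (is.null(sourceId))
    sourceId <- sprintf("%s_%s_seed%d", config$behaviour, dayTag,
                        config$seed)
  list(
    clip = AudioClip(x, fs, sourceId = sourceId, dayTag = dayTag),
    labels = data.frame(start_s = 0, end_s = n / fs,
                        label = config$behaviour),
    events = gen$events
  )
}

#' Default two-day benchmark layout
#'
#' Per-day, per-behaviour labeled durations in seconds. The defaults
#' mirror the field study's recording budget: landing 48/30 s, foraging
#' 90/60 s, flushing 12/15 s across the two days, so class imbalance
#' (foraging much larger than flushing) and the day split are genuinely
#' exercised.
#'
#' @return named list of named numeric vectors (seconds per behaviour).
#' @export
defaultDayProfiles <- function() {
  list(
    day1 = c(flushing = 12, foraging = 90, landing = 48),
    day2 = c(flushing = 15, foraging = 60, landing = 30)
  )
}

#' Generate the two-day synthetic benchmark
#'
#' One scene per day and behaviour, with durations from the day profiles
#' and per-scene seeds derived deterministically from `seed`. The
#' returned manifest (key-value text lines) records every parameter and
#' seed; [benchmarkFromManifest()] reconstructs the identical dataset.
#'
#' @param dayProfiles layout as from [defaultDayProfiles()].
#' @param seed master seed.
#' @param sceneOverrides named list of [sceneConfig()] arguments applied
#'   to every scene (e.g. `list(snrDb = 20)`); per-behaviour parameters
#'   not overridden come from [behaviourDefaults()].
#' @param uniformBehaviour if `TRUE`, every scene is generated with the
#'   foraging acoustic parameters regardless of its label — a negative
#'   control in which labels carry no acoustic information and
#'   classification should fall to chance.
#' @param scenesPerClass number of independent scenes each per-day,
#'   per-behaviour duration is split into (default 1, mirroring single
#'   behaviour events per day; larger values reduce scene-level sampling
#'   noise, e.g. for the uniform-behaviour null).
#' @return list of class `syntheticBenchmark`: `clips` (list of
#'   [AudioClip-class]), `labels` (parallel list of label tables) and
#'   `manifest` (character vector).
#' @export
makeBenchmark <- function(dayProfiles = defaultDayProfiles(), seed = 1L,
                          sceneOverrides = list(),
                          uniformBehaviour = FALSE, scenesPerClass = 1L) {
  clips <- list(); labels <- list()
  manifest <- c("benchmark_version: 1",
                sprintf("seed: %d", as.integer(seed)),
                sprintf("uniform_behaviour: %s", uniformBehaviour))
  stream <- 0L
  for (dd in names(dayProfiles)) {
    prof <- dayProfiles[[dd]]
    for (bb in names(prof)) {
      for (ss in seq_len(scenesPerClass)) {
        stream <- stream + 1L
        sceneSeed <- as.integer(deriveSeed(seed, stream))
        acoustic <- if (uniformBehaviour) behaviourDefaults("foraging")
                    else behaviourDefaults(bb)
        args <- modifyList(
          c(list(behaviour = bb,
                 durationS = unname(prof[[bb]]) / scenesPerClass,
                 seed = sceneSeed),
            acoustic[c("callRate", "overlap", "f0Range")]),
          sceneOverrides)
        cfg <- do.call(sceneConfig, args)
        srcId <- sprintf("%s_%s_s%d_seed%d", bb, dd, ss, sceneSeed)
        sc <- synthScene(cfg, dayTag = dd, sourceId = srcId)
        clips[[length(clips) + 1L]] <- sc$clip
        labels[[length(labels) + 1L]] <- sc$labels
        manifest <- c(manifest, sprintf(
          "scene: day=%s behaviour=%s source=%s duration_s=%g call_rate=%g overlap=%g f0_min=%g f0_max=%g n_harmonics=%d band_min=%g band_max=%g snr_db=%g sample_rate=%g seed=%d",
          dd, bb, srcId, cfg$durationS, cfg$callRate, cfg$overlap,
          cfg$f0Range[1], cfg$f0Range[2], cfg$nHarmonics, cfg$band[1],
          cfg$band[2], cfg$snrDb, cfg$sampleRate, cfg$seed))
      }
    }
  }
  structure(list(clips = clips, labels = labels, manifest = manifest),
            class = "syntheticBenchmark")
}

#' Rebuild a benchmark bit-exactly from its manifest
#'
#' @param manifest character vector as produced by [makeBenchmark()].
#' @return a `syntheticBenchmark` identical to the original.
#' @export
benchmarkFromManifest <- function(manifest) {
  sceneLines <- grep("^scene: ", manifest, value = TRUE)
  clips <- list(); labels <- list()
  for (ln in sceneLines) {
    kv <- strsplit(strsplit(sub("^scene: ", "", ln), " ")[[1]], "=")
    vals <- setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
    cfg <- sceneConfig(
      behaviour = vals[["behaviour"]],
      durationS = as.numeric(vals[["duration_s"]]),
      callRate = as.numeric(vals[["call_rate"]]),
      overlap = as.numeric(vals[["overlap"]]),
      f0Range = as.numeric(c(vals[["f0_min"]], vals[["f0_max"]])),
      nHarmonics = as.integer(vals[["n_harmonics"]]),
      band = as.numeric(c(vals[["band_min"]], vals[["band_max"]])),
      snrDb = as.numeric(vals[["snr_db"]]),
      sampleRate = as.numeric(vals[["sample_rate"]]),
      seed = as.integer(vals[["seed"]])
    )
    sc <- synthScene(cfg, dayTag = vals[["day"]],
                     sourceId = vals[["source"]])
    clips[[length(clips) + 1L]] <- sc$clip
    labels[[length(labels) + 1L]] <- sc$labels
  }
  structure(list(clips = clips, labels = labels, manifest = manifest),
            class = "syntheticBenchmark")
}

#' Write a benchmark to disk (WAV + label tables + manifest)
#'
#' @param benchmark a `syntheticBenchmark` from [makeBenchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(benchmark$clips)) {
    clip <- benchmark$clips[[i]]
    base <- file.path(dir, sourceId(clip))
    writeWav(clip, paste0(base, ".wav"))
    writeLabelTable(benchmark$labels[[i]], paste0(base, ".labels.tsv"))
  }
  writeLines(benchmark$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
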