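# Greenwood Function Cepstral Coefficients: perceptual frequency warping,
# warped-axis filter bank, and the log-energy cosine transform.

#' Construct a Greenwood perceptual scale
#'
#' Derives the cochlear-map warping constants from the species' hearing
#' band: \eqn{A = f_{min}/(1-k)} and \eqn{a = \log_{10}(f_{max}/A + k)},
#' so that perceived frequency runs from 0 at `fMin` to 1 at `fMax`. The
#' default k = 0.88 is the cross-species approximation of the cochlear
#' integration constant; the default 500-6000 Hz band is where barnacle
#' goose calls carry most of their spectral energy.
#'
#' @param fMin,fMax hearing/analysis band edges in Hz (0 < fMin < fMax).
#' @param k dimensionless integration constant, 0 < k < 1.
#' @return A [PerceptualScale-class] of family `"greenwood"`.
#' @examples
#' sc <- greenwoodScale(500, 6000, 0.88)
#' sc@A       # 4166.667 Hz
#' sc@a       # 0.36549
#' @export
greenwoodScale <- function(fMin = 500, fMax = 6000, k = 0.88) {
  .assertScalarNumeric(fMin, "fMin")
  .assertScalarNumeric(fMax, "fMax")
  if (!(k > 0 && k < 1)) stop("k must lie strictly between 0 and 1")
  if (fMax <= fMin) stop("need fMin < fMax")
  A <- fMin / (1 - k)
  a <- log10(fMax / A + k)
  new("PerceptualScale", family = "greenwood", k = k, A = A, a = a,
      fMin = fMin, fMax = fMax)
}

#' Construct a mel perceptual scale
#'
#' The human-hearing warping \eqn{F_{mel} = (1000/\log 2)\log(1 + F/1000)}
#' (1000 Hz maps to 1000 mel). Band edges only delimit the filter bank.
#'
#' @param fMin,fMax filter-bank band edges in Hz.
#' @return A [PerceptualScale-class] of family `"mel"`.
#' @export
melScale <- function(fMin = 500, fMax = 6000) {
  .assertScalarNumeric(fMin, "fMin")
  .assertScalarNumeric(fMax, "fMax")
  if (fMax <= fMin) stop("need fMin < fMax")
  new("PerceptualScale", family = "mel", k = NA_real_, A = NA_real_,
      a = NA_real_, fMin = fMin, fMax = fMax)
}

#' @rdname perceivedFrequency
#' @export
setMethod("perceivedFrequency", "PerceptualScale", function(f, scale) {
  if (any(f < 0)) stop("frequency must be non-negative")
  if (scale@family == "greenwood") {
    (1 / scale@a) * log10(f / scale@A + scale@k)
  } else {
    (1000 / log(2)) * log(1 + f / 1000)
  }
})

#' @rdname inversePerceivedFrequency
#' @export
setMethod("inversePerceivedFrequency", "PerceptualScale",
function(p, scale) {
  if (scale@family == "greenwood") {
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      stop("perceived frequency outside [0, 1] for a greenwood scale")
    scale@A * (10^(scale@a * p) - scale@k)
  } else {
    if (any(p < 0)) stop("perceived frequency must be non-negative")
    1000 * (2^(p / 1000) - 1)
  }
})

# Window profile over a filter support, parameterised by relative
# position r in [0, 1] (computed on the perceived axis, so the peak sits
# at the centre frequency).
.filterProfile <- function(r, shape) {
  switch(shape,
    hamming    = 0.54 - 0.46 * cos(2 * pi * r),
    hanning    = 0.5 * (1 - cos(2 * pi * r)),
    triangular = 1 - abs(2 * r - 1),
    stop("unknown filter shape: ", shape)
  )
}

#' Build a warped-axis critical-band filter bank
#'
#' Places `nFilters` band filters with centres uniformly spaced on the
#' perceived-frequency axis between the scale's band edges: with
#' \eqn{\Delta p = (p_{max}-p_{min})/(n+1)}, filter j is centred at
#' \eqn{p_{min} + j\,\Delta p} and spans its two neighbouring centres
#' (the boundary filters span to the band edges). The chosen window shape
#' is laid over each support on the perceived axis and every filter is
#' scaled to unit weight sum. Weights are tabulated over the one-sided
#' FFT bin grid.
#'
#' @param scale a [PerceptualScale-class].
#' @param nFilters number of band filters (default 20).
#' @param nFft FFT length in samples (default 2048).
#' @param sampleRate sampling rate in Hz.
#' @param shape `"hamming"` (default), `"hanning"` or `"triangular"`.
#' @return A [FilterBank-class] with an `nFilters x (nFft/2 + 1)` weight
#'   matrix.
#' @examples
#' bank <- buildFilterbank(greenwoodScale(500, 6000), sampleRate = 44100)
#' dim(filterWeights(bank))
#' @export
buildFilterbank <- function(scale, nFilters = 20L, nFft = 2048L,
                            sampleRate = 44100, shape = "hamming") {
  stopifnot(is(scale, "PerceptualScale"))
  .assertScalarNumeric(sampleRate, "sampleRate")
  if (scale@fMax > sampleRate / 2)
    stop("fMax (", scale@fMax, " Hz) exceeds the Nyquist frequency (",
         sampleRate / 2, " Hz)")
  nFilters <- as.integer(nFilters)
  nFft <- as.integer(nFft)

  pMin <- perceivedFrequency(scale@fMin, scale)
  pMax <- perceivedFrequency(scale@fMax, scale)
  dp <- (pMax - pMin) / (nFilters + 1)
  pGrid <- pMin + (0:(nFilters + 1)) * dp        # edges + centres
  fGrid <- inversePerceivedFrequency(pGrid, scale)

  binFreq <- (0:(nFft %/% 2)) * sampleRate / nFft
  binP <- perceivedFrequency(binFreq, scale)
  W <- matrix(0, nFilters, length(binFreq))
  for (j in seq_len(nFilters)) {
    lo <- pGrid[j]; hi <- pGrid[j + 2L]
    inside <- binP >= lo & binP <= hi
    r <- (binP[inside] - lo) / (hi - lo)
    W[j, inside] <- .filterProfile(r, shape)
    s <- sum(W[j, ])
    if (s <= 0)
      stop("filter ", j, " has empty support; increase nFft or widen band")
    W[j, ] <- W[j, ] / s
  }
  new("FilterBank", weights = W, centerFreqs = fGrid[2:(nFilters + 1L)],
      shape = shape, sampleRate = sampleRate, nFft = nFft, scale = scale)
}

#' Cosine transform of band log-energies (DCT-II, unnormalised)
#'
#' Converts per-band log-energies \eqn{S_k} into cepstral coefficients
#' \eqn{c_n = \sum_{k=0}^{K-1} S_k \cos(n (k + 1/2) \pi / K)}. A flat
#' band vector therefore maps to `c0 = K * s` with all higher coefficients
#' zero, and a DCT basis vector in band space maps to a single nonzero
#' coefficient of magnitude K/2.
#'
#' With K bands, `nCoeffs = K + 1` coefficients (c0 ... cK) are returned
#' by default so that the 0th coefficient is part of the feature vector;
#' note that cK is identically zero under this transform (cos((k+1/2)pi)
#' vanishes), mirroring the zero-padding convention of classical cepstral
#' toolboxes.
#'
#' @param S numeric vector of K band log-energies, or a `K x n` matrix
#'   (one frame per column).
#' @param nCoeffs number of coefficients to return (default K + 1).
#' @param phase `"dct2"` (default) uses the orthogonal DCT-II phase
#'   (k + 1/2); `"shifted"` uses phase (k - 1/2), kept only for
#'   comparison with transcriptions that print the transform that way.
#' @return matrix `nCoeffs x n` (a vector input is treated as one frame).
#' @export
cepstralTransform <- function(S, nCoeffs = NULL, phase = c("dct2", "shifted")) {
  phase <- match.arg(phase)
  if (is.vector(S)) S <- matrix(S, ncol = 1L)
  K <- nrow(S)
  if (is.null(nCoeffs)) nCoeffs <- K + 1L
  k0 <- seq_len(K) - 1L                      # 0-based band index
  off <- if (phase == "dct2") 0.5 else -0.5
  D <- outer(0:(nCoeffs - 1L), k0 + off,
             function(n, kk) cos(n * kk * pi / K))
  out <- D %*% S
  rownames(out) <- paste0("c", 0:(nCoeffs - 1L))
  out
}

# Hamming time window (periodic-symmetric form used in short-time DSP).
.hammingWindow <- function(N) 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1))

#' Compute cepstral coefficients for analysis frames
#'
#' The extraction pipeline per frame: Hamming time window, magnitude-
#' squared one-sided FFT, per-filter band energies (filter weights times
#' the power spectrum), natural log with a floor, then the cosine
#' transform of [cepstralTransform()]. An all-zero frame is valid: every
#' band energy sits at the floor, giving a finite flat-spectrum cepstrum.
#'
#' @param frames numeric matrix `frameLen x n` (one frame per column, as
#'   produced by [frameSequence()]), or a single frame vector. `frameLen`
#'   must equal the bank's FFT length.
#' @param bank a [FilterBank-class].
#' @param nCoeffs number of cepstral coefficients (default 21 for the
#'   20-filter bank: c0 ... c20 with c0 included).
#' @param energyFloor floor applied to band energies before the log
#'   (default 1e-10).
#' @param timeWindow `"hamming"` (default) or `"none"`.
#' @return matrix `nCoeffs x n` of cepstral coefficients.
#' @export
extractCepstra <- function(frames, bank, nCoeffs = 21L,
                           energyFloor = 1e-10,
                           timeWindow = c("hamming", "none")) {
  timeWindow <- match.arg(timeWindow)
  stopifnot(is(bank, "FilterBank"))
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  nFft <- as.integer(bank@nFft)
  if (nrow(frames) != nFft)
    stop("frame length ", nrow(frames), " does not match the bank's FFT ",
         "length ", nFft)
  if (timeWindow == "hamming")
    frames <- frames * .hammingWindow(nFft)
  spec <- stats::mvfft(frames)[seq_len(nFft %/% 2L + 1L), , drop = FALSE]
  power <- Re(spec * Conj(spec))
  bandE <- bank@weights %*% power
  S <- log(pmax(bandE, energyFloor))
  cepstralTransform(S, nCoeffs = nCoeffs)
}

#' Assemble a GfccFeatureSet from a coefficient matrix
#'
#' Builds the feature container directly from a matrix — useful for
#' simulation studies that bypass audio synthesis. Vectors are recycled
#' across frames.
#'
#' @param cepstra numeric matrix, one coefficient per row, one frame per
#'   column.
#' @param sequenceId sequence id per frame (frames sharing an id are
#'   aggregated at classification time).
#' @param label behaviour label per frame.
#' @param day day tag per frame (default `"day1"`).
#' @param clip source clip id per frame (default `"clip"`).
#' @param frameIndex frame index within its sequence (default: computed
#'   by order of appearance).
#' @return A [GfccFeatureSet-class].
#' @export
GfccFeatureSet <- function(cepstra, sequenceId, label, day = "day1",
                           clip = "clip", frameIndex = NULL) {
  cepstra <- as.matrix(cepstra)
  n <- ncol(cepstra)
  sequenceId <- rep_len(as.character(sequenceId), n)
  if (is.null(frameIndex))
    frameIndex <- stats::ave(seq_len(n), sequenceId, FUN = seq_along) - 1L
  meta <- data.frame(clip = rep_len(as.character(clip), n),
                     sequence_id = sequenceId,
                     frame_index = as.integer(frameIndex),
                     day = rep_len(as.character(day), n),
                     label = rep_len(as.character(label), n))
  .makeFeatureSet(cepstra, meta)
}

.makeFeatureSet <- function(mat, meta) {
  rownames(mat) <- paste0("c", seq_len(nrow(mat)) - 1L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cepstra = mat),
    colData = S4Vectors::DataFrame(meta)
  )
  new("GfccFeatureSet", se)
}

#' Extract a labeled cepstral feature set from audio clips
#'
#' Runs segmentation, framing and cepstral extraction over one or more
#' labeled clips and assembles a [GfccFeatureSet-class]: one column per
#' analysis frame, tagged with its clip, 100 ms sequence id, frame index,
#' day tag and behaviour label. Ordering is deterministic (clip order,
#' then window start, then frame offset).
#'
#' @param clips an [AudioClip-class] or list of them.
#' @param labelTables a label table data.frame (columns `start_s`,
#'   `end_s`, `label`) or a list parallel to `clips`.
#' @param scale a [PerceptualScale-class] (default greenwood 500-6000 Hz,
#'   k = 0.88).
#' @param nFilters,shape filter bank parameters (see [buildFilterbank()]).
#' @param frameLen,hop framing parameters; `NULL` selects
#'   [defaultFrameLength()] at the clip's rate and a 50% hop.
#' @param nCoeffs cepstral coefficients per frame (default 21).
#' @param rmsFloor optional sequence fidelity floor (see
#'   [segmentSequences()]).
#' @return A [GfccFeatureSet-class]; empty input yields a 0-column set.
#' @export
extractFeatures <- function(clips, labelTables,
                            scale = greenwoodScale(),
                            nFilters = 20L, shape = "hamming",
                            frameLen = NULL, hop = NULL, nCoeffs = 21L,
                            rmsFloor = NULL) {
  if (is(clips, "AudioClip")) clips <- list(clips)
  if (is.data.frame(labelTables)) labelTables <- list(labelTables)
  if (length(clips) != length(labelTables))
    stop("need one label table per clip")

  emptyMeta <- data.frame(clip = character(), sequence_id = character(),
                          frame_index = integer(), day = character(),
                          label = character())
  mats <- list(); metas <- list()
  banks <- list()  # one bank per distinct (rate, frameLen)
  for (i in seq_along(clips)) {
    clip <- clips[[i]]
    win <- segmentSequences(clip, labelTables[[i]], rmsFloor = rmsFloor)
    if (nrow(win) == 0L) next
    fs <- sampleRate(clip)
    fl <- if (is.null(frameLen)) defaultFrameLength(fs) else as.integer(frameLen)
    hp <- if (is.null(hop)) fl %/% 2L else as.integer(hop)
    key <- paste(fs, fl)
    if (is.null(banks[[key]]))
      banks[[key]] <- buildFilterbank(scale, nFilters = nFilters,
                                      nFft = fl, sampleRate = fs,
                                      shape = shape)
    offs <- .frameOffsets(win$length_samples[1], fl, hp)
    starts <- rep(win$start_sample, each = length(offs)) +
      rep(offs, times = nrow(win))
    idx <- outer(seq_len(fl), starts, `+`)
    frames <- matrix(audioSamples(clip)[idx], nrow = fl)
    mats[[length(mats) + 1L]] <-
      extractCepstra(frames, banks[[key]], nCoeffs = nCoeffs)
    metas[[length(metas) + 1L]] <- data.frame(
      clip = sourceId(clip),
      sequence_id = rep(win$sequence_id, each = length(offs)),
      frame_index = rep(seq_along(offs) - 1L, times = nrow(win)),
      day = dayTag(clip),
      label = rep(win$label, each = length(offs))
    )
  }
  if (!length(mats))
    return(.makeFeatureSet(matrix(0, nCoeffs, 0), emptyMeta))
  .makeFeatureSet(do.call(cbind, mats), do.call(rbind, metas))
}
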