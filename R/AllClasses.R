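#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats fft sd var prcomp rnorm runif rpois predict setNames
#' @importFrom utils combn read.delim write.table modifyList head
NULL

#' AudioClip: a mono audio signal with acquisition metadata
#'
#' Container for a single-channel field recording (or synthetic scene).
#' Amplitudes are dimensionless and normalised to lie in \[-1, 1\];
#' the sampling rate is carried so durations in seconds map to samples.
#'
#' @slot samples numeric vector of amplitudes in \[-1, 1\].
#' @slot sampleRate sampling rate in Hz (scalar, > 0).
#' @slot sourceId free-text identifier of the originating file or scene.
#' @slot dayTag categorical grouping key (e.g. `"day1"`), used by the
#'   day-split evaluation protocol.
#'
#' @seealso [readWav()], [synthScene()]
#' @export
setClass("AudioClip",
  slots = c(
    samples    = "numeric",
    sampleRate = "numeric",
    sourceId   = "character",
    dayTag     = "character"
  )
)

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (length(object@samples) && max(abs(object@samples)) > 1 + 1e-6)
    msg <- c(msg, "samples must lie in [-1, 1] (normalise on load)")
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (length(object@dayTag) != 1L)
    msg <- c(msg, "dayTag must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric amplitude vector in \[-1, 1\].
#' @param sampleRate sampling rate in Hz.
#' @param sourceId identifier string (defaults to `"clip"`).
#' @param dayTag grouping tag (defaults to `"day1"`).
#' @return An [AudioClip-class] object.
#' @examples
#' clip <- AudioClip(sin(2 * pi * 440 * seq_len(4410) / 44100), 44100)
#' duration(clip)
#' @export
AudioClip <- function(samples, sampleRate, sourceId = "clip", dayTag = "day1") {
  new("AudioClip", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate),
      sourceId = as.character(sourceId), dayTag = as.character(dayTag))
}

#' PerceptualScale: a Hz-to-perceived-frequency warping
#'
#' Parameterises the frequency warping used to place filter-bank centres.
#' The `greenwood` family is the cochlear-map warping
#' \eqn{F_p = (1/a)\,\log_{10}(F/A + k)} with species constants derived
#' from the hearing range: \eqn{A = f_{min}/(1-k)} and
#' \eqn{a = \log_{10}(f_{max}/A + k)}, so that the perceived frequency of
#' \eqn{f_{min}} is 0 and of \eqn{f_{max}} is 1. The `mel` family is the
#' human-hearing special case \eqn{F_{mel} = (1000/\log 2)\,\log(1 + F/1000)}.
#'
#' @slot family `"greenwood"` or `"mel"`.
#' @slot k dimensionless integration constant (greenwood; 0 < k < 1).
#' @slot A scale constant in Hz (greenwood).
#' @slot a dimensionless scale exponent (greenwood).
#' @slot fMin,fMax band edges in Hz delimiting the filter bank.
#'
#' @seealso [greenwoodScale()], [melScale()], [perceivedFrequency()]
#' @export
setClass("PerceptualScale",
  slots = c(
    family = "character",
    k      = "numeric",
    A      = "numeric",
    a      = "numeric",
    fMin   = "numeric",
    fMax   = "numeric"
  )
)

setValidity("PerceptualScale", function(object) {
  msg <- character()
  if (!object@family %in% c("greenwood", "mel"))
    msg <- c(msg, "family must be 'greenwood' or 'mel'")
  if (!(object@fMin > 0 && object@fMax > object@fMin))
    msg <- c(msg, "need 0 < fMin < fMax")
  if (object@family == "greenwood") {
    if (!(object@k > 0 && object@k < 1))
      msg <- c(msg, "greenwood k must satisfy 0 < k < 1")
    else {
      if (abs(object@A - object@fMin / (1 - object@k)) >
          1e-6 * object@A)
        msg <- c(msg, "A must equal fMin / (1 - k)")
      if (abs(object@a - log10(object@fMax / object@A + object@k)) > 1e-9)
        msg <- c(msg, "a must equal log10(fMax / A + k)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FilterBank: band filters on the warped frequency axis
#'
#' A set of overlapping band-pass weightings applied to a one-sided power
#' spectrum. Centres are uniformly spaced on the perceived-frequency axis
#' between the scale's band edges; each filter spans its two neighbouring
#' centres and is windowed (Hamming by default) over that support, then
#' scaled to unit weight sum.
#'
#' @slot weights `nFilters x (nFft/2 + 1)` matrix of non-negative gains.
#' @slot centerFreqs filter centre frequencies in Hz, strictly increasing.
#' @slot shape `"hamming"`, `"hanning"` or `"triangular"`.
#' @slot sampleRate sampling rate the bin grid refers to (Hz).
#' @slot nFft FFT length the bin grid refers to (samples).
#' @slot scale the [PerceptualScale-class] used to place the centres.
#'
#' @seealso [buildFilterbank()]
#' @export
setClass("FilterBank",
  slots = c(
    weights     = "matrix",
    centerFreqs = "numeric",
    shape       = "character",
    sampleRate  = "numeric",
    nFft        = "numeric",
    scale       = "PerceptualScale"
  )
)

setValidity("FilterBank", function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@centerFreqs))
    msg <- c(msg, "one weight row per centre frequency required")
  if (ncol(object@weights) != object@nFft / 2 + 1)
    msg <- c(msg, "weights must have nFft/2 + 1 columns (one-sided bins)")
  if (any(object@weights < 0))
    msg <- c(msg, "filter weights must be non-negative")
  if (is.unsorted(object@centerFreqs, strictly = TRUE))
    msg <- c(msg, "centre frequencies must be strictly increasing")
  if (!object@shape %in% c("hamming", "hanning", "triangular"))
    msg <- c(msg, "shape must be hamming, hanning or triangular")
  if (length(msg)) msg else TRUE
})

#' GfccFeatureSet: cepstral features with frame metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose `"cepstra"`
#' assay holds one column per 2048-sample analysis frame and one row per
#' cepstral coefficient (c0 ... c20 by default). Column metadata carries
#' `clip`, `sequence_id`, `frame_index`, `day` and `label`, which the
#' classifier and the evaluation protocols use for sequence-level
#' aggregation, leakage-free fold grouping and day splits.
#'
#' @seealso [extractFeatures()], [trainModelSet()], [runProtocol()]
#' @export
setClass("GfccFeatureSet", contains = "SummarizedExperiment")

setValidity("GfccFeatureSet", function(object) {
  msg <- character()
  if (!"cepstra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'cepstra' is required")
  need <- c("clip", "sequence_id", "frame_index", "day", "label")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SelectionResult: a chosen feature subset and its criterion value
#'
#' @slot selectedIndices 0-based coefficient indices (into c0 ... c20),
#'   sorted increasing; length equals `dTarget`.
#' @slot criterionValue the class-separability criterion evaluated on the
#'   selected subset.
#' @slot dTarget requested subset size.
#'
#' @seealso [branchAndBoundSelect()], [exhaustiveSelect()]
#' @export
setClass("SelectionResult",
  slots = c(
    selectedIndices = "integer",
    criterionValue  = "numeric",
    dTarget         = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@selectedIndices) != object@dTarget)
    msg <- c(msg, "selectedIndices length must equal dTarget")
  if (anyDuplicated(object@selectedIndices))
    msg <- c(msg, "selected indices must be unique")
  if (any(object@selectedIndices < 0))
    msg <- c(msg, "indices are 0-based and must be non-negative")
  if (length(msg)) msg else TRUE
})

#' NormalizationStats: per-feature standardisation parameters
#'
#' Mean and standard deviation of each retained feature, estimated on
#' training data only and applied unchanged to test data, so each training
#' column has zero mean and unit variance.
#'
#' @slot mean per-feature means.
#' @slot sd per-feature standard deviations (all > 0).
#' @seealso [fitNormalization()], [applyNormalization()]
#' @export
setClass("NormalizationStats",
  slots = c(mean = "numeric", sd = "numeric"))

setValidity("NormalizationStats", function(object) {
  msg <- character()
  if (length(object@mean) != length(object@sd))
    msg <- c(msg, "mean and sd must have the same length")
  if (any(object@sd <= 0))
    msg <- c(msg, "all standard deviations must be positive")
  if (length(msg)) msg else TRUE
})

#' GridSearchResult: tuned RBF-SVM hyperparameters
#'
#' Result of the power-of-two grid search over (C, gamma) with stratified,
#' sequence-grouped cross-validation.
#'
#' @slot bestC,bestGamma the winning grid point (ties broken toward the
#'   smaller C, then the smaller gamma).
#' @slot cvTable data.frame with columns `C`, `gamma`, `accuracy` (mean CV
#'   accuracy per grid point).
#' @seealso [gridSearchPair()]
#' @export
setClass("GridSearchResult",
  slots = c(bestC = "numeric", bestGamma = "numeric", cvTable = "data.frame"))

setValidity("GridSearchResult", function(object) {
  msg <- character()
  if (!all(c("C", "gamma", "accuracy") %in% colnames(object@cvTable)))
    msg <- c(msg, "cvTable needs columns C, gamma, accuracy")
  if (nrow(object@cvTable)) {
    top <- max(object@cvTable$accuracy)
    hit <- object@cvTable$C == object@bestC &
           object@cvTable$gamma == object@bestGamma
    if (!any(hit) || object@cvTable$accuracy[hit][1] < top - 1e-12)
      msg <- c(msg, "best pair must attain the maximal CV accuracy")
  }
  if (length(msg)) msg else TRUE
})

#' TrainedModelSet: the three pairwise SVMs plus preprocessing state
#'
#' Everything needed to classify new audio sequences: the three pairwise
#' RBF-SVM decision functions of the one-versus-one directed graph, the
#' training normalisation statistics, the selected coefficient subset and
#' the tuned hyperparameters per pair.
#'
#' @slot models named list of three pairwise models, keyed
#'   `"flushing|landing"`, `"flushing|foraging"`, `"landing|foraging"`.
#'   Each element is an [e1071::svm] fit (or, for testing, a function
#'   taking a feature matrix and returning `list(label=, decision=)`).
#' @slot norm [NormalizationStats-class] for the screened feature columns.
#' @slot selection [SelectionResult-class] (0-based coefficient indices).
#' @slot classLevels class order, `c("flushing", "landing", "foraging")`.
#' @slot tuning named list of [GridSearchResult-class] per pair.
#' @slot params misc fit parameters (grid, folds, seed, screened columns).
#' @seealso [trainModelSet()], [predictSequences()]
#' @export
setClass("TrainedModelSet",
  slots = c(
    models      = "list",
    norm        = "NormalizationStats",
    selection   = "SelectionResult",
    classLevels = "character",
    tuning      = "list",
    params      = "list"
  )
)

setValidity("TrainedModelSet", function(object) {
  msg <- character()
  if (length(object@models) != 3L)
    msg <- c(msg, "exactly three pairwise models required (K(K-1)/2, K=3)")
  pairs <- names(object@models)
  want <- c("flushing|landing", "flushing|foraging", "landing|foraging")
  if (!setequal(pairs, want))
    msg <- c(msg, paste("models must be keyed:", paste(want, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
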