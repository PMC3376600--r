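#' @rdname AudioClip-class
#' @param object,x an object.
#' @export
setGeneric("audioSamples", function(x) standardGeneric("audioSamples"))

#' @rdname AudioClip-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname AudioClip-class
#' @export
setGeneric("dayTag", function(x) standardGeneric("dayTag"))

#' @rdname AudioClip-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname AudioClip-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Map physical frequency to perceived frequency
#'
#' Applies the scale's warping: for the greenwood family
#' \eqn{F_p = (1/a)\log_{10}(F/A + k)} (so the band edges map to 0 and 1);
#' for the mel family \eqn{F_{mel} = (1000/\log 2)\log(1 + F/1000)}
#' (so 1000 Hz maps to 1000 mel). Strictly increasing in `f`.
#'
#' @param f frequency in Hz (vectorised, must be >= 0).
#' @param scale a [PerceptualScale-class].
#' @return perceived frequency (dimensionless for greenwood, mel for mel).
#' @examples
#' sc <- greenwoodScale(500, 6000)
#' perceivedFrequency(c(500, 6000), sc)  # 0 and 1
#' @export
setGeneric("perceivedFrequency", function(f, scale)
  standardGeneric("perceivedFrequency"), signature = "scale")

#' Map perceived frequency back to Hz
#'
#' Exact inverse of [perceivedFrequency()]; used to place filter-bank
#' centres laid out uniformly on the perceived axis.
#'
#' @param p perceived frequency (vectorised). For the greenwood family it
#'   must lie in \[0, 1\]; for mel it must be >= 0.
#' @param scale a [PerceptualScale-class].
#' @return frequency in Hz.
#' @export
setGeneric("inversePerceivedFrequency", function(p, scale)
  standardGeneric("inversePerceivedFrequency"), signature = "scale")

#' @rdname FilterBank-class
#' @param x an object.
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))

#' @rdname FilterBank-class
#' @export
setGeneric("centerFrequencies", function(x)
  standardGeneric("centerFrequencies"))

#' @rdname GfccFeatureSet-class
#' @param x an object.
#' @export
setGeneric("cepstra", function(x) standardGeneric("cepstra"))

#' @rdname GfccFeatureSet-class
#' @export
setGeneric("behaviour", function(x) standardGeneric("behaviour"))

#' @rdname GfccFeatureSet-class
#' @export
setGeneric("sequenceId", function(x) standardGeneric("sequenceId"))

#' @rdname SelectionResult-class
#' @param x an object.
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @rdname SelectionResult-class
#' @export
setGeneric("criterionValue", function(x) standardGeneric("criterionValue"))
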