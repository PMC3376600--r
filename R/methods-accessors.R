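# Accessor and show methods for the S4 containers.

#' @rdname AudioClip-class
#' @export
setMethod("audioSamples", "AudioClip", function(x) x@samples)

#' @rdname AudioClip-class
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)

#' @rdname AudioClip-class
#' @export
setMethod("dayTag", "AudioClip", function(x) x@dayTag)

#' @rdname AudioClip-class
#' @export
setMethod("sourceId", "AudioClip", function(x) x@sourceId)

#' @rdname AudioClip-class
#' @export
setMethod("duration", "AudioClip",
          function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip '%s' (%s): %d samples @ %g Hz (%.3f s), peak %.3f\n",
              object@sourceId, object@dayTag, length(object@samples),
              object@sampleRate, duration(object),
              max(abs(object@samples))))
})

setMethod("show", "PerceptualScale", function(object) {
  if (object@family == "greenwood") {
    cat(sprintf(
      "PerceptualScale greenwood: k=%g, A=%.4g Hz, a=%.6g, band %g-%g Hz\n",
      object@k, object@A, object@a, object@fMin, object@fMax))
  } else {
    cat(sprintf("PerceptualScale mel: band %g-%g Hz\n",
                object@fMin, object@fMax))
  }
})

#' @rdname FilterBank-class
#' @export
setMethod("filterWeights", "FilterBank", function(x) x@weights)

#' @rdname FilterBank-class
#' @export
setMethod("centerFrequencies", "FilterBank", function(x) x@centerFreqs)

setMethod("show", "FilterBank", function(object) {
  cat(sprintf(
    "FilterBank: %d %s filters, centres %.1f-%.1f Hz, nFft=%d @ %g Hz\n",
    nrow(object@weights), object@shape, min(object@centerFreqs),
    max(object@centerFreqs), as.integer(object@nFft), object@sampleRate))
})

#' @rdname GfccFeatureSet-class
#' @export
setMethod("cepstra", "GfccFeatureSet",
          function(x) SummarizedExperiment::assay(x, "cepstra"))

#' @rdname GfccFeatureSet-class
#' @export
setMethod("behaviour", "GfccFeatureSet",
          function(x) SummarizedExperiment::colData(x)$label)

#' @rdname GfccFeatureSet-class
#' @export
setMethod("sequenceId", "GfccFeatureSet",
          function(x) SummarizedExperiment::colData(x)$sequence_id)

#' @rdname GfccFeatureSet-class
#' @export
setMethod("dayTag", "GfccFeatureSet",
          function(x) SummarizedExperiment::colData(x)$day)

setMethod("show", "GfccFeatureSet", function(object) {
  lab <- table(behaviour(object))
  cat(sprintf(
    "GfccFeatureSet: %d coefficients x %d frames (%d sequences)\n",
    nrow(object), ncol(object), length(unique(sequenceId(object)))))
  cat("  frames per label:",
      paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
})

#' @rdname SelectionResult-class
#' @export
setMethod("selectedIndices", "SelectionResult", function(x) x@selectedIndices)

#' @rdname SelectionResult-class
#' @export
setMethod("criterionValue", "SelectionResult", function(x) x@criterionValue)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: d=%d, indices {%s}, criterion %.6g\n",
              object@dTarget,
              paste(object@selectedIndices, collapse = ", "),
              object@criterionValue))
})

setMethod("show", "NormalizationStats", function(object) {
  cat(sprintf("NormalizationStats for %d features\n", length(object@mean)))
})

setMethod("show", "GridSearchResult", function(object) {
  cat(sprintf(
    "GridSearchResult: best C=%g, gamma=%g (CV accuracy %.4f over %d points)\n",
    object@bestC, object@bestGamma,
    max(object@cvTable$accuracy), nrow(object@cvTable)))
})

setMethod("show", "TrainedModelSet", function(object) {
  cat("TrainedModelSet (one-vs-one DAG, 3 pairwise RBF SVMs)\n")
  cat("  selected coefficients:",
      paste(object@selection@selectedIndices, collapse = ", "), "\n")
  for (p in names(object@tuning)) {
    g <- object@tuning[[p]]
    cat(sprintf("  %-18s C=%g gamma=%g\n", p, g@bestC, g@bestGamma))
  }
})
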