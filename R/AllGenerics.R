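#' @name chromstack-accessors
#' @title Accessors for chromstack S4 objects
#' @description Slot accessors for [StackedHMM-class], [StackedHMMFit-class],
#'   [ObservationChunk-class] and [Segmentation-class]. Always use these
#'   rather than `@`.
#' @param object an object of the relevant class.
#' @return The slot contents (see each accessor).
NULL

#' @rdname chromstack-accessors
#' @export
setGeneric("emissionProbs", function(object) standardGeneric("emissionProbs"))
#' @rdname chromstack-accessors
#' @export
setGeneric("transitionProbs", function(object) standardGeneric("transitionProbs"))
#' @rdname chromstack-accessors
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))
#' @rdname chromstack-accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))
#' @rdname chromstack-accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname chromstack-accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname chromstack-accessors
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))
#' @rdname chromstack-accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname chromstack-accessors
#' @export
setGeneric("binSize", function(object) standardGeneric("binSize"))
#' @rdname chromstack-accessors
#' @export
setGeneric("chromSizes", function(object) standardGeneric("chromSizes"))
#' @rdname chromstack-accessors
#' @export
setGeneric("binCalls", function(object) standardGeneric("binCalls"))

#' @rdname chromstack-accessors
#' @export
setMethod("emissionProbs", "StackedHMM", function(object) object@emissions)
#' @rdname chromstack-accessors
#' @export
setMethod("transitionProbs", "StackedHMM", function(object) object@transitions)
#' @rdname chromstack-accessors
#' @export
setMethod("initialProbs", "StackedHMM", function(object) object@initialProbs)
#' @rdname chromstack-accessors
#' @export
setMethod("featureNames", "StackedHMM", function(object) object@featureNames)
#' @rdname chromstack-accessors
#' @export
setMethod("nStates", "StackedHMM", function(object) nrow(object@emissions))
#' @rdname chromstack-accessors
#' @export
setMethod("nFeatures", "StackedHMM", function(object) ncol(object@emissions))
#' @rdname chromstack-accessors
#' @export
setMethod("logLikTrace", "StackedHMMFit", function(object) object@logLikTrace)

#' @rdname chromstack-accessors
#' @export
setMethod("binCalls", "ObservationChunk", function(object) object@calls)

#' @rdname chromstack-accessors
#' @export
setMethod("stateLabels", "Segmentation", function(object) object@stateLabels)
#' @rdname chromstack-accessors
#' @export
setMethod("binSize", "Segmentation", function(object) object@binSize)
#' @rdname chromstack-accessors
#' @export
setMethod("chromSizes", "Segmentation", function(object) object@chromSizes)
#' @rdname chromstack-accessors
#' @export
setMethod("nStates", "Segmentation", function(object) length(object@stateLabels))

setMethod("show", "StackedHMM", function(object) {
  cat(sprintf(
    "%s: %d states x %d features\n", class(object),
    nStates(object), nFeatures(object)
  ))
  cat("  emission range: [",
      sprintf("%.4g", min(object@emissions)), ", ",
      sprintf("%.4g", max(object@emissions)), "]\n", sep = "")
  if (is(object, "StackedHMMFit") && length(object@logLikTrace)) {
    cat(sprintf(
      "  %d training iterations, final sampled logLik %.2f\n",
      length(object@logLikTrace), tail(object@logLikTrace, 1)
    ))
  }
})

setMethod("show", "ObservationChunk", function(object) {
  cat(sprintf(
    "ObservationChunk %s: %d bins x %d datasets (startBin %d)\n",
    object@tag, nrow(object@calls), ncol(object@calls), object@startBin
  ))
})

setMethod("show", "Segmentation", function(object) {
  nb <- sum(vapply(object@states, length, integer(1)))
  cat(sprintf(
    "Segmentation: %d states over %d chromosomes (%d bins of %d bp)\n",
    nStates(object), length(object@states), nb, object@binSize
  ))
})
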