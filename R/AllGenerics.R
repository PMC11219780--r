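#' @include AllClasses.R
NULL

#' @rdname IndicatorExperiment
#' @param x,object an `IndicatorExperiment`
#' @export
setGeneric("indicatorNames", function(x) standardGeneric("indicatorNames"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("indicatorValues", function(x) standardGeneric("indicatorValues"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("inputMatrix", function(x) standardGeneric("inputMatrix"))

#' @rdname IndicatorExperiment
#' @export
setGeneric("outcomeVector", function(x) standardGeneric("outcomeVector"))

#' @rdname MarkerModule
#' @param x a `MarkerModule`
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @rdname MarkerModule
#' @export
setGeneric("moduleComplement", function(x) standardGeneric("moduleComplement"))

#' @rdname MarkerModule
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))

#' @rdname MarkerModule
#' @export
setGeneric("mergeTree", function(x) standardGeneric("mergeTree"))

#' @rdname EWISeries
#' @param x an `EWISeries`
#' @export
setGeneric("ewiValues", function(x) standardGeneric("ewiValues"))

#' @rdname EWISeries
#' @export
setGeneric("flaggedSamples", function(x) standardGeneric("flaggedSamples"))

#' @rdname BPNetworkFit
#' @param x a `BPNetworkFit`
#' @export
setGeneric("networkModel", function(x) standardGeneric("networkModel"))

#' @rdname BPNetworkFit
#' @export
setGeneric("geTrace", function(x) standardGeneric("geTrace"))

## ---- IndicatorExperiment accessors -----------------------------------------

#' @rdname IndicatorExperiment
#' @export
setMethod("indicatorNames", "IndicatorExperiment", function(x) rownames(x))

#' @rdname IndicatorExperiment
#' @export
setMethod("sampleIDs", "IndicatorExperiment", function(x) colnames(x))

#' @rdname IndicatorExperiment
#' @export
setMethod("outcomeName", "IndicatorExperiment",
          function(x) metadata(x)$outcomeName)

#' @rdname IndicatorExperiment
#' @export
setMethod("isScaled", "IndicatorExperiment",
          function(x) isTRUE(metadata(x)$scaled))

#' @rdname IndicatorExperiment
#' @export
setMethod("missingMask", "IndicatorExperiment",
          function(x) assay(x, "mask"))

#' Indicator values as a samples x indicators matrix
#' @rdname IndicatorExperiment
#' @export
setMethod("indicatorValues", "IndicatorExperiment",
          function(x) t(assay(x, "values")))

#' Input (non-outcome) indicators, samples x indicators
#' @rdname IndicatorExperiment
#' @export
setMethod("inputMatrix", "IndicatorExperiment", function(x) {
  v <- indicatorValues(x)
  v[, setdiff(colnames(v), outcomeName(x)), drop = FALSE]
})

#' @rdname IndicatorExperiment
#' @export
setMethod("outcomeVector", "IndicatorExperiment", function(x) {
  indicatorValues(x)[, outcomeName(x)]
})

setMethod("show", "IndicatorExperiment", function(object) {
  cat(sprintf("IndicatorExperiment: %d indicators x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  outcome: %s | scaled: %s | missing cells: %d\n",
              outcomeName(object), isScaled(object),
              sum(assay(object, "mask"))))
})

## ---- other accessors -------------------------------------------------------

#' @rdname MarkerModule
#' @export
setMethod("moduleMembers", "MarkerModule", function(x) x@members)

#' @rdname MarkerModule
#' @export
setMethod("moduleComplement", "MarkerModule", function(x) x@complement)

#' @rdname MarkerModule
#' @export
setMethod("importanceScores", "MarkerModule", function(x) x@importance)

#' @rdname MarkerModule
#' @export
setMethod("mergeTree", "MarkerModule", function(x) x@tree)

setMethod("show", "MarkerModule", function(object) {
  cat(sprintf("MarkerModule: %d members (of %d indicators), mode '%s'\n",
              length(object@members),
              length(object@members) + length(object@complement),
              object@mode))
  cat(sprintf("  cut height %.4g at percentile %g (minSize %d)\n",
              object@cutHeight, object@percentile, object@minSize))
  cat("  members:", paste(object@members, collapse = ", "), "\n")
})

#' @rdname EWISeries
#' @export
setMethod("ewiValues", "EWISeries", function(x) {
  stats::setNames(x@ewi, x@sampleIDs)
})

#' @rdname EWISeries
#' @export
setMethod("flaggedSamples", "EWISeries", function(x) x@flagged)

setMethod("show", "EWISeries", function(object) {
  cat(sprintf("EWISeries over %d samples (guard epsilon %.1g)\n",
              length(object@sampleIDs), object@epsilon))
  cat(sprintf("  saturated: %d | flagged: %s\n", sum(object@saturated),
              if (length(object@flagged))
                paste(object@sampleIDs[object@flagged], collapse = ", ")
              else "(not flagged yet or none)"))
})

#' @rdname BPNetworkFit
#' @export
setMethod("networkModel", "BPNetworkFit", function(x) x@model)

#' @rdname BPNetworkFit
#' @export
setMethod("geTrace", "BPNetworkFit", function(x) x@geTrace)

setMethod("show", "BPNetwork", function(object) {
  cat(sprintf("BPNetwork: %d -> %d -> %d (%s hidden, %s output)\n",
              ncol(object@W), nrow(object@W), nrow(object@Wout),
              object@hiddenTransfer, object@outputTransfer))
})

setMethod("show", "BPNetworkFit", function(object) {
  show(object@model)
  cat(sprintf("  trained %d epochs, final GE = %.3g\n",
              length(object@geTrace), object@finalGE))
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport (n = %d samples)\n", object@nSamples))
  print(object@blockStats)
  cat(sprintf("  delta = mean|rho|_within - mean|rho|_cross = %.4f\n",
              object@delta))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d samples x %d inputs + outcome, ",
                     "module %d (lambda %.2f)\n"),
              object@nSamples, object@nIndicators, object@moduleSize,
              object@lambda))
  cat(sprintf("  anomalies: %d (shift %.1f SD, skew %.2f) | missing %.1f%% | seed %d\n",
              object@nAnomalies, object@anomalyShift, object@anomalySkewness,
              100 * object@missingRate, object@seed))
})

setMethod("show", "SplitIndex", function(object) {
  cat(sprintf("SplitIndex (%s): %d train / %d test (fraction %.2f)\n",
              object@mode, length(object@train), length(object@test),
              object@fraction))
})
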