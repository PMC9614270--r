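#' Accessors for pipeline containers
#'
#' Small accessor family for the S4 containers: sampling rate, channel
#' labels, patient identifier, segment count, total clean duration, burst
#' suppression scalars and frame counts.
#'
#' @param object a pipeline container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("cleanDuration", function(object) standardGeneric("cleanDuration"))
#' @rdname accessors
#' @export
setGeneric("bsr", function(object) standardGeneric("bsr"))
#' @rdname accessors
#' @export
setGeneric("lsp", function(object) standardGeneric("lsp"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameStarts", function(object) standardGeneric("frameStarts"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SegmentSeries", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "SegmentSeries", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("patientId", "EEGRecording", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "SegmentSeries", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("patientId", "SpectralFrameSeries", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "CovarianceFrameSeries", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("nSegments", "SegmentSeries", function(object) length(object@starts))
#' @rdname accessors
#' @export
setMethod("cleanDuration", "SegmentSeries",
  function(object) sum(object@ends - object@starts))
#' @rdname accessors
#' @export
setMethod("bsr", "BurstSuppressionProfile", function(object) object@bsr)
#' @rdname accessors
#' @export
setMethod("lsp", "BurstSuppressionProfile", function(object) object@lsp)
#' @rdname accessors
#' @export
setMethod("nFrames", "SpectralFrameSeries", function(object) length(object@frameStarts))
#' @rdname accessors
#' @export
setMethod("nFrames", "CovarianceFrameSeries", function(object) length(object@frameStarts))
#' @rdname accessors
#' @export
setMethod("frameStarts", "SpectralFrameSeries", function(object) object@frameStarts)
#' @rdname accessors
#' @export
setMethod("frameStarts", "CovarianceFrameSeries", function(object) object@frameStarts)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording '", object@patientId, "': ",
      nrow(object@signal), " channels (",
      paste(object@channelLabels, collapse = ", "), "), ",
      ncol(object@signal), " samples @ ", object@samplingRate, " Hz (",
      sprintf("%.1f", ncol(object@signal) / object@samplingRate / 60),
      " min)\n", sep = "")
})

setMethod("show", "SegmentSeries", function(object) {
  cat("SegmentSeries '", object@sourceId, "': ", nSegments(object),
      " segments, ", sprintf("%.1f", cleanDuration(object) / 60),
      " min clean @ ", object@samplingRate, " Hz\n", sep = "")
})

setMethod("show", "BurstSuppressionProfile", function(object) {
  cat("BurstSuppressionProfile: BSR ", sprintf("%.3f", object@bsr),
      ", LSP ", sprintf("%.1f", object@lsp), " s over ",
      sprintf("%.1f", object@analyzedDuration / 60), " min analyzed\n",
      sep = "")
})

setMethod("show", "SpectralFrameSeries", function(object) {
  cat("SpectralFrameSeries '", object@patientId, "': ", nFrames(object),
      " frames x ", length(object@freqGrid), " frequencies [",
      min(object@freqGrid), ", ", max(object@freqGrid), "] Hz\n", sep = "")
})

setMethod("show", "CovarianceFrameSeries", function(object) {
  d <- dim(object@matrices)
  cat("CovarianceFrameSeries '", object@patientId, "': ", d[3],
      " frames of ", d[1], "x", d[2], " SPD matrices\n", sep = "")
})

setMethod("show", "BaggedEnsemble", function(object) {
  cat("BaggedEnsemble (", object@kind, "): ", length(object@estimators),
      " saved estimators, final acceptance threshold ",
      sprintf("%.4f", utils::tail(object@thresholdHistory, 1)), "\n", sep = "")
})

setMethod("show", "FusionState", function(object) {
  cat("FusionState: shifted subset {", paste(object@subset, collapse = ", "),
      "}\n  thresholds: ",
      paste(sprintf("%s=%.3f", names(object@thresholds), object@thresholds),
            collapse = ", "),
      "\n  training AUCs: ",
      paste(sprintf("%s=%.3f", names(object@trainingAucs), object@trainingAucs),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "GroupedModelSet", function(object) {
  cat("GroupedModelSet: dedicated stacks for {",
      paste(object@groups, collapse = ", "),
      "} + all-medications fallback (minGroupSize ",
      object@minGroupSize, ")\n", sep = "")
})
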