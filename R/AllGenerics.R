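#' Accessors
#'
#' Small accessor generics for the package's containers: `samples()` returns
#' the channels x time matrix, `samplingRate()` the rate in Hz,
#' `channelNames()` the channel (or bipolar pair) labels, `nChannels()` the
#' channel count, `strengths()` the named strength vector, and `adjacency()`
#' the adjacency matrix.
#'
#' @param x a package object.
#' @return the slot value; see details per class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("strengths", function(x) standardGeneric("strengths"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setMethod("samples", "RecordingSegment", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samples", "BipolarRecording", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "RecordingSegment", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "BipolarRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EnvelopeEpochs", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("channelNames", "RecordingSegment", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "BipolarRecording", function(x) x@pairNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EnvelopeEpochs", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "SkewnessMatrix", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "AdjacencyMatrix", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "StrengthVector", function(x) names(x@s))

#' @rdname accessors
#' @export
setMethod("nChannels", "RecordingSegment", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("nChannels", "BipolarRecording", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("nChannels", "EnvelopeEpochs", function(x) dim(x@values)[1L])

#' @rdname accessors
#' @export
setMethod("strengths", "StrengthVector", function(x) x@s)
#' @rdname accessors
#' @export
setMethod("adjacency", "AdjacencyMatrix", function(x) x@Z)

#' @export
#' @describeIn SkewnessMatrix-class the raw N x T matrix.
setMethod("as.matrix", "SkewnessMatrix", function(x, ...) x@Y)
#' @export
#' @describeIn AdjacencyMatrix-class the raw N x N matrix.
setMethod("as.matrix", "AdjacencyMatrix", function(x, ...) x@Z)

setMethod("show", "RecordingSegment", function(object) {
  cat(sprintf("RecordingSegment '%s': %d channels x %d samples @ %g Hz (%.1f s), %d bad\n",
              object@patientId, nrow(object@samples), ncol(object@samples),
              object@fs, ncol(object@samples) / object@fs,
              sum(object@badFlags)))
})

setMethod("show", "BipolarRecording", function(object) {
  cat(sprintf("BipolarRecording '%s': %d pairs x %d samples @ %g Hz\n",
              object@patientId, nrow(object@samples), ncol(object@samples),
              object@fs))
})

setMethod("show", "EnvelopeEpochs", function(object) {
  d <- dim(object@values)
  cat(sprintf("EnvelopeEpochs: %d channels x %d epochs x %d samples (epoch %g s)\n",
              d[1L], d[2L], d[3L], object@epochLen))
})

setMethod("show", "SkewnessMatrix", function(object) {
  cat(sprintf("SkewnessMatrix: %d channels x %d epochs, %d degenerate cells\n",
              nrow(object@Y), ncol(object@Y), sum(object@degenerateMask)))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  z <- object@Z[upper.tri(object@Z)]
  cat(sprintf("AdjacencyMatrix: %d nodes, mean |rho| %.3f, max %.3f\n",
              nrow(object@Z), mean(z), max(z)))
})

setMethod("show", "StrengthVector", function(object) {
  cat(sprintf("StrengthVector '%s': %d channels, range [%.3f, %.3f]\n",
              object@patientId, length(object@s), min(object@s), max(object@s)))
})

setMethod("show", "RocResult", function(object) {
  ci <- if (is.na(object@ciLow)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", object@ciLow, object@ciHigh)
  cat(sprintf("RocResult: AUC %.3f%s over %d positives / %d negatives\n",
              object@auc, ci, object@nPos, object@nNeg))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d patients x %d channels, %g s @ %g Hz\n",
    "  rates %g (epileptic) vs %g (normal) events/s, amplitude %gx RMS\n",
    "  coupling %g, effectOutcome %g, seed %d\n"),
    object@nPatients, object@nChannels, object@duration, object@fs,
    object@eventRateEpileptic, object@eventRateNormal,
    object@eventAmplitude, object@coupling, object@effectOutcome,
    as.integer(object@seed)))
})

setMethod("show", "SimCohort", function(object) {
  cat(sprintf("SimCohort: %d patients (%s)\n", length(object@recordings),
              paste(table(object@outcomes$group), collapse = " / ")))
})
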