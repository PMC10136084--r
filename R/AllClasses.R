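#' @import methods
NULL

#' Raw multichannel iEEG segment
#'
#' One patient's referential recording: a channels x time sample matrix in
#' microvolts, the sampling rate, channel names in electrode-shaft notation
#' (e.g. \code{"A1"}, \code{"A2"}, ..., \code{"B1"}), and per-channel bad
#' flags. Flagged channels carry no data guarantees and are dropped by
#' [removeBadChannels()] before any computation.
#'
#' @slot samples numeric matrix, channels x time.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector, one per row of `samples`.
#' @slot badFlags logical vector marking channels to exclude.
#' @slot patientId single string.
#' @export
setClass("RecordingSegment",
  representation(
    samples = "matrix",
    fs = "numeric",
    channelNames = "character",
    badFlags = "logical",
    patientId = "character"
  )
)

setValidity("RecordingSegment", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@channelNames))
    msg <- c(msg, "channelNames length must equal the number of sample rows")
  if (length(object@badFlags) != length(object@channelNames))
    msg <- c(msg, "badFlags must align with channelNames")
  if (length(object@patientId) != 1L)
    msg <- c(msg, "patientId must be a single string")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(msg)) msg else TRUE
})

#' @param samples,fs,channelNames,badFlags,patientId see slots.
#' @rdname RecordingSegment-class
#' @export
RecordingSegment <- function(samples, fs, channelNames = rownames(samples),
                             badFlags = rep(FALSE, nrow(samples)),
                             patientId = "patient") {
  samples <- as.matrix(samples)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(nrow(samples)))
  rownames(samples) <- channelNames
  new("RecordingSegment", samples = samples, fs = as.numeric(fs),
      channelNames = as.character(channelNames),
      badFlags = as.logical(badFlags), patientId = patientId)
}

#' Bipolar-rereferenced recording
#'
#' Channels are differences between adjacent contacts on the same electrode
#' shaft ("A1-A2" = A1 minus A2). `flatFlags` marks channels found constant
#' (fewer than two local maxima) during envelope extraction.
#'
#' @slot samples numeric matrix, bipolar channels x time.
#' @slot pairNames character, "contactA-contactB" per row.
#' @slot fs sampling rate in Hz.
#' @slot patientId single string.
#' @slot flatFlags logical per channel; set by [upperEnvelope()].
#' @export
setClass("BipolarRecording",
  representation(
    samples = "matrix",
    pairNames = "character",
    fs = "numeric",
    patientId = "character",
    flatFlags = "logical"
  )
)

setValidity("BipolarRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@pairNames))
    msg <- c(msg, "pairNames length must equal the number of sample rows")
  if (length(object@flatFlags) &&
      length(object@flatFlags) != length(object@pairNames))
    msg <- c(msg, "flatFlags must align with pairNames")
  if (length(msg)) msg else TRUE
})

#' @param samples,pairNames,fs,patientId,flatFlags see slots.
#' @rdname BipolarRecording-class
#' @export
BipolarRecording <- function(samples, pairNames, fs, patientId = "patient",
                             flatFlags = rep(FALSE, nrow(samples))) {
  samples <- as.matrix(samples)
  new("BipolarRecording", samples = samples, pairNames = as.character(pairNames),
      fs = as.numeric(fs), patientId = patientId, flatFlags = as.logical(flatFlags))
}

#' Epoched envelope container
#'
#' The upper envelope cut into non-overlapping epochs: an N x T x L array
#' (channels x epochs x samples-per-epoch) with L = round(fs * epochLen).
#' The trailing partial epoch, if any, is dropped.
#'
#' @slot values numeric array N x T x L.
#' @slot fs sampling rate in Hz.
#' @slot epochLen epoch length in seconds.
#' @slot channelNames bipolar channel names.
#' @slot flatFlags logical per channel, carried from [upperEnvelope()].
#' @export
setClass("EnvelopeEpochs",
  representation(
    values = "array",
    fs = "numeric",
    epochLen = "numeric",
    channelNames = "character",
    flatFlags = "logical"
  )
)

setValidity("EnvelopeEpochs", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "values must be a channels x epochs x samples array")
  else if (d[1L] != length(object@channelNames))
    msg <- c(msg, "first dimension must match channelNames")
  if (length(object@epochLen) != 1L || object@epochLen <= 0)
    msg <- c(msg, "epochLen must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Per-channel, per-epoch envelope skewness
#'
#' The N x T feature matrix Y: entry (i, t) is the biased sample skewness of
#' channel i's envelope samples within epoch t. `degenerateMask` marks
#' zero-variance epochs whose skewness was defined as 0.
#'
#' @slot Y numeric matrix N x T.
#' @slot channelNames character.
#' @slot degenerateMask logical matrix N x T.
#' @export
setClass("SkewnessMatrix",
  representation(Y = "matrix", channelNames = "character",
                 degenerateMask = "matrix")
)

setValidity("SkewnessMatrix", function(object) {
  msg <- character()
  if (nrow(object@Y) != length(object@channelNames))
    msg <- c(msg, "channelNames must match rows of Y")
  if (!all(dim(object@degenerateMask) == dim(object@Y)))
    msg <- c(msg, "degenerateMask must have the shape of Y")
  if (anyNA(object@Y) || any(!is.finite(object@Y)))
    msg <- c(msg, "Y must be finite")
  if (length(msg)) msg else TRUE
})

#' Functional network adjacency
#'
#' Symmetric N x N matrix of absolute Spearman correlations between channel
#' skewness time series; diagonal forced to zero; entries in [0, 1].
#'
#' @slot Z numeric matrix N x N.
#' @slot channelNames character.
#' @export
setClass("AdjacencyMatrix",
  representation(Z = "matrix", channelNames = "character")
)

setValidity("AdjacencyMatrix", function(object) {
  Z <- object@Z
  msg <- character()
  if (nrow(Z) != ncol(Z)) msg <- c(msg, "Z must be square")
  if (nrow(Z) != length(object@channelNames))
    msg <- c(msg, "channelNames must match Z")
  if (any(abs(Z - t(Z)) > 1e-12)) msg <- c(msg, "Z must be symmetric")
  if (any(diag(Z) != 0)) msg <- c(msg, "diagonal of Z must be 0")
  if (any(Z < 0) || any(Z > 1)) msg <- c(msg, "entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Node connectivity strength
#'
#' Per-channel sum of adjacency edge weights; each entry lies in [0, N - 1].
#'
#' @slot s named numeric vector.
#' @slot patientId single string.
#' @export
setClass("StrengthVector",
  representation(s = "numeric", patientId = "character")
)

setValidity("StrengthVector", function(object) {
  msg <- character()
  if (is.null(names(object@s))) msg <- c(msg, "s must be named by channel")
  if (any(object@s < 0)) msg <- c(msg, "strengths must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ROC curve with AUC
#'
#' Thresholds sweep the score range from +Inf (nothing called positive,
#' sensitivity 0 / FPR 0) to -Inf (everything positive, both 1); a score is
#' called positive when it strictly exceeds the threshold. AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney U statistic
#' with ties credited one half.
#'
#' @slot thresholds,sensitivity,fpr numeric vectors of equal length.
#' @slot auc area under the curve in [0, 1].
#' @slot ciLow,ciHigh bootstrap 95% CI bounds (NA when not computed).
#' @slot nPos,nNeg class counts.
#' @export
setClass("RocResult",
  representation(
    thresholds = "numeric", sensitivity = "numeric", fpr = "numeric",
    auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
    nPos = "integer", nNeg = "integer"
  )
)

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic iEEG generator. Background is Gaussian
#' 1/f^`baselineExponent` noise at unit RMS; transient oscillatory events
#' (sinusoid x Hann window) ride on it. Event times follow an inhomogeneous
#' Poisson process whose per-second intensity mixes a constant with a shared
#' log-Gaussian latent process; `coupling` in [0, 1] sets the mixture weight
#' and thereby how strongly epileptic channels co-vary. `effectOutcome`
#' controls, for poor-outcome patients, how many epileptic-behaving channels
#' lie outside the labeled (resected/onset) tissue.
#'
#' @export
setClass("SimConfig",
  representation(
    nPatients = "numeric", nChannels = "numeric", fracEpileptic = "numeric",
    fs = "numeric", duration = "numeric", baselineExponent = "numeric",
    eventRateEpileptic = "numeric", eventRateNormal = "numeric",
    eventFreqRange = "numeric", eventDurationRange = "numeric",
    eventAmplitude = "numeric", coupling = "numeric",
    effectOutcome = "numeric", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@nChannels) || object@nChannels < 2)
    msg <- c(msg, "nChannels must be >= 2")
  if (!one(object@fracEpileptic) || object@fracEpileptic < 0 ||
      object@fracEpileptic > 1)
    msg <- c(msg, "fracEpileptic must lie in [0, 1]")
  if (one(object@fracEpileptic) && one(object@nChannels) &&
      round(object@fracEpileptic * object@nChannels) < 1)
    msg <- c(msg, "fracEpileptic * nChannels must be at least 1")
  if (!one(object@fs) || object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(object@eventFreqRange) != 2L ||
      object@eventFreqRange[1L] < 80 ||
      object@eventFreqRange[2L] >= object@fs / 2 ||
      diff(object@eventFreqRange) < 0)
    msg <- c(msg, "eventFreqRange must be an ordered pair within [80, fs/2)")
  if (length(object@eventDurationRange) != 2L ||
      any(object@eventDurationRange <= 0) ||
      diff(object@eventDurationRange) < 0)
    msg <- c(msg, "eventDurationRange must be an ordered positive pair")
  if (!one(object@coupling) || object@coupling < 0 || object@coupling > 1)
    msg <- c(msg, "coupling must lie in [0, 1]")
  if (!one(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be positive")
  if (one(object@duration) &&
      object@duration * max(object@eventRateEpileptic,
                            object@eventRateNormal) < 1)
    msg <- c(msg, "duration x event rate must give at least 1 expected event")
  if (length(msg)) msg else TRUE
})

#' Simulated cohort with ground truth
#'
#' @slot recordings list of [RecordingSegment-class].
#' @slot truth list of per-channel logical vectors (epileptic label).
#' @slot outcomes data.frame with patient, ilae, engel, group.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("SimCohort",
  representation(recordings = "list", truth = "list",
                 outcomes = "data.frame", config = "SimConfig")
)

setValidity("SimCohort", function(object) {
  msg <- character()
  if (length(object@recordings) != length(object@truth))
    msg <- c(msg, "recordings and truth must have equal length")
  ok <- mapply(function(r, tr) length(tr) == length(r@channelNames),
               object@recordings, object@truth)
  if (length(ok) && !all(ok))
    msg <- c(msg, "each truth vector must match its recording's channel count")
  if (length(msg)) msg else TRUE
})
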