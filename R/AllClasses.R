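#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib EEGmicrostates, .registration = TRUE
NULL

.EEG_GROUPS <- c("HOA", "AD", "MCIs", "MCIc", "unknown")

#' EEGRecording: a multichannel EEG epoch
#'
#' Container for one resting-state EEG epoch: a channels-by-samples voltage
#' matrix (microvolts) with its sampling rate, ordered 10-20 channel labels
#' and subject metadata. Constructed by [EEGRecording()], [readEDF()],
#' [readMatrixText()] or the synthetic generator [generateEEG()].
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of channel names, one per matrix row.
#' @slot subjectId subject identifier.
#' @slot group diagnostic group, one of `"HOA"`, `"AD"`, `"MCIs"`, `"MCIc"`,
#'   `"unknown"`.
#'
#' @seealso [preprocessEEG()], [gfpCurve()], [backfit()]
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    labels = "character",
    subjectId = "character",
    group = "character"
  ),
  prototype(
    fs = 250,
    subjectId = "unknown",
    group = "unknown"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "data must be a numeric matrix")
  }
  if (length(object@labels) != nrow(object@data)) {
    msg <- c(msg, sprintf(
      "number of channel labels (%d) must equal number of data rows (%d)",
      length(object@labels), nrow(object@data)
    ))
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (!all(object@group %in% .EEG_GROUPS)) {
    msg <- c(msg, paste0("group must be one of: ", paste(.EEG_GROUPS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate (Hz).
#' @param labels channel names; defaults to `ch1..chN`.
#' @param subjectId subject identifier string.
#' @param group diagnostic group label.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2, 100), fs = 100,
#'                     labels = c("Fp1", "Fp2"))
#' nChannels(rec)
#' @export
EEGRecording <- function(data, fs, labels = NULL, subjectId = "unknown",
                         group = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  new("EEGRecording",
    data = data, fs = as.numeric(fs),
    labels = as.character(labels),
    subjectId = as.character(subjectId), group = as.character(group)
  )
}

#' MicrostateModel: an ordered set of microstate topographies
#'
#' Result of polarity-invariant clustering: `k` unit-norm, zero-mean scalp
#' maps (rows), the global explained variance (GEV) achieved on the data the
#' model was fitted to, and whether the model is subject- or cohort-level.
#'
#' @slot maps numeric matrix, k x channels; each row unit norm, zero mean.
#' @slot gev global explained variance in `[0, 1]`.
#' @slot level `"subject"` or `"cohort"`.
#' @slot channelNames channel names the maps are defined over.
#' @slot classNames optional microstate class names (e.g. `"A".."D"`).
#' @seealso [modifiedKMeans()], [fitCohort()], [alignModels()], [backfit()]
#' @export
setClass("MicrostateModel",
  representation(
    maps = "matrix",
    gev = "numeric",
    level = "character",
    channelNames = "character",
    classNames = "character"
  ),
  prototype(gev = NA_real_, level = "subject")
)

setValidity("MicrostateModel", function(object) {
  msg <- character()
  if (nrow(object@maps) < 2L) {
    msg <- c(msg, "a microstate model needs at least 2 maps")
  }
  if (length(object@channelNames) &&
      length(object@channelNames) != ncol(object@maps)) {
    msg <- c(msg, "channelNames length must match map columns")
  }
  if (!is.na(object@gev) && (object@gev < -1e-9 || object@gev > 1 + 1e-9)) {
    msg <- c(msg, "gev must lie in [0, 1]")
  }
  nrm <- sqrt(rowSums(object@maps^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    msg <- c(msg, "every map must have unit norm")
  }
  if (!object@level %in% c("subject", "cohort")) {
    msg <- c(msg, "level must be 'subject' or 'cohort'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MicrostateModel
#' @param maps k x channels matrix of unit-norm, zero-mean topographies.
#' @param gev global explained variance (may be `NA` for hand-built models).
#' @param level `"subject"` or `"cohort"`.
#' @param channelNames,classNames optional metadata.
#' @return A [MicrostateModel-class].
#' @export
MicrostateModel <- function(maps, gev = NA_real_, level = "subject",
                            channelNames = character(),
                            classNames = character()) {
  new("MicrostateModel",
    maps = maps, gev = as.numeric(gev), level = level,
    channelNames = as.character(channelNames),
    classNames = as.character(classNames)
  )
}

#' LabelSequence: per-sample microstate labels
#'
#' The backfitted microstate class (an integer in `1..k`) for every sample of
#' a recording, together with the sampling rate needed to convert run lengths
#' to durations.
#'
#' @slot labels integer vector of class indices in `1..k`.
#' @slot fs sampling rate (Hz).
#' @slot k number of microstate classes.
#' @seealso [backfit()], [sequenceStats()], [microstateLZC()]
#' @export
setClass("LabelSequence",
  representation(labels = "integer", fs = "numeric", k = "integer")
)

setValidity("LabelSequence", function(object) {
  msg <- character()
  if (length(object@labels) == 0L) msg <- c(msg, "empty label sequence")
  if (any(object@labels < 1L | object@labels > object@k)) {
    msg <- c(msg, "labels must lie in 1..k")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelSequence
#' @param labels integer class indices (1..k).
#' @param fs sampling rate (Hz).
#' @param k number of classes; defaults to `max(labels)`.
#' @return A [LabelSequence-class] object.
#' @export
LabelSequence <- function(labels, fs, k = max(labels)) {
  new("LabelSequence",
    labels = as.integer(labels), fs = as.numeric(fs),
    k = as.integer(k)
  )
}

#' KLCurve: Krzanowski-Lai criterion over a range of k
#'
#' Holds the within-cluster dispersion `W(k)`, the penalized successive
#' differences `DIFF(k)` and the criterion `KL(k) = |DIFF(k)| / |DIFF(k+1)|`
#' for each tested number of clusters, plus the selected optimum.
#'
#' @slot kValues integer vector of tested cluster counts.
#' @slot W within-cluster dispersion per k (1 - r^2 distance).
#' @slot DIFF penalized dispersion increments (NA where undefined).
#' @slot KL criterion values (NA where undefined).
#' @slot kOpt the k maximizing KL over the interior of the range.
#' @seealso [selectKKL()]
#' @export
setClass("KLCurve",
  representation(
    kValues = "integer", W = "numeric", DIFF = "numeric",
    KL = "numeric", kOpt = "integer"
  )
)

setValidity("KLCurve", function(object) {
  n <- length(object@kValues)
  msg <- character()
  if (length(object@W) != n || length(object@DIFF) != n || length(object@KL) != n) {
    msg <- c(msg, "W, DIFF and KL must align with kValues")
  }
  if (!object@kOpt %in% object@kValues) {
    msg <- c(msg, "kOpt must be one of the tested k values")
  }
  if (length(msg)) msg else TRUE
})
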