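#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "LabelSequence", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@labels)

#' @rdname MicrostateModel-class
#' @export
setMethod("channelNames", "MicrostateModel", function(x) x@channelNames)

#' @rdname EEGRecording-class
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)

#' @rdname EEGRecording-class
#' @export
setMethod("groupLabel", "EEGRecording", function(x) x@group)

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs
  ))
  cat(sprintf("  subject: %s  group: %s\n", object@subjectId, object@group))
  lab <- object@labels
  if (length(lab) > 8) lab <- c(lab[1:8], "...")
  cat("  channels:", paste(lab, collapse = " "), "\n")
})

#' @rdname MicrostateModel-class
#' @export
setMethod("microstateMaps", "MicrostateModel", function(x) x@maps)

#' @rdname MicrostateModel-class
#' @export
setMethod("gev", "MicrostateModel", function(x) x@gev)

#' @rdname MicrostateModel-class
#' @export
setMethod("nStates", "MicrostateModel", function(x) nrow(x@maps))

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf(
    "MicrostateModel (%s level): k = %d over %d channels, GEV = %s\n",
    object@level, nrow(object@maps), ncol(object@maps),
    if (is.na(object@gev)) "NA" else sprintf("%.3f", object@gev)
  ))
  if (length(object@classNames)) {
    cat("  classes:", paste(object@classNames, collapse = " "), "\n")
  }
})

#' @rdname LabelSequence-class
#' @export
setMethod("stateLabels", "LabelSequence", function(x) x@labels)

#' @rdname LabelSequence-class
#' @export
setMethod("nStates", "LabelSequence", function(x) x@k)

setMethod("show", "LabelSequence", function(object) {
  n <- length(object@labels)
  ntr <- sum(diff(object@labels) != 0L)
  cat(sprintf(
    "LabelSequence: %d samples @ %g Hz, k = %d, %d transitions\n",
    n, object@fs, object@k, ntr
  ))
})

#' @rdname KLCurve-class
#' @export
setMethod("optimalK", "KLCurve", function(x) x@kOpt)

setMethod("show", "KLCurve", function(object) {
  cat("Krzanowski-Lai curve\n")
  print(data.frame(
    k = object@kValues, W = object@W, DIFF = object@DIFF, KL = object@KL
  ), row.names = FALSE)
  cat("k_opt =", object@kOpt, "\n")
})
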