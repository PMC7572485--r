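#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EEGRecording-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname MicrostateModel-class
#' @export
setGeneric("microstateMaps", function(x) standardGeneric("microstateMaps"))

#' @rdname MicrostateModel-class
#' @export
setGeneric("gev", function(x) standardGeneric("gev"))

#' @rdname MicrostateModel-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname LabelSequence-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname KLCurve-class
#' @export
setGeneric("optimalK", function(x) standardGeneric("optimalK"))
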