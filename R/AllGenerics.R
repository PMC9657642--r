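#' @include AllGenerics.R
NULL

#' @rdname EEGRecording-class
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("recordSource", function(x) standardGeneric("recordSource"))

#' @rdname FeatureSignal-class
#' @export
setGeneric("envelope", function(x) standardGeneric("envelope"))

#' @rdname FeatureSignal-class
#' @export
setGeneric("filteredAverage", function(x) standardGeneric("filteredAverage"))

#' @rdname FeatureSignal-class
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))

#' @rdname SeizureEpochSet-class
#' @export
setGeneric("epochRanges", function(x) standardGeneric("epochRanges"))

#' @rdname SeizureEpochSet-class
#' @export
setGeneric("epochTable", function(x) standardGeneric("epochTable"))

#' @rdname SeizureEpochSet-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("annotationEntries", function(x) standardGeneric("annotationEntries"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("annotationRoster", function(x) standardGeneric("annotationRoster"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("totalHours", function(x) standardGeneric("totalHours"))
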