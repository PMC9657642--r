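#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- EEGRecording

#' EEGRecording: a multichannel scalp EEG record
#'
#' Container for a channels x samples signal matrix in microvolts, with the
#' sampling rate and the channel labels in header order. Channel order is
#' preserved from the source file because localization reports channel
#' indices relative to it.
#'
#' @slot data numeric matrix, channels in rows, samples in columns, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of 10-20 (bipolar) channel names.
#' @slot startTime wall-clock start time string ("hh.mm.ss") or NA.
#' @slot source source file name or "".
#'
#' @param data,fs,channelLabels,startTime,source see slots.
#' @param x an EEGRecording.
#' @return `EEGRecording()` returns a validated EEGRecording object.
#'
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), nrow = 2), fs = 256,
#'                     channelLabels = c("FP1-F7", "T7-P7"))
#' nChannels(rec)
#' nSamples(rec)
#' @aliases channelData samplingRate channelLabels nChannels nSamples
#'   recordSource
#' @export EEGRecording
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", channelLabels = "character",
                 startTime = "character", source = "character"),
  prototype(startTime = NA_character_, source = ""))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite samples (NaN/Inf rejected)")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "one label per channel (row) is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique (deduplicate on load)")
  if (length(msg)) msg else TRUE
})

EEGRecording <- function(data, fs, channelLabels = NULL,
                         startTime = NA_character_, source = "") {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  if (is.null(channelLabels))
    channelLabels <- sprintf("CH%02d", seq_len(nrow(data)))
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels),
      startTime = startTime, source = source)
}

#' @rdname EEGRecording-class
#' @export
setMethod("channelData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("recordSource", "EEGRecording", function(x) x@source)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@data), "channels x",
      ncol(object@data), "samples @", object@fs, "Hz (",
      sprintf("%.1f", ncol(object@data) / object@fs), "s )\n")
  lab <- object@channelLabels
  if (length(lab) > 6) lab <- c(lab[1:6], "...")
  cat("  channels:", paste(lab, collapse = ", "), "\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

# ---------------------------------------------------------------- FeatureSignal

#' FeatureSignal: the normalized moving-RMS envelope of the channel average
#'
#' The single 1-D trace the detector operates on. `envelope` is the
#' normalized ([0,1]) moving-RMS envelope of the rectified, feature-filtered
#' channel average; `filteredAverage` is that average before the RMS stage,
#' in unnormalized microvolt units (used for the in-band power criterion);
#' `normFactor` is the maximum the envelope was divided by.
#'
#' @slot envelope numeric in [0,1], one value per sample.
#' @slot filteredAverage numeric, same length, microvolts.
#' @slot normFactor the pre-normalization envelope maximum (0 for an all-zero
#'   envelope).
#' @slot fs sampling rate in Hz.
#' @param x a FeatureSignal.
#' @aliases envelope filteredAverage normFactor
#' @seealso [buildFeatureSignal()]
#' @export FeatureSignal
#' @exportClass FeatureSignal
setClass("FeatureSignal",
  representation(envelope = "numeric", filteredAverage = "numeric",
                 normFactor = "numeric", fs = "numeric"))

setValidity("FeatureSignal", function(object) {
  msg <- character(0)
  if (length(object@envelope) != length(object@filteredAverage))
    msg <- c(msg, "envelope and filteredAverage must have equal length")
  if (length(object@normFactor) != 1L || object@normFactor < 0)
    msg <- c(msg, "normFactor must be a single non-negative number")
  if (length(object@envelope) &&
      (min(object@envelope) < -1e-12 || max(object@envelope) > 1 + 1e-9))
    msg <- c(msg, "envelope must lie in [0, 1]")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

FeatureSignal <- function(envelope, filteredAverage, normFactor, fs) {
  new("FeatureSignal", envelope = as.numeric(envelope),
      filteredAverage = as.numeric(filteredAverage),
      normFactor = as.numeric(normFactor), fs = as.numeric(fs))
}

#' @rdname FeatureSignal-class
#' @export
setMethod("envelope", "FeatureSignal", function(x) x@envelope)

#' @rdname FeatureSignal-class
#' @export
setMethod("filteredAverage", "FeatureSignal", function(x) x@filteredAverage)

#' @rdname FeatureSignal-class
#' @export
setMethod("normFactor", "FeatureSignal", function(x) x@normFactor)

#' @rdname FeatureSignal-class
#' @export
setMethod("samplingRate", "FeatureSignal", function(x) x@fs)

#' @rdname FeatureSignal-class
#' @export
setMethod("nSamples", "FeatureSignal", function(x) length(x@envelope))

setMethod("show", "FeatureSignal", function(object) {
  cat("FeatureSignal:", length(object@envelope), "samples @", object@fs,
      "Hz; normFactor =", format(object@normFactor, digits = 4), "\n")
})

# -------------------------------------------------------------- SeizureEpochSet

#' SeizureEpochSet: detected seizure intervals for one record
#'
#' An IRanges-backed set of disjoint, sorted sample intervals (1-based,
#' closed, as is usual for IRanges) with per-epoch scores in the metadata
#' columns: `peakValue` (normalized envelope at the onset peak),
#' `peakWidthS` (half-prominence width of the onset peak, seconds) and
#' `power` (time-integrated squared in-band average, microvolt^2 * s).
#'
#' @slot epochs an [IRanges::IRanges] with mcols peakValue, peakWidthS, power.
#' @slot nSamples record length in samples.
#' @slot fs sampling rate in Hz.
#' @param x a SeizureEpochSet.
#' @aliases epochRanges epochTable nEpochs
#' @seealso [detectSeizures()], [epochsToMask()]
#' @export SeizureEpochSet
#' @exportClass SeizureEpochSet
setClass("SeizureEpochSet",
  representation(epochs = "IRanges", nSamples = "integer", fs = "numeric"))

setValidity("SeizureEpochSet", function(object) {
  msg <- character(0)
  ir <- object@epochs
  if (length(ir)) {
    if (is.unsorted(IRanges::start(ir)))
      msg <- c(msg, "epochs must be sorted by start")
    if (length(ir) > 1 &&
        any(IRanges::start(ir)[-1] <= IRanges::end(ir)[-length(ir)]))
      msg <- c(msg, "epochs must be pairwise disjoint")
    if (min(IRanges::start(ir)) < 1L ||
        max(IRanges::end(ir)) > object@nSamples)
      msg <- c(msg, "epochs must lie within [1, nSamples]")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

SeizureEpochSet <- function(epochs = IRanges::IRanges(), nSamples, fs) {
  mc <- S4Vectors::mcols(epochs)
  for (col in c("peakValue", "peakWidthS", "power"))
    if (is.null(mc[[col]])) mc[[col]] <- rep(NA_real_, length(epochs))
  S4Vectors::mcols(epochs) <- mc
  new("SeizureEpochSet", epochs = epochs, nSamples = as.integer(nSamples),
      fs = as.numeric(fs))
}

#' @rdname SeizureEpochSet-class
#' @export
setMethod("epochRanges", "SeizureEpochSet", function(x) x@epochs)

#' @rdname SeizureEpochSet-class
#' @export
setMethod("nEpochs", "SeizureEpochSet", function(x) length(x@epochs))

#' @rdname SeizureEpochSet-class
#' @export
setMethod("samplingRate", "SeizureEpochSet", function(x) x@fs)

#' @rdname SeizureEpochSet-class
#' @export
setMethod("nSamples", "SeizureEpochSet", function(x) x@nSamples)

#' @describeIn SeizureEpochSet-class data.frame view with onset/end in
#'   seconds (half-open in seconds: onsetS = (start-1)/fs, endS = end/fs).
#' @export
setMethod("epochTable", "SeizureEpochSet", function(x) {
  ir <- x@epochs
  mc <- S4Vectors::mcols(ir)
  data.frame(
    startSample = IRanges::start(ir), endSample = IRanges::end(ir),
    onsetS = (IRanges::start(ir) - 1) / x@fs, endS = IRanges::end(ir) / x@fs,
    peakValue = mc$peakValue, peakWidthS = mc$peakWidthS, power = mc$power)
})

setMethod("show", "SeizureEpochSet", function(object) {
  cat("SeizureEpochSet:", length(object@epochs), "epoch(s) in",
      object@nSamples, "samples @", object@fs, "Hz\n")
  if (length(object@epochs)) print(epochTable(object))
})

# ---------------------------------------------------------------- AnnotationSet

#' AnnotationSet: ground-truth seizure intervals per file
#'
#' Expert seizure annotations as (fileId, onsetS, endS) triples in seconds
#' from record start, plus the roster of all files (including files with no
#' seizures, which are needed for true-negative accounting). Entries are
#' normalized on construction: sorted by (fileId, onsetS) and overlapping
#' intervals within a file merged.
#'
#' @slot entries data.frame with columns fileId, onsetS, endS.
#' @slot roster character vector of all file ids under evaluation.
#' @slot totalHours total recording time in hours (NA if unknown).
#' @param x an AnnotationSet.
#' @aliases annotationEntries annotationRoster totalHours
#' @seealso [readAnnotations()]
#' @export AnnotationSet
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(entries = "data.frame", roster = "character",
                 totalHours = "numeric"),
  prototype(totalHours = NA_real_))

setValidity("AnnotationSet", function(object) {
  e <- object@entries
  msg <- character(0)
  if (!all(c("fileId", "onsetS", "endS") %in% names(e)))
    return("entries needs columns fileId, onsetS, endS")
  if (nrow(e)) {
    if (any(e$onsetS < 0)) msg <- c(msg, "onsetS must be >= 0")
    if (any(e$endS <= e$onsetS)) msg <- c(msg, "endS must exceed onsetS")
    if (!all(e$fileId %in% object@roster))
      msg <- c(msg, "every annotated file must be in the roster")
    o <- order(e$fileId, e$onsetS)
    if (any(o != seq_len(nrow(e))))
      msg <- c(msg, "entries must be sorted by (fileId, onsetS)")
    same <- e$fileId[-1] == e$fileId[-nrow(e)]
    if (nrow(e) > 1 && any(same & e$onsetS[-1] < e$endS[-nrow(e)]))
      msg <- c(msg, "entries within a file must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotationSet-class
#' @param entries,roster,totalHours see slots.
#' @export
AnnotationSet <- function(entries = data.frame(fileId = character(0),
                                               onsetS = numeric(0),
                                               endS = numeric(0)),
                          roster = character(0), totalHours = NA_real_) {
  entries <- as.data.frame(entries)[, c("fileId", "onsetS", "endS")]
  entries$fileId <- as.character(entries$fileId)
  roster <- unique(c(as.character(roster), entries$fileId))
  entries <- normalizeEntries(entries)
  new("AnnotationSet", entries = entries, roster = roster,
      totalHours = as.numeric(totalHours))
}

# sort by (fileId, onset) and merge overlapping/touching intervals per file;
# merging never reduces total covered seconds
normalizeEntries <- function(entries) {
  if (!nrow(entries)) return(entries)
  entries <- entries[order(entries$fileId, entries$onsetS), , drop = FALSE]
  out <- do.call(rbind, lapply(split(entries, entries$fileId), function(e) {
    keep <- e[1, , drop = FALSE]
    if (nrow(e) > 1) for (i in 2:nrow(e)) {
      j <- nrow(keep)
      if (e$onsetS[i] <= keep$endS[j]) {
        keep$endS[j] <- max(keep$endS[j], e$endS[i])
      } else keep <- rbind(keep, e[i, , drop = FALSE])
    }
    keep
  }))
  rownames(out) <- NULL
  out[order(out$fileId, out$onsetS), , drop = FALSE]
}

#' @rdname AnnotationSet-class
#' @export
setMethod("annotationEntries", "AnnotationSet", function(x) x@entries)

#' @rdname AnnotationSet-class
#' @export
setMethod("annotationRoster", "AnnotationSet", function(x) x@roster)

#' @rdname AnnotationSet-class
#' @export
setMethod("totalHours", "AnnotationSet", function(x) x@totalHours)

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", nrow(object@entries), "seizure(s) across",
      length(object@roster), "file(s)")
  if (!is.na(object@totalHours)) cat(";", object@totalHours, "h total")
  cat("\n")
})

# ----------------------------------------------------------------- Param types

#' Parameters of the per-channel denoising cascade
#'
#' @param lpCutoff low-pass cutoff, Hz (default 35).
#' @param lpOrder FIR low-pass order, even (default 50).
#' @param powerlineFreq power-line fundamental, Hz (default 60; use 50 for
#'   European recordings).
#' @param powerlineEnabled apply the power-line notch (default TRUE).
#' @param powerlineHarmonics number of harmonics to notch, NA = all below
#'   Nyquist (default NA).
#' @param notchQ quality factor of each notch section (default 60; keeps the
#'   passband within 1 percent at +/- 5 Hz under zero-phase application).
#' @param dcLambda pole radius of the recursive DC-removal notch
#'   H(z) = (1 - z^-1)/(1 - lambda z^-1), in (0,1) (default 0.9991).
#' @param zeroPhase apply all stages forward-backward (default TRUE); FALSE
#'   gives the causal single-pass variant.
#' @return a validated `PreprocessParams` object.
#' @seealso [preprocessRecording()]
#' @export PreprocessParams
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(lpCutoff = "numeric", lpOrder = "integer",
                 powerlineFreq = "numeric", powerlineEnabled = "logical",
                 powerlineHarmonics = "numeric", notchQ = "numeric",
                 dcLambda = "numeric", zeroPhase = "logical"))

setValidity("PreprocessParams", function(object) {
  msg <- character(0)
  if (object@lpCutoff <= 0) msg <- c(msg, "lpCutoff must be positive")
  if (object@lpOrder < 2L || object@lpOrder %% 2L != 0L)
    msg <- c(msg, "lpOrder must be even and >= 2")
  if (object@dcLambda <= 0 || object@dcLambda >= 1)
    msg <- c(msg, "dcLambda must lie strictly in (0, 1)")
  if (object@powerlineFreq <= 0) msg <- c(msg, "powerlineFreq must be positive")
  if (object@notchQ <= 0) msg <- c(msg, "notchQ must be positive")
  if (length(msg)) msg else TRUE
})

PreprocessParams <- function(lpCutoff = 35, lpOrder = 50, powerlineFreq = 60,
                             powerlineEnabled = TRUE, powerlineHarmonics = NA,
                             notchQ = 60, dcLambda = 0.9991, zeroPhase = TRUE) {
  new("PreprocessParams", lpCutoff = as.numeric(lpCutoff),
      lpOrder = as.integer(lpOrder), powerlineFreq = as.numeric(powerlineFreq),
      powerlineEnabled = isTRUE(powerlineEnabled),
      powerlineHarmonics = as.numeric(powerlineHarmonics),
      notchQ = as.numeric(notchQ), dcLambda = as.numeric(dcLambda),
      zeroPhase = isTRUE(zeroPhase))
}

#' Parameters of the feature-signal stage
#'
#' The feature filter "tunes the receiver" to the seizure band: a 30th-order
#' FIR selection of 0.1-4.1 Hz applied to the rectified channel average,
#' followed by a 150-sample centered moving RMS and per-record
#' normalization. By default only the low-pass component is applied and the
#' low band edge is left to the DC-removal notch of the preprocessing stage;
#' set `applyHighpass = TRUE` for the literal split band-pass.
#'
#' @param bandLo lower band edge, Hz (default 0.1).
#' @param bandHi upper band edge, Hz (default 4.1).
#' @param ffOrder FIR order of each component (default 30).
#' @param rmsWindow moving-RMS window length, samples (default 150).
#' @param applyHighpass apply the band-low high-pass stage (default FALSE).
#' @param rectifyFirst rectify before the feature filter (default TRUE).
#' @return a validated `FeatureParams` object.
#' @seealso [buildFeatureSignal()]
#' @export FeatureParams
#' @exportClass FeatureParams
setClass("FeatureParams",
  representation(bandLo = "numeric", bandHi = "numeric", ffOrder = "integer",
                 rmsWindow = "integer", applyHighpass = "logical",
                 rectifyFirst = "logical"))

setValidity("FeatureParams", function(object) {
  msg <- character(0)
  if (object@bandLo < 0 || object@bandHi <= object@bandLo)
    msg <- c(msg, "need 0 <= bandLo < bandHi")
  if (object@ffOrder < 2L) msg <- c(msg, "ffOrder must be >= 2")
  if (object@rmsWindow < 1L) msg <- c(msg, "rmsWindow must be >= 1")
  if (length(msg)) msg else TRUE
})

FeatureParams <- function(bandLo = 0.1, bandHi = 4.1, ffOrder = 30,
                          rmsWindow = 150, applyHighpass = FALSE,
                          rectifyFirst = TRUE) {
  new("FeatureParams", bandLo = as.numeric(bandLo), bandHi = as.numeric(bandHi),
      ffOrder = as.integer(ffOrder), rmsWindow = as.integer(rmsWindow),
      applyHighpass = isTRUE(applyHighpass), rectifyFirst = isTRUE(rectifyFirst))
}

#' Parameters of the epoch detector
#'
#' @param minEpochSamples minimum epoch length and merge gap, samples
#'   (default 256 = 1 s at 256 Hz; the "seizLinterval" of the method).
#' @param powerThreshold in-band power threshold in unnormalized
#'   microvolt^2 * s units separating seizures from large physiological
#'   artefacts such as jaw clenches (default 200; sensible range 180-220;
#'   the "seizAggressiveness" of the method). Set to 0 to disable the power
#'   test.
#' @param ampLower lower envelope limit as a fraction of 1 (default 0.075,
#'   sensible range 0.05-0.1); epoch extent threshold and minimum peak
#'   prominence.
#' @param ampUpper upper envelope limit as a fraction of 1 (default 0.9,
#'   sensible range 0.8-1); onset peaks must reach it.
#' @param widthMinS,widthMaxS admissible half-prominence width of the onset
#'   peak, seconds (defaults 0.4 and 1.8).
#' @return a validated `DetectionParams` object.
#' @seealso [detectSeizures()]
#' @export DetectionParams
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(minEpochSamples = "integer", powerThreshold = "numeric",
                 ampLower = "numeric", ampUpper = "numeric",
                 widthMinS = "numeric", widthMaxS = "numeric"))

setValidity("DetectionParams", function(object) {
  msg <- character(0)
  if (object@minEpochSamples < 1L)
    msg <- c(msg, "minEpochSamples must be >= 1")
  if (!(object@ampLower > 0 && object@ampLower < object@ampUpper &&
        object@ampUpper <= 1))
    msg <- c(msg, "need 0 < ampLower < ampUpper <= 1")
  if (!(object@widthMinS > 0 && object@widthMinS < object@widthMaxS))
    msg <- c(msg, "need 0 < widthMinS < widthMaxS")
  if (object@powerThreshold < 0)
    msg <- c(msg, "powerThreshold must be >= 0")
  if (length(msg)) msg else TRUE
})

DetectionParams <- function(minEpochSamples = 256, powerThreshold = 200,
                            ampLower = 0.075, ampUpper = 0.9,
                            widthMinS = 0.4, widthMaxS = 1.8) {
  new("DetectionParams", minEpochSamples = as.integer(minEpochSamples),
      powerThreshold = as.numeric(powerThreshold),
      ampLower = as.numeric(ampLower), ampUpper = as.numeric(ampUpper),
      widthMinS = as.numeric(widthMinS), widthMaxS = as.numeric(widthMaxS))
}
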