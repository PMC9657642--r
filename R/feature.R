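#' @include preprocess.R
NULL

#' Arithmetic average across EEG channels
#'
#' @param recording an [EEGRecording-class] with at least one channel.
#' @return numeric vector, the sample-wise mean of all channels.
#' @export
averageChannels <- function(recording) {
  dat <- channelData(recording)
  if (nrow(dat) < 1L || ncol(dat) < 1L)
    stop("cannot average an empty recording")
  colMeans(dat)
}

#' Full-wave rectification
#'
#' Element-wise absolute value. Rectifying before the feature filter folds
#' the fast oscillations of the seizure dipoles into a low-frequency
#' amplitude trace the short RMS window can follow.
#'
#' @param signal numeric vector.
#' @return `abs(signal)`.
#' @export
rectify <- function(signal) abs(signal)

#' Seizure-band feature filter
#'
#' Zero-phase FIR selection of the seizure band (default 0.1-4.1 Hz),
#' raising the in-band signal-to-noise ratio the way a receiver is tuned to
#' a carrier. Implemented as a low-pass at `bandHi` optionally composed
#' with a high-pass at `bandLo` (off by default; the recursive DC notch of
#' the preprocessing stage already covers the low edge, and a 30th-order
#' FIR cannot realize a 0.1 Hz edge at EEG sampling rates).
#'
#' @param signal numeric vector.
#' @param params a [FeatureParams()] object.
#' @param fs sampling rate, Hz.
#' @return filtered signal, same length.
#' @export
featureFilter <- function(signal, params = FeatureParams(), fs) {
  if (params@bandHi >= fs / 2)
    stop("feature band must lie inside (0, fs/2)")
  if (length(signal) <= 3L * (params@ffOrder + 1L))
    stop("signal too short for the requested filter order")
  b <- designLowpass(params@ffOrder, params@bandHi, fs)
  out <- zeroPhaseFilter(signal, b)
  if (params@applyHighpass && params@bandLo > 0) {
    bh <- designHighpass(params@ffOrder, params@bandLo, fs)
    out <- zeroPhaseFilter(out, bh)
  }
  out
}

#' Centered moving RMS envelope
#'
#' Sliding root-mean-square with a centered window (default 150 samples).
#' At the record edges the window shrinks to the available samples, so the
#' output has the same length as the input.
#'
#' @param signal numeric vector.
#' @param window window length in samples.
#' @return numeric vector of local RMS values.
#' @export
movingRMS <- function(signal, window = 150) {
  window <- as.integer(window)
  n <- length(signal)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window exceeds signal length")
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, signal^2))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Normalize an envelope to [0, 1]
#'
#' Divides by the envelope maximum so detection thresholds can be stated as
#' fractions of one. The maximum is returned as the normalization factor;
#' an all-zero envelope maps to itself with factor 0.
#'
#' @param envelope non-negative numeric vector.
#' @return list with elements `envelope` (in [0,1]) and `normFactor`.
#' @export
normalizeEnvelope <- function(envelope) {
  if (length(envelope) && min(envelope) < 0)
    stop("envelope must be non-negative")
  m <- if (length(envelope)) max(envelope) else 0
  if (m == 0) return(list(envelope = envelope, normFactor = 0))
  list(envelope = envelope / m, normFactor = m)
}

#' Build the feature signal from a multichannel recording
#'
#' The full collapse of the multichannel EEG into the single trace the
#' detector reads: preprocess each channel, average, rectify, apply the
#' seizure-band feature filter, take the 150-sample moving RMS and
#' normalize per record. The filtered average before the RMS stage is
#' retained in unnormalized units for the in-band power criterion.
#'
#' @param recording an [EEGRecording-class].
#' @param preParams a [PreprocessParams()] object.
#' @param featParams a [FeatureParams()] object.
#' @return a [FeatureSignal-class].
#' @examples
#' sim <- simulateRecording(seed = 1, durationS = 60, nChannels = 8,
#'                          seizures = data.frame(onsetS = 20, durationS = 25))
#' fsig <- buildFeatureSignal(sim$recording)
#' which.max(envelope(fsig)) / samplingRate(fsig)  # inside the seizure
#' @export
buildFeatureSignal <- function(recording, preParams = PreprocessParams(),
                               featParams = FeatureParams()) {
  methods::validObject(featParams)
  fs <- samplingRate(recording)
  # every preprocessing stage is linear and time-invariant with identical
  # coefficients on every channel, so the average of the preprocessed
  # channels equals the preprocessed average; computing it that way costs
  # one channel's filtering instead of all of them
  avgRec <- EEGRecording(matrix(averageChannels(recording), nrow = 1L),
                         fs = fs, channelLabels = "AVG")
  avg <- channelData(preprocessRecording(avgRec, preParams))[1L, ]
  if (featParams@rectifyFirst) {
    filt <- featureFilter(rectify(avg), featParams, fs)
  } else {
    filt <- rectify(featureFilter(avg, featParams, fs))
  }
  env <- movingRMS(filt, featParams@rmsWindow)
  nrm <- normalizeEnvelope(env)
  FeatureSignal(envelope = pmin(pmax(nrm$envelope, 0), 1),
                filteredAverage = filt, normFactor = nrm$normFactor, fs = fs)
}
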