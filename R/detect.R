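#' @include feature.R
NULL

# Local maxima of a numeric vector. Plateaus count once, with the leftmost
# plateau sample as the peak index. Returns integer indices.
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  isMax <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                    r$values[2:(k - 1)] > r$values[3:k], FALSE)
  starts[isMax]
}

# Topographic prominence of the peak at index i: walk out to the nearest
# higher sample on each side (or the record edge) and take the minimum in
# between; prominence = height - the higher of the two side minima.
peakProminence <- function(x, i) {
  h <- x[i]
  leftHigher <- which(x[seq_len(i - 1L)] > h)
  lo <- if (length(leftHigher)) max(leftHigher) + 1L else 1L
  leftBase <- min(x[lo:i])
  rightHigher <- which(x[(i + 1L):length(x)] > h)
  hi <- if (length(rightHigher)) i + min(rightHigher) - 1L else length(x)
  rightBase <- min(x[i:hi])
  h - max(leftBase, rightBase)
}

# Half-prominence width: the contiguous run of samples around the peak at
# or above height - prominence/2, in samples. Peaks clipped by the record
# boundary are measured on the available support.
halfPromWidth <- function(x, i, prominence) {
  thr <- x[i] - prominence / 2
  lo <- i
  while (lo > 1L && x[lo - 1L] >= thr) lo <- lo - 1L
  hi <- i
  n <- length(x)
  while (hi < n && x[hi + 1L] >= thr) hi <- hi + 1L
  c(lo = lo, hi = hi, width = hi - lo + 1L)
}

#' Find candidate onset peaks in the feature signal
#'
#' Seizure onsets appear in the feature signal as sharp discontinuity
#' peaks. This returns every local maximum with height and prominence at
#' least `ampLower`, with its half-prominence width; peaks whose height
#' also reaches `ampUpper` are onset candidates (`onset = TRUE`), the rest
#' are retained as epoch-extent evidence only.
#'
#' @param feature a [FeatureSignal-class].
#' @param params a [DetectionParams()] object.
#' @return data.frame with columns index, height, widthS, prominence,
#'   supportLo, supportHi, onset. Zero rows when nothing qualifies.
#' @export
findOnsetPeaks <- function(feature, params = DetectionParams()) {
  env <- envelope(feature)
  fs <- samplingRate(feature)
  idx <- localMaxima(env)
  idx <- idx[env[idx] >= params@ampLower]
  rows <- lapply(idx, function(i) {
    p <- peakProminence(env, i)
    if (p < params@ampLower) return(NULL)
    w <- halfPromWidth(env, i, p)
    data.frame(index = i, height = env[i], widthS = unname(w["width"]) / fs,
               prominence = p, supportLo = unname(w["lo"]),
               supportHi = unname(w["hi"]),
               onset = env[i] >= params@ampUpper)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(index = integer(0), height = numeric(0),
                      widthS = numeric(0), prominence = numeric(0),
                      supportLo = integer(0), supportHi = integer(0),
                      onset = logical(0)))
  do.call(rbind, rows)
}

#' Keep candidates whose onset-peak width is seizure-like
#'
#' Discontinuities narrower than `widthMinS` (amplitude spikes) or wider
#' than `widthMaxS` (slow swings, sustained artefacts) are not seizure
#' onsets.
#'
#' @param candidates data.frame as from [findOnsetPeaks()].
#' @param params a [DetectionParams()] object.
#' @return the filtered data.frame.
#' @export
widthFilter <- function(candidates, params = DetectionParams()) {
  keep <- candidates$widthS >= params@widthMinS &
          candidates$widthS <= params@widthMaxS
  candidates[keep, , drop = FALSE]
}

#' In-band power of an epoch
#'
#' Time-integrated squared unnormalized filtered average over
#' `[startSample, endSample]`: `sum(x^2) / fs`, units microvolt^2 * s.
#' Compared against the power threshold ("seizAggressiveness") to exclude
#' broadband artefacts (e.g. jaw clenches) whose energy lies outside the
#' seizure band and therefore barely reaches the filtered average.
#'
#' @param filteredAvg unnormalized feature-filtered channel average.
#' @param startSample,endSample 1-based inclusive sample bounds.
#' @param fs sampling rate, Hz.
#' @return the power score (scalar).
#' @export
epochPower <- function(filteredAvg, startSample, endSample, fs) {
  if (endSample < startSample || startSample < 1L ||
      endSample > length(filteredAvg))
    stop("empty or out-of-range epoch interval")
  sum(filteredAvg[startSample:endSample]^2) / fs
}

#' Grow candidates to epoch extent and merge near-contiguous epochs
#'
#' Each surviving onset candidate grows to the surrounding contiguous
#' region where the envelope stays at or above `ampLower`; regions closer
#' than `minEpochSamples` are merged; merged epochs shorter than
#' `minEpochSamples` are discarded. Per-epoch power is computed over the
#' final extent.
#'
#' @param candidates data.frame of onset candidates (rows of
#'   [findOnsetPeaks()] output after filtering).
#' @param feature the [FeatureSignal-class] the candidates came from.
#' @param params a [DetectionParams()] object.
#' @return a [SeizureEpochSet-class].
#' @export
growAndMerge <- function(candidates, feature, params = DetectionParams()) {
  env <- envelope(feature)
  fs <- samplingRate(feature)
  n <- length(env)
  empty <- SeizureEpochSet(IRanges::IRanges(), nSamples = n, fs = fs)
  if (!nrow(candidates)) return(empty)
  above <- env >= params@ampLower
  reg <- t(vapply(as.integer(candidates$index), function(i) {
    lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < n && above[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
  }, integer(2)))
  ir <- IRanges::reduce(IRanges::IRanges(start = reg[, 1], end = reg[, 2]),
                        min.gapwidth = params@minEpochSamples)
  ir <- ir[IRanges::width(ir) >= params@minEpochSamples]
  if (!length(ir)) return(empty)
  mc <- S4Vectors::DataFrame(
    peakValue = vapply(seq_along(ir), function(k) {
      inside <- candidates$index >= IRanges::start(ir)[k] &
                candidates$index <= IRanges::end(ir)[k]
      if (any(inside)) max(candidates$height[inside]) else NA_real_
    }, numeric(1)),
    peakWidthS = vapply(seq_along(ir), function(k) {
      inside <- candidates$index >= IRanges::start(ir)[k] &
                candidates$index <= IRanges::end(ir)[k]
      if (any(inside))
        candidates$widthS[inside][which.max(candidates$height[inside])]
      else NA_real_
    }, numeric(1)),
    power = vapply(seq_along(ir), function(k) {
      epochPower(filteredAverage(feature), IRanges::start(ir)[k],
                 IRanges::end(ir)[k], fs)
    }, numeric(1)))
  S4Vectors::mcols(ir) <- mc
  SeizureEpochSet(ir, nSamples = n, fs = fs)
}

#' Detect seizure epochs in a feature signal
#'
#' The automated detection rule: find onset peaks (height >= `ampUpper`,
#' prominence >= `ampLower`), keep those with half-prominence width in
#' `[widthMinS, widthMaxS]` and in-band power over the peak support of at
#' least `powerThreshold`, then grow each survivor to the surrounding
#' region above `ampLower` and merge near-contiguous regions. Fully
#' deterministic.
#'
#' @param feature a [FeatureSignal-class].
#' @param params a [DetectionParams()] object.
#' @return a [SeizureEpochSet-class].
#' @examples
#' sim <- simulateRecording(seed = 2, durationS = 120, nChannels = 8,
#'                          seizures = data.frame(onsetS = 40, durationS = 30))
#' det <- detectSeizures(buildFeatureSignal(sim$recording))
#' epochTable(det)
#' @export
detectSeizures <- function(feature, params = DetectionParams()) {
  methods::validObject(params)
  cand <- findOnsetPeaks(feature, params)
  cand <- cand[cand$onset, , drop = FALSE]
  cand <- widthFilter(cand, params)
  if (nrow(cand) && params@powerThreshold > 0) {
    pw <- vapply(seq_len(nrow(cand)), function(r) {
      epochPower(filteredAverage(feature), cand$supportLo[r],
                 cand$supportHi[r], samplingRate(feature))
    }, numeric(1))
    cand <- cand[pw >= params@powerThreshold, , drop = FALSE]
  }
  growAndMerge(cand, feature, params)
}

#' Binary seizure mask of a record
#'
#' @param epochs a [SeizureEpochSet-class].
#' @return integer vector of length `nSamples(epochs)` with 1 inside
#'   epochs and 0 elsewhere.
#' @seealso [maskToEpochs()] for the inverse.
#' @export
epochsToMask <- function(epochs) {
  mask <- integer(nSamples(epochs))
  ir <- epochRanges(epochs)
  for (k in seq_along(ir))
    mask[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- 1L
  mask
}

#' Recover an epoch set from a binary mask
#'
#' @param mask 0/1 integer vector.
#' @param fs sampling rate, Hz.
#' @return a [SeizureEpochSet-class]; `epochsToMask(maskToEpochs(m, fs))`
#'   is identical to `m`.
#' @export
maskToEpochs <- function(mask, fs) {
  ir <- IRanges::reduce(IRanges::IRanges(which(mask != 0), width = 1L))
  SeizureEpochSet(ir, nSamples = length(mask), fs = fs)
}

#' Convert manually picked time points into epochs
#'
#' Assisted-manual mode: the analyst marks onset/offset pairs on the
#' feature-signal display (or supplies them as a two-column file). Pairs
#' become epochs, the 0.4-1.8 s duration rule is NOT applied to the epoch
#' itself (manual epochs are tens of seconds); instead picks closer
#' together than `widthMinS` seconds are flagged as not-a-seizure and
#' dropped, and the usual merge and minimum-length rules apply.
#'
#' @param pickedTimesS even-length ascending numeric vector of seconds
#'   (onset1, offset1, onset2, offset2, ...).
#' @param feature the [FeatureSignal-class] of the record (for length, fs
#'   and power scoring).
#' @param params a [DetectionParams()] object.
#' @return a [SeizureEpochSet-class].
#' @export
picksToEpochs <- function(pickedTimesS, feature, params = DetectionParams()) {
  fs <- samplingRate(feature)
  n <- nSamples(feature)
  if (length(pickedTimesS) %% 2L != 0L)
    stop("picked times must come in onset/offset pairs (even count)")
  if (is.unsorted(pickedTimesS, strictly = FALSE))
    stop("picked times must be ascending")
  if (!length(pickedTimesS))
    return(SeizureEpochSet(IRanges::IRanges(), nSamples = n, fs = fs))
  onsets <- pickedTimesS[seq(1, length(pickedTimesS), by = 2)]
  offsets <- pickedTimesS[seq(2, length(pickedTimesS), by = 2)]
  keep <- (offsets - onsets) >= params@widthMinS  # duration rule on picks
  onsets <- onsets[keep]; offsets <- offsets[keep]
  if (!length(onsets))
    return(SeizureEpochSet(IRanges::IRanges(), nSamples = n, fs = fs))
  start <- pmax(1L, floor(onsets * fs) + 1L)
  end <- pmin(n, ceiling(offsets * fs))
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end),
                        min.gapwidth = params@minEpochSamples)
  ir <- ir[IRanges::width(ir) >= params@minEpochSamples]
  env <- envelope(feature)
  if (length(ir)) {
    S4Vectors::mcols(ir) <- S4Vectors::DataFrame(
      peakValue = vapply(seq_along(ir), function(k)
        max(env[IRanges::start(ir)[k]:IRanges::end(ir)[k]]), numeric(1)),
      peakWidthS = rep(NA_real_, length(ir)),
      power = vapply(seq_along(ir), function(k)
        epochPower(filteredAverage(feature), IRanges::start(ir)[k],
                   IRanges::end(ir)[k], fs), numeric(1)))
  }
  SeizureEpochSet(ir, nSamples = n, fs = fs)
}
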