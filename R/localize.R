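#' @include detect.R
NULL

#' Per-channel contribution scores within masked seizure samples
#'
#' Applies the same per-channel processing the feature signal uses
#' (preprocess, rectify, feature filter), restricts each processed channel
#' to the masked samples, and scores it by its amplitude excursion
#' (max - min) there. The median of these excursions is the localization
#' threshold; channels strictly above `threshold * margin` are flagged as
#' originating the seizure.
#'
#' @param recording the source [EEGRecording-class].
#' @param mask 0/1 vector marking seizure samples (see [epochsToMask()]).
#' @param preParams a [PreprocessParams()] object.
#' @param featParams a [FeatureParams()] object.
#' @param margin multiplier on the median threshold (default 1.0, the
#'   literal median rule; larger values select fewer channels -- around 1.5
#'   reproduces sparse channel pictures on real records).
#' @return data.frame with columns channelIndex, channelLabel, ampDiff
#'   (microvolts), aboveThreshold, plus the threshold as attribute
#'   "threshold".
#' @export
channelScores <- function(recording, mask, preParams = PreprocessParams(),
                          featParams = FeatureParams(), margin = 1.0) {
  if (sum(mask != 0) < 1L)
    stop("mask selects no seizure samples")
  fs <- samplingRate(recording)
  idx <- which(mask != 0)
  # filter only the segment spanning the mask (plus context); the filters'
  # own reflection padding handles the segment edges
  ctx <- round(5 * fs)
  lo <- max(1L, min(idx) - ctx)
  hi <- min(nSamples(recording), max(idx) + ctx)
  segDat <- channelData(recording)[, lo:hi, drop = FALSE]
  segDat <- segDat - rowMeans(segDat)  # per-channel offsets carry no signal
  seg <- EEGRecording(segDat, fs = fs,
                      channelLabels = channelLabels(recording))
  dat <- channelData(preprocessRecording(seg, preParams))
  segIdx <- idx - lo + 1L
  amp <- vapply(seq_len(nrow(dat)), function(ch) {
    x <- featureFilter(rectify(dat[ch, ]), featParams, fs)[segIdx]
    max(x) - min(x)
  }, numeric(1))
  thr <- stats::median(amp)
  out <- data.frame(channelIndex = seq_len(nrow(dat)),
                    channelLabel = channelLabels(recording),
                    ampDiff = amp,
                    aboveThreshold = amp > thr * margin)
  attr(out, "threshold") <- thr
  out
}

# combining forms for compound lobe labels, in anatomical order
.lobePrefix <- c(FP = "frontal", F = "frontal", T = "temporal",
                 C = "central", P = "parietal", O = "occipital")
.lobeOrder <- c("frontal", "temporal", "central", "parietal", "occipital")
.lobeCombining <- c(frontal = "fronto", temporal = "temporo",
                    central = "centro", parietal = "parieto",
                    occipital = "occipital")

# electrode name -> lobe (10-20 prefixes; FP checked before F)
electrodeLobe <- function(electrode) {
  e <- toupper(trimws(electrode))
  if (grepl("^FP", e)) return("frontal")
  p <- substr(e, 1L, 1L)
  if (p %in% names(.lobePrefix)) unname(.lobePrefix[p]) else NA_character_
}

#' Map selected channels to a cortical lobe
#'
#' Votes by 10-20 electrode-name prefix (FP/F frontal, T temporal,
#' C central, P parietal, O occipital). Bipolar labels such as "T7-P7"
#' contribute both electrodes. Plurality wins; a two-way tie yields the
#' compound label (e.g. "temporo-occipital"); wider ties yield "mixed";
#' unknown labels are ignored.
#'
#' @param selectedLabels character vector of channel labels.
#' @return a lobe label string.
#' @export
mapToLobe <- function(selectedLabels) {
  electrodes <- unlist(strsplit(selectedLabels, "-", fixed = TRUE))
  # deduplication suffixes from readEDF are numeric; drop pure-number parts
  electrodes <- electrodes[!grepl("^[0-9]+$", electrodes)]
  lobes <- vapply(electrodes, electrodeLobe, character(1))
  lobes <- lobes[!is.na(lobes)]
  if (!length(lobes)) stop("no recognizable 10-20 labels to map")
  counts <- table(factor(lobes, levels = .lobeOrder))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  if (length(top) == 2L)
    return(paste0(.lobeCombining[top[1]], "-", top[2]))
  "mixed"
}

#' Localize detected epochs to channels and lobe
#'
#' Runs [channelScores()] per epoch and maps the selected channels to a
#' cortical lobe. The per-record lobe is the plurality over epochs.
#'
#' @inheritParams channelScores
#' @param epochs a [SeizureEpochSet-class] for the same record.
#' @return list with one element per epoch (each a list of `scores`,
#'   `threshold`, `selected`, `lobe`) plus attribute "recordLobe".
#' @examples
#' sim <- simulateRecording(seed = 3, durationS = 90, nChannels = 8,
#'                          seizures = data.frame(onsetS = 30, durationS = 30))
#' det <- detectSeizures(buildFeatureSignal(sim$recording))
#' loc <- localizeEpochs(sim$recording, det)
#' attr(loc, "recordLobe")
#' @export
localizeEpochs <- function(recording, epochs, preParams = PreprocessParams(),
                           featParams = FeatureParams(), margin = 1.0) {
  if (nEpochs(epochs) == 0L) stop("no epochs to localize")
  ir <- epochRanges(epochs)
  res <- lapply(seq_along(ir), function(k) {
    mask <- integer(nSamples(epochs))
    mask[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- 1L
    sc <- channelScores(recording, mask, preParams, featParams, margin)
    sel <- sc$channelLabel[sc$aboveThreshold]
    list(scores = sc, threshold = attr(sc, "threshold"), selected = sel,
         lobe = if (length(sel)) mapToLobe(sel) else NA_character_)
  })
  lobes <- vapply(res, function(r) r$lobe, character(1))
  lobes <- lobes[!is.na(lobes)]
  attr(res, "recordLobe") <- if (length(lobes))
    names(sort(table(lobes), decreasing = TRUE))[1] else NA_character_
  res
}
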