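#' @include feature.R
NULL

# 1/f-amplitude (pink) noise of length n with unit standard deviation,
# via spectral shaping of seeded white noise.
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid the DC bin
  f <- pmin(f, n - f + 1)              # fold to two-sided frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

hann <- function(n) {
  if (n <= 1) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Simulate a multichannel scalp-EEG-like recording with ground truth
#'
#' Seeded generator of the signal classes the detector must separate:
#' pink-noise background with occasional 10 Hz alpha bursts, slow drift,
#' per-channel DC offsets, common 60 Hz interference, brief large jaw/EMG
#' bursts (20-35 Hz, 0.1-0.3 s), and injected seizures on a channel
#' subset. Each seizure is rhythmic 1-4 Hz activity with a second-harmonic
#' spike component, amplitude-ramped, and opens with a short high-amplitude
#' onset complex -- the "baseline discontinuity" the feature signal shows
#' at a real seizure onset. The same seed gives bitwise-identical output.
#'
#' @param seed integer RNG seed for this record.
#' @param nChannels number of EEG channels (default 23).
#' @param fs sampling rate, Hz (default 256).
#' @param durationS record length, seconds (default 3600).
#' @param seizures NULL for none, or a data.frame with columns onsetS and
#'   durationS (seconds; 30-120 s is the realistic range) and optional
#'   freqHz (1-4) and gain (amplitude multiplier over the background
#'   standard deviation, >= 3; default 7, i.e. ~210 microvolt rhythms, which
#'   keeps the constructed in-band contrast comfortably above the asserted
#'   3x floor). Seizures must lie within the record and not overlap.
#' @param seizureChannels optional list (one integer vector per seizure) of
#'   channel indices carrying the seizure; default: a seeded contiguous
#'   block of `min(6, nChannels)` channels.
#' @param backgroundAmp background pink-noise standard deviation, microvolts
#'   (default 30).
#' @param spikeFactor onset-complex amplitude as a multiple of the sustained
#'   ictal amplitude (default 4).
#' @param alphaRatePerMin rate of 1 s alpha bursts (default 6).
#' @param emgRatePerHour rate of jaw/EMG bursts (default 30).
#' @param emgAmp EMG burst amplitude, microvolts (default 80).
#' @param powerlineAmp 60 Hz interference amplitude, microvolts (default 10).
#' @param driftAmp slow (< 0.05 Hz) drift amplitude, microvolts (default 30).
#' @param dcOffsetMax per-channel DC offset bound, microvolts (default 200).
#' @param recordId file id used in the returned annotations.
#' @param checkInBand assert that each injected ictal segment carries at
#'   least 3x the in-band (seizure band) RMS of the adjacent background on
#'   its channel subset (default TRUE).
#' @return list with elements `recording` ([EEGRecording-class]) and
#'   `annotations` ([AnnotationSet-class] listing exactly the injected
#'   seizures).
#' @examples
#' sim <- simulateRecording(seed = 1, durationS = 30, nChannels = 4)
#' sim$recording
#' @export
simulateRecording <- function(seed, nChannels = 23, fs = 256,
                              durationS = 3600, seizures = NULL,
                              seizureChannels = NULL, backgroundAmp = 30,
                              spikeFactor = 4, alphaRatePerMin = 6,
                              emgRatePerHour = 30, emgAmp = 80,
                              powerlineAmp = 10, driftAmp = 30,
                              dcOffsetMax = 200,
                              recordId = sprintf("sim_%d.edf", seed),
                              checkInBand = TRUE) {
  n <- round(durationS * fs)
  stopifnot(n >= fs, nChannels >= 1)
  if (!is.null(seizures) && nrow(seizures)) {
    seizures <- seizures[order(seizures$onsetS), , drop = FALSE]
    if (is.null(seizures$freqHz)) seizures$freqHz <- NA_real_
    if (is.null(seizures$gain)) seizures$gain <- 7
    ends <- seizures$onsetS + seizures$durationS
    if (any(seizures$onsetS < 0) || any(ends > durationS))
      stop("seizures must lie within the record")
    if (nrow(seizures) > 1 &&
        any(seizures$onsetS[-1] < ends[-nrow(seizures)]))
      stop("injected seizures must not overlap")
  }

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed %% 2147483647L)

  t <- seq_len(n) / fs
  dat <- matrix(0, nrow = nChannels, ncol = n)

  # background + drift + DC offset, per channel
  for (ch in seq_len(nChannels)) {
    x <- backgroundAmp * pinkNoise(n)
    fDrift <- stats::runif(1, 0.01, 0.04)
    x <- x + driftAmp * sin(2 * pi * fDrift * t + stats::runif(1, 0, 2 * pi))
    x <- x + stats::runif(1, -dcOffsetMax, dcOffsetMax)
    dat[ch, ] <- x
  }

  # common 60 Hz interference
  if (powerlineAmp > 0)
    dat <- dat + matrix(powerlineAmp * sin(2 * pi * 60 * t +
                                           stats::runif(1, 0, 2 * pi)),
                        nrow = nChannels, ncol = n, byrow = TRUE)

  # alpha bursts: 10 Hz, 1 s, Hanning-windowed, on a small random subset
  nAlpha <- stats::rpois(1, alphaRatePerMin * durationS / 60)
  for (k in seq_len(nAlpha)) {
    c0 <- stats::runif(1, 0.5, durationS - 0.5)
    i0 <- max(1L, round((c0 - 0.5) * fs)); i1 <- min(n, i0 + fs - 1L)
    idx <- i0:i1
    chans <- sample.int(nChannels, min(3L, nChannels))
    w <- hann(length(idx))
    burst <- 20 * sin(2 * pi * 10 * t[idx] + stats::runif(1, 0, 2 * pi)) * w
    dat[chans, idx] <- dat[chans, idx] +
      matrix(burst, nrow = length(chans), ncol = length(idx), byrow = TRUE)
  }

  # jaw/EMG bursts: 20-35 Hz, 0.1-0.3 s, independent across channels
  nEmg <- stats::rpois(1, emgRatePerHour * durationS / 3600)
  for (k in seq_len(nEmg)) {
    dur <- stats::runif(1, 0.1, 0.3)
    c0 <- stats::runif(1, dur, durationS - dur)
    i0 <- max(1L, round(c0 * fs)); i1 <- min(n, i0 + round(dur * fs) - 1L)
    idx <- i0:i1
    w <- hann(length(idx))
    for (ch in seq_len(nChannels)) {
      fe <- stats::runif(1, 20, 35)
      dat[ch, idx] <- dat[ch, idx] +
        emgAmp * sin(2 * pi * fe * t[idx] + stats::runif(1, 0, 2 * pi)) * w
    }
  }

  # injected seizures
  annRows <- NULL
  if (!is.null(seizures) && nrow(seizures)) {
    seizures$channels <- vector("list", nrow(seizures))
    for (s in seq_len(nrow(seizures))) {
      on <- seizures$onsetS[s]; du <- seizures$durationS[s]
      fI <- seizures$freqHz[s]
      if (is.na(fI)) fI <- stats::runif(1, 1, 4)
      gain <- max(seizures$gain[s], 3)
      if (!is.null(seizureChannels)) {
        chans <- seizureChannels[[s]]
        stopifnot(length(chans) >= 1, all(chans %in% seq_len(nChannels)))
      } else {
        blk <- min(6L, nChannels)
        st <- sample.int(max(nChannels - blk + 1L, 1L), 1L)
        chans <- st:(st + blk - 1L)
      }
      i0 <- floor(on * fs) + 1L
      i1 <- min(n, ceiling((on + du) * fs))
      idx <- i0:i1
      tt <- (idx - i0) / fs
      ampSustained <- gain * backgroundAmp * stats::runif(1, 0.97, 1.03)
      ramp <- pmin(1, pmin(tt, max(tt) - tt) / 3)   # 3 s rise/fall
      wave <- ampSustained * ramp *
        (sin(2 * pi * fI * tt + stats::runif(1, 0, 2 * pi)) +
         0.3 * sin(4 * pi * fI * tt))
      # onset complex: brief high-amplitude discontinuity at seizure start;
      # fixed 3 Hz so its envelope does not depend on the ictal frequency
      spikeLen <- min(length(idx), round(0.5 * fs))
      spikeEnv <- hann(spikeLen)
      wave[seq_len(spikeLen)] <- wave[seq_len(spikeLen)] +
        spikeFactor * ampSustained * spikeEnv *
          sin(2 * pi * 3 * tt[seq_len(spikeLen)])
      dat[chans, idx] <- dat[chans, idx] +
        matrix(wave, nrow = length(chans), ncol = length(idx), byrow = TRUE)
      annRows <- rbind(annRows, data.frame(fileId = recordId, onsetS = on,
                                           endS = on + du))
      prevEnd <- if (s > 1)
        ceiling((seizures$onsetS[s - 1] + seizures$durationS[s - 1]) * fs)
      else 0L
      if (checkInBand)
        assertInBandContrast(dat, chans, i0, i1, fs, n, prevEnd)
      seizures$channels[[s]] <- chans
    }
  }

  labels <- chbStyleLabels(nChannels)
  rec <- EEGRecording(dat, fs = fs, channelLabels = labels, source = recordId)
  ann <- if (is.null(annRows))
    AnnotationSet(roster = recordId, totalHours = durationS / 3600)
  else AnnotationSet(annRows, roster = recordId, totalHours = durationS / 3600)
  list(recording = rec, annotations = ann,
       seizures = if (is.null(seizures)) NULL else seizures)
}

# ictal in-band (0.1-4.1 Hz) RMS must dominate adjacent background by
# >= 3x on the injected channels (construction guarantee; segment-local
# check). The low band edge matters: sub-0.1 Hz drift is not in band, so
# it is removed (DC notch) before measuring.
assertInBandContrast <- function(dat, chans, i0, i1, fs, n, prevEnd = 0L) {
  b <- designLowpass(30, 4.1, fs)
  dcn <- designDCNotch(0.9991)
  # background window: the seizure-free stretch just before onset (after any
  # previous seizure), falling back to after the seizure for onsets at t=0
  len <- min(i1 - i0 + 1L, i0 - prevEnd - 1L - fs)
  bgIdx <- if (len >= 5L * fs) (i0 - len):(i0 - 1L)
           else (i1 + 1L):min(n, i1 + (i1 - i0 + 1L))
  inband <- function(x) {
    x <- zeroPhaseFilter(x - mean(x), dcn$b, dcn$a)
    sqrt(mean(zeroPhaseFilter(x, b)^2))
  }
  for (ch in chans) {
    if (inband(dat[ch, i0:i1]) < 3 * inband(dat[ch, bgIdx]))
      stop("injected seizure lacks 3x in-band contrast on channel ", ch)
  }
  invisible(TRUE)
}

# plausible 10-20 bipolar labels for n channels (recycled block)
chbStyleLabels <- function(n) {
  base <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3",
            "C3-P3", "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
            "FP2-F8", "F8-T8", "T8-P8", "P8-O2", "FZ-CZ", "CZ-PZ",
            "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8", "T8-P8")
  dedupLabels(rep(base, length.out = n))
}

#' Draw the study-condition seizure layout for one corpus record
#'
#' Record `index` of a corpus keyed by `seed` gets its own RNG stream
#' (seeded by seed and index), so corpora are reproducible under any
#' generation order. Every fifth record is artefact-only (no seizures) so
#' false positives per hour are measurable; the rest carry 1-3 seizures of
#' 30-120 s at seeded positions with at least 20 s clearance.
#'
#' @param seed corpus seed.
#' @param index record number (1-based).
#' @param durationS record length in seconds (default 600).
#' @inheritParams simulateRecording
#' @return as [simulateRecording()], with `recordId` "simNNNN.edf".
#' @export
simulateCorpusRecord <- function(seed, index, durationS = 600, nChannels = 23,
                                 fs = 256, ...) {
  rseed <- as.integer((as.numeric(seed) * 10007 + index) %% 2147483647)
  recordId <- sprintf("sim%04d.edf", index)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(rseed)
  seizures <- NULL
  if (index %% 5L != 0L) {
    k <- min(sample(1:3, 1), max(1L, durationS %/% 120L))
    slot <- durationS / k
    rows <- lapply(seq_len(k), function(j) {
      du <- stats::runif(1, 30, min(120, slot - 45))
      on <- stats::runif(1, (j - 1) * slot + 20, j * slot - du - 20)
      data.frame(onsetS = on, durationS = du)
    })
    seizures <- do.call(rbind, rows)
  }
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  simulateRecording(seed = rseed, nChannels = nChannels, fs = fs,
                    durationS = durationS, seizures = seizures,
                    recordId = recordId, ...)
}

#' Write a synthetic test corpus to disk
#'
#' Generates `nRecords` corpus records (see [simulateCorpusRecord()]),
#' writes each as EDF plus a ground-truth CSV in the annotations dialect
#' (`truth.csv`) and a manifest (`manifest.csv`) with per-file seizure
#' counts. Re-running with the same seed reproduces every byte of the
#' truth file.
#'
#' @param nRecords number of records.
#' @param seed corpus seed.
#' @param dir output directory (created if needed).
#' @param durationS record length in seconds (default 600).
#' @param ... forwarded to [simulateCorpusRecord()].
#' @return invisibly, the manifest data.frame.
#' @export
makeTestSuite <- function(nRecords, seed, dir, durationS = 600, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL
  truth <- NULL
  for (i in seq_len(nRecords)) {
    sim <- simulateCorpusRecord(seed, i, durationS = durationS, ...)
    fileId <- recordSource(sim$recording)
    writeEDF(sim$recording, file.path(dir, fileId))
    e <- annotationEntries(sim$annotations)
    truth <- rbind(truth, e)
    manifest <- rbind(manifest,
                      data.frame(file_id = fileId, n_seizures = nrow(e),
                                 duration_s = durationS))
  }
  if (is.null(truth))
    truth <- data.frame(fileId = character(0), onsetS = numeric(0),
                        endS = numeric(0))
  utils::write.csv(data.frame(file_id = truth$fileId,
                              onset_s = truth$onsetS, end_s = truth$endS),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
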