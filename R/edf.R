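#' @include AllClasses.R
NULL

# EDF header field widths (16-bit European Data Format). Strings are ASCII,
# right-padded with spaces; samples are little-endian int16 scaled linearly
# between the digital and physical extrema declared per signal.

padField <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

readField <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    trimws(readChar(con, width, useBytes = TRUE))
  }, character(1))
}

#' Read an EDF/EDF+ recording
#'
#' Reads all EEG signals of a 16-bit EDF file into an [EEGRecording-class].
#' Channels whose label is on `dropLabels` (placeholder and non-EEG
#' channels such as ECG) are discarded before any processing, because the
#' channel average must span EEG channels only. Duplicate labels are
#' disambiguated deterministically with "-1", "-2", ... suffixes in order
#' of appearance. All retained signals must share one sampling rate.
#'
#' @param path path to an EDF file.
#' @param dropLabels character vector of channel labels to discard
#'   (exact match after trimming).
#' @return an [EEGRecording-class]; data in the physical units declared in
#'   the file (microvolts for scalp EEG), channel order as in the header.
#' @seealso [writeEDF()]
#' @export
readEDF <- function(path, dropLabels = c("-", "--", ".", "ECG", "EKG",
                                         "VNS", "LOC", "ROC")) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readField(con, 8L)
  if (!version %in% c("0", "")) stop("unrecognized EDF version field: ",
                                     version)
  readField(con, 80L)            # patient id
  readField(con, 80L)            # recording id
  readField(con, 8L)             # start date
  startTime <- readField(con, 8L)
  headerBytes <- suppressWarnings(as.integer(readField(con, 8L)))
  readField(con, 44L)            # reserved
  nRecords <- suppressWarnings(as.integer(readField(con, 8L)))
  recDur <- suppressWarnings(as.numeric(readField(con, 8L)))
  ns <- suppressWarnings(as.integer(readField(con, 4L)))
  if (is.na(ns) || ns < 1L || is.na(nRecords) || nRecords < 1L ||
      is.na(recDur) || recDur <= 0 || is.na(headerBytes))
    stop("corrupt EDF header")
  labels <- readField(con, 16L, ns)
  readField(con, 80L, ns)        # transducer
  readField(con, 8L, ns)         # physical dimension
  physMin <- as.numeric(readField(con, 8L, ns))
  physMax <- as.numeric(readField(con, 8L, ns))
  digMin <- as.numeric(readField(con, 8L, ns))
  digMax <- as.numeric(readField(con, 8L, ns))
  readField(con, 80L, ns)        # prefiltering
  spr <- as.integer(readField(con, 8L, ns))
  readField(con, 32L, ns)        # reserved
  if (any(is.na(c(physMin, physMax, digMin, digMax, spr))) ||
      any(digMax <= digMin) || any(spr < 1L))
    stop("corrupt EDF signal headers")

  keep <- !(labels %in% dropLabels) & nzchar(labels)
  if (!any(keep)) stop("no EEG channels remain after label filtering")
  fsAll <- spr / recDur
  if (length(unique(fsAll[keep])) != 1L)
    stop("unsupported layout: EEG channels have mixed sampling rates")

  raw <- readBin(con, "integer", n = nRecords * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nRecords * sum(spr)) stop("truncated EDF data section")
  # de-interleave: records of per-signal blocks
  offsets <- c(0L, cumsum(spr))
  recLen <- sum(spr)
  data <- matrix(0, nrow = sum(keep), ncol = nRecords * spr[which(keep)[1]])
  row <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    row <- row + 1L
    idx <- as.vector(outer(seq_len(spr[s]) + offsets[s],
                           (seq_len(nRecords) - 1L) * recLen, "+"))
    scale <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
    data[row, ] <- (raw[idx] - digMin[s]) * scale + physMin[s]
  }
  if (any(!is.finite(data))) stop("non-finite samples after EDF load")

  rec <- EEGRecording(data, fs = fsAll[keep][1],
                      channelLabels = dedupLabels(labels[keep]),
                      startTime = if (nzchar(startTime)) startTime
                                  else NA_character_,
                      source = basename(path))
  rec
}

# duplicate labels get -1, -2, ... suffixes (every member of a duplicated
# group is suffixed, so addressing is deterministic)
dedupLabels <- function(labels) {
  dup <- labels %in% labels[duplicated(labels)]
  if (!any(dup)) return(labels)
  for (lab in unique(labels[dup])) {
    i <- which(labels == lab)
    labels[i] <- paste0(lab, "-", seq_along(i))
  }
  labels
}

#' Write an EEGRecording to EDF
#'
#' Writes 16-bit EDF with a symmetric physical range per channel chosen
#' from the channel extrema, so the round-trip quantization error is
#' bounded by (physical range) / 2^15 and exact zeros survive exactly.
#' Records are 1 s long when the sample count divides evenly by the
#' sampling rate, otherwise a single data record holds the whole signal.
#'
#' @param recording an [EEGRecording-class] with finite samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(recording, path) {
  dat <- channelData(recording)
  if (ncol(dat) < 1L) stop("cannot write an empty recording (0 samples)")
  if (any(!is.finite(dat))) stop("non-finite samples cannot be written to EDF")
  fs <- samplingRate(recording)
  n <- ncol(dat)
  nc <- nrow(dat)
  if (fs == round(fs) && n %% fs == 0L) {
    recDur <- 1; spr <- as.integer(fs); nRecords <- as.integer(n / fs)
  } else {
    recDur <- n / fs; spr <- as.integer(n); nRecords <- 1L
  }
  ampl <- pmax(apply(abs(dat), 1L, max), 1e-9)
  digMin <- -32767L; digMax <- 32767L
  physMin <- -ampl; physMax <- ampl

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(padField(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8L)
  wr("X X X X", 80L)
  wr("Startdate X X X X", 80L)
  wr("01.01.00", 8L)
  wr(if (is.na(recording@startTime)) "00.00.00" else recording@startTime, 8L)
  wr(as.character(256L * (nc + 1L)), 8L)
  wr("", 44L)
  wr(as.character(nRecords), 8L)
  wr(format(recDur, digits = 7), 8L)
  wr(as.character(nc), 4L)
  for (f in list(list(channelLabels(recording), 16L),
                 list(rep("", nc), 80L),
                 list(rep("uV", nc), 8L),
                 list(formatC(physMin, digits = 6, width = 8), 8L),
                 list(formatC(physMax, digits = 6, width = 8), 8L),
                 list(rep(digMin, nc), 8L),
                 list(rep(digMax, nc), 8L),
                 list(rep("", nc), 80L),
                 list(rep(spr, nc), 8L),
                 list(rep("", nc), 32L)))
    wr(f[[1]], f[[2]])

  # symmetric digital range: dig = round(x * 32767 / ampl), so 0 -> 0 exactly
  dig <- round(dat * (digMax / ampl))
  dig <- pmin(pmax(dig, digMin), digMax)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])[seq_len(spr), ,
                                                     drop = FALSE]),
             con, size = 2L, endian = "little")
  }
  invisible(path)
}
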