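#' @include AllClasses.R
NULL

#' Read seizure annotations
#'
#' Three dialects are supported:
#' \describe{
#'   \item{csv}{header `file_id,onset_s,end_s`, one row per seizure.}
#'   \item{json}{array of objects with fields `file_id`, `onset_s`, `end_s`.}
#'   \item{chbmit_summary}{the `*-summary.txt` block format of the CHB-MIT
#'     scalp EEG corpus: "File Name:", "Number of Seizures in File:" and
#'     per-seizure "Seizure Start Time:"/"Seizure End Time:" lines with
#'     integer seconds. Files with zero seizures contribute no entries but
#'     stay on the roster for true-negative accounting.}
#' }
#'
#' @param path annotation file.
#' @param dialect one of "csv", "json", "chbmit_summary".
#' @param roster optional extra file ids to keep on the roster (e.g. files
#'   with no seizures when reading the csv dialect).
#' @param totalHours optional total recording hours for FP/h reporting.
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path, dialect = c("csv", "chbmit_summary", "json"),
                            roster = character(0), totalHours = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- switch(dialect,
    csv = readAnnotationsCSV(path),
    json = readAnnotationsJSON(path),
    chbmit_summary = readChbmitSummary(path))
  AnnotationSet(ann$entries, roster = c(roster, ann$roster),
                totalHours = totalHours)
}

readAnnotationsCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file_id", "onset_s", "end_s")
  if (!all(need %in% names(tab)))
    stop("csv dialect requires a header with columns ",
         paste(need, collapse = ", "))
  bad <- which(tab$end_s <= tab$onset_s)
  if (length(bad))
    stop("end <= start at data line ", bad[1], " of ", path)
  list(entries = data.frame(fileId = tab$file_id, onsetS = tab$onset_s,
                            endS = tab$end_s),
       roster = unique(tab$file_id))
}

readAnnotationsJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(obj) == 0L)
    return(list(entries = data.frame(fileId = character(0),
                                     onsetS = numeric(0), endS = numeric(0)),
                roster = character(0)))
  need <- c("file_id", "onset_s", "end_s")
  if (!all(need %in% names(obj)))
    stop("json dialect requires objects with fields ",
         paste(need, collapse = ", "))
  bad <- which(obj$end_s <= obj$onset_s)
  if (length(bad)) stop("end <= start at entry ", bad[1], " of ", path)
  list(entries = data.frame(fileId = obj$file_id, onsetS = obj$onset_s,
                            endS = obj$end_s),
       roster = unique(obj$file_id))
}

readChbmitSummary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  roster <- character(0)
  fileId <- character(0); onset <- numeric(0); end <- numeric(0)
  current <- NA_character_
  pendingStart <- NULL
  num <- function(x) as.numeric(sub("^.*?:\\s*([0-9.]+).*$", "\\1", x))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*File Name\\s*:", ln)) {
      current <- trimws(sub("^\\s*File Name\\s*:\\s*", "", ln))
      roster <- c(roster, current)
      pendingStart <- NULL
    } else if (grepl("^\\s*Seizure.*Start Time\\s*:", ln)) {
      pendingStart <- num(ln)
    } else if (grepl("^\\s*Seizure.*End Time\\s*:", ln)) {
      if (is.null(pendingStart) || is.na(current))
        stop("summary parse error: end time without start at line ", i)
      e <- num(ln)
      if (e <= pendingStart)
        stop("end <= start at line ", i, " of ", path)
      fileId <- c(fileId, current); onset <- c(onset, pendingStart)
      end <- c(end, e)
      pendingStart <- NULL
    }
  }
  list(entries = data.frame(fileId = fileId, onsetS = onset, endS = end),
       roster = unique(roster))
}

#' Write detected epochs to CSV or JSON
#'
#' One row/object per epoch with the source file id, onset and end in
#' seconds (2 decimals), the normalized peak value and the in-band epoch
#' power, sorted by (fileId, onset). An empty detection set yields a
#' header-only CSV (or empty JSON array).
#'
#' @param detections either a data.frame as returned by [detectionTable()],
#'   or a named list of [SeizureEpochSet-class] objects keyed by file id.
#' @param path output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
writeDetections <- function(detections, path) {
  if (is.list(detections) && !is.data.frame(detections))
    detections <- do.call(rbind, Map(detectionTable, detections,
                                     names(detections)))
  if (is.null(detections) || nrow(detections) == 0L)
    detections <- data.frame(file_id = character(0), onset_s = numeric(0),
                             end_s = numeric(0), peak_value = numeric(0),
                             power = numeric(0))
  detections <- detections[order(detections$file_id, detections$onset_s), ,
                           drop = FALSE]
  detections$onset_s <- round(detections$onset_s, 2)
  detections$end_s <- round(detections$end_s, 2)
  rownames(detections) <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(detections, path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(detections, path, row.names = FALSE)
  }
  invisible(path)
}

#' Flat detection table for one record
#'
#' @param epochs a [SeizureEpochSet-class].
#' @param fileId the source file id to stamp on every row.
#' @return data.frame with columns file_id, onset_s, end_s, peak_value, power.
#' @export
detectionTable <- function(epochs, fileId) {
  tab <- epochTable(epochs)
  data.frame(file_id = rep(fileId, nrow(tab)), onset_s = tab$onsetS,
             end_s = tab$endS, peak_value = tab$peakValue, power = tab$power)
}

#' Read a detection table written by [writeDetections()]
#'
#' @param path .csv or .json detections file.
#' @return data.frame with columns file_id, onset_s, end_s, peak_value, power.
#' @export
readDetections <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(out) == 0L)
      out <- data.frame(file_id = character(0), onset_s = numeric(0),
                        end_s = numeric(0))
    out
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
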