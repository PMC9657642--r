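#' @include detect.R
NULL

#' Match detections against annotated seizures
#'
#' Event matching with the any-overlap rule: an annotated seizure counts as
#' a true positive when at least one detection overlaps it and as a false
#' negative otherwise; a detection overlapping no annotation is a false
#' positive; a roster record with neither annotations nor detections is a
#' true negative (record-unit accounting, the convention of per-patient
#' seizure tables).
#'
#' @param detections data.frame with columns file_id, onset_s, end_s (as
#'   from [readDetections()] / [detectionTable()]).
#' @param truth an [AnnotationSet-class]; its roster must cover every file
#'   appearing in `detections`.
#' @param latencyS optional onset-latency window: a detection only matches
#'   an annotation when additionally its onset lies within `latencyS`
#'   seconds of the annotated onset (default Inf = pure any-overlap).
#' @return named integer vector c(tp, fp, fn, tn).
#' @export
matchEvents <- function(detections, truth, latencyS = Inf) {
  roster <- annotationRoster(truth)
  ann <- annotationEntries(truth)
  if (nrow(detections) && !all(detections$file_id %in% roster))
    stop("detections reference files missing from the roster: ",
         paste(setdiff(unique(detections$file_id), roster), collapse = ", "))
  tp <- 0L; fn <- 0L; fp <- 0L
  for (f in roster) {
    a <- ann[ann$fileId == f, , drop = FALSE]
    d <- detections[detections$file_id == f, , drop = FALSE]
    if (nrow(a)) {
      hit <- logical(nrow(a))
      used <- logical(nrow(d))
      if (nrow(d)) for (i in seq_len(nrow(a))) {
        ov <- d$onset_s < a$endS[i] & d$end_s > a$onsetS[i]
        if (is.finite(latencyS))
          ov <- ov & abs(d$onset_s - a$onsetS[i]) <= latencyS
        hit[i] <- any(ov)
        used <- used | ov
      }
      tp <- tp + sum(hit)
      fn <- fn + sum(!hit)
      fp <- fp + sum(!used)
    } else {
      fp <- fp + nrow(d)
    }
  }
  annotated <- unique(ann$fileId)
  detected <- unique(detections$file_id[detections$file_id %in% roster])
  tn <- sum(!(roster %in% annotated) & !(roster %in% detected))
  c(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tn = as.integer(tn))
}

checkCounts <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts)))
    stop("counts must be a named vector with tp, fp, fn, tn")
  if (any(counts[need] < 0)) stop("counts must be non-negative")
  counts[need]
}

#' Confusion-count metrics
#'
#' The six standard detection metrics on the percent scale, each returning
#' NA (an "undefined" signal, deliberately neither 0 nor 100) when its
#' denominator is zero:
#' sensitivity = 100 TP/(TP+FN); specificity = 100 TN/(TN+FP);
#' precision = 100 TP/(TP+FP); accuracy = 100 (TP+TN)/(TP+TN+FP+FN);
#' F-measure = harmonic mean of precision and sensitivity;
#' G-mean = sqrt(sensitivity x specificity).
#'
#' @param counts named vector with elements tp, fp, fn, tn.
#' @return percent value (scalar), NA when undefined.
#' @name metrics
NULL

#' @rdname metrics
#' @export
sensitivityPct <- function(counts) {
  counts <- checkCounts(counts)
  d <- counts["tp"] + counts["fn"]
  if (d == 0) return(NA_real_)
  unname(100 * counts["tp"] / d)
}

#' @rdname metrics
#' @export
specificityPct <- function(counts) {
  counts <- checkCounts(counts)
  d <- counts["tn"] + counts["fp"]
  if (d == 0) return(NA_real_)
  unname(100 * counts["tn"] / d)
}

#' @rdname metrics
#' @export
precisionPct <- function(counts) {
  counts <- checkCounts(counts)
  d <- counts["tp"] + counts["fp"]
  if (d == 0) return(NA_real_)
  unname(100 * counts["tp"] / d)
}

#' @rdname metrics
#' @export
accuracyPct <- function(counts) {
  counts <- checkCounts(counts)
  d <- sum(counts)
  if (d == 0) return(NA_real_)
  unname(100 * (counts["tp"] + counts["tn"]) / d)
}

#' @rdname metrics
#' @export
fMeasurePct <- function(counts) {
  p <- precisionPct(counts); s <- sensitivityPct(counts)
  if (is.na(p) || is.na(s) || p + s == 0) return(NA_real_)
  2 * p * s / (p + s)
}

#' @rdname metrics
#' @export
gMeanPct <- function(counts) {
  s <- sensitivityPct(counts); sp <- specificityPct(counts)
  if (is.na(s) || is.na(sp)) return(NA_real_)
  sqrt(s * sp)
}

#' False positives per hour
#'
#' @param fp false-positive count.
#' @param hours recording hours (> 0).
#' @return fp / hours.
#' @export
fpPerHour <- function(fp, hours) {
  if (!is.finite(hours) || hours <= 0) stop("hours must be positive")
  fp / hours
}

#' Full metrics report for one unit (patient or record set)
#'
#' @param counts named vector with tp, fp, fn, tn.
#' @param hours optional recording hours for the FP/h column.
#' @return one-row data.frame with the counts, the six percent metrics
#'   (full precision; round for display) and fpPerHour.
#' @export
metricsReport <- function(counts, hours = NA_real_) {
  counts <- checkCounts(counts)
  data.frame(tp = counts["tp"], fp = counts["fp"], fn = counts["fn"],
             tn = counts["tn"],
             sensitivity = sensitivityPct(counts),
             specificity = specificityPct(counts),
             precision = precisionPct(counts),
             accuracy = accuracyPct(counts),
             fMeasure = fMeasurePct(counts),
             gMean = gMeanPct(counts),
             fpPerHour = if (is.na(hours)) NA_real_
                         else fpPerHour(counts["fp"], hours),
             row.names = NULL)
}

#' Aggregate per-patient reports into a dataset summary
#'
#' Two views are reported because they generally differ: the unweighted
#' arithmetic mean of each per-patient metric (the convention of
#' per-patient benchmark tables) and the metrics of the pooled counts.
#'
#' @param perPatient data.frame of [metricsReport()] rows (one per patient).
#' @param hours optional total recording hours.
#' @return list with `means` (named numeric, NA-removed means of the six
#'   metrics), `pooledCounts` (summed tp/fp/fn/tn) and `pooled` (metrics of
#'   the pooled counts).
#' @export
aggregateMetrics <- function(perPatient, hours = NA_real_) {
  stopifnot(nrow(perPatient) >= 1L)
  cols <- c("sensitivity", "specificity", "precision", "accuracy",
            "fMeasure", "gMean")
  means <- vapply(cols, function(cl) mean(perPatient[[cl]], na.rm = TRUE),
                  numeric(1))
  pooled <- c(tp = sum(perPatient$tp), fp = sum(perPatient$fp),
              fn = sum(perPatient$fn), tn = sum(perPatient$tn))
  list(means = means, pooledCounts = pooled,
       pooled = metricsReport(pooled, hours))
}

#' Published per-patient confusion counts (CHB-MIT benchmark)
#'
#' Published per-patient TP/FP/FN/TN counts for the CHB-MIT paediatric
#' scalp EEG corpus under this detection approach, shipped as plain-text
#' CSV: `"manual"` is the assisted manual review over all 24 patients,
#' `"automated"` the fully automated rule over the 17 patients it was
#' reported for. These counts are inputs to the metric arithmetic (the
#' corpus itself is an external download and is not required).
#'
#' @param mode "manual" or "automated".
#' @return data.frame with columns patient, trials, tp, fp, fn, tn.
#' @export
chbmitPublishedCounts <- function(mode = c("manual", "automated")) {
  mode <- match.arg(mode)
  f <- system.file("extdata", paste0("chbmit_", mode, "_counts.csv"),
                   package = "seizefeat", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
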