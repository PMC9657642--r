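#' @include evaluate.R localize.R simulate.R
NULL

# flat config keys accepted in YAML / runConfig(), mapped to param objects
.configKeys <- list(
  lpCutoff = "preprocess", lpOrder = "preprocess",
  powerlineFreq = "preprocess", powerlineEnabled = "preprocess",
  powerlineHarmonics = "preprocess", notchQ = "preprocess",
  dcLambda = "preprocess", zeroPhase = "preprocess",
  bandLo = "feature", bandHi = "feature", ffOrder = "feature",
  rmsWindow = "feature", applyHighpass = "feature", rectifyFirst = "feature",
  minEpochSamples = "detect", powerThreshold = "detect",
  ampLower = "detect", ampUpper = "detect",
  widthMinS = "detect", widthMaxS = "detect")

#' Assemble a validated run configuration
#'
#' Merges a flat key-value list (e.g. read from a YAML file) over the
#' default parameters. Unknown keys are rejected; every parameter object
#' is validated, so out-of-range values (e.g. dcLambda = 1.2) fail here
#' with a parameter error. The returned object carries a provenance block:
#' package version and a checksum of the effective parameter set.
#'
#' @param overrides named list of parameter overrides, or a YAML file path.
#' @return list with elements `preprocess`, `feature`, `detect` (validated
#'   parameter objects) and `provenance`.
#' @export
runConfig <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- yaml::read_yaml(overrides)
  if (is.null(overrides)) overrides <- list()
  unknown <- setdiff(names(overrides), names(.configKeys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  pick <- function(group) overrides[names(overrides)[
    vapply(names(overrides), function(k) .configKeys[[k]] == group,
           logical(1))]]
  pre <- do.call(PreprocessParams, pick("preprocess"))
  feat <- do.call(FeatureParams, pick("feature"))
  det <- do.call(DetectionParams, pick("detect"))
  for (p in list(pre, feat, det)) methods::validObject(p)
  flat <- effectiveParams(pre, feat, det)
  tf <- tempfile()
  writeLines(paste(names(flat), vapply(flat, format, character(1)),
                   sep = "="), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(preprocess = pre, feature = feat, detect = det,
       provenance = list(package = "seizefeat",
                         version = as.character(
                           utils::packageVersion("seizefeat")),
                         paramHash = hash, params = flat))
}

effectiveParams <- function(pre, feat, det) {
  vals <- list()
  for (obj in list(pre, feat, det))
    for (sl in methods::slotNames(class(obj)))
      vals[[sl]] <- methods::slot(obj, sl)
  vals[order(names(vals))]
}

logMsg <- function(level, ..., logLevel = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[logLevel]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}

#' Run detection over a set of EDF files
#'
#' The per-file loop of the method: read, build the feature signal, detect
#' epochs, write one detections CSV per input plus a combined table.
#' Deterministic: the same config and inputs give identical outputs.
#'
#' @param paths character vector of EDF file paths.
#' @param config a [runConfig()] object (or overrides list / YAML path).
#' @param outDir output directory for per-file detection CSVs (NULL = none).
#' @param logLevel "debug", "info", "warn" or "quiet".
#' @return data.frame of all detections (columns file_id, onset_s, end_s,
#'   peak_value, power), with the config provenance as attribute
#'   "provenance" and per-file row counts as attribute "files".
#' @export
runDetect <- function(paths, config = runConfig(), outDir = NULL,
                      logLevel = "info") {
  if (!is.list(config) || is.null(config$detect)) config <- runConfig(config)
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  all <- NULL
  counts <- integer(0)
  for (p in paths) {
    t0 <- Sys.time()
    rec <- readEDF(p)
    feat <- buildFeatureSignal(rec, config$preprocess, config$feature)
    det <- detectSeizures(feat, config$detect)
    tab <- detectionTable(det, basename(p))
    counts[basename(p)] <- nrow(tab)
    if (!is.null(outDir))
      writeDetections(tab, file.path(outDir,
                                     sub("\\.edf$", ".csv", basename(p),
                                         ignore.case = TRUE)))
    all <- rbind(all, tab)
    logMsg("info", basename(p), ": ", nrow(tab), " epoch(s) in ",
           sprintf("%.2f", as.numeric(Sys.time() - t0, units = "secs")),
           " s", logLevel = logLevel)
  }
  if (is.null(all))
    all <- data.frame(file_id = character(0), onset_s = numeric(0),
                      end_s = numeric(0), peak_value = numeric(0),
                      power = numeric(0))
  attr(all, "provenance") <- config$provenance
  attr(all, "files") <- counts
  all
}

#' Score detections and produce a per-patient style report
#'
#' Groups the roster into patients (by `patientOf`, default: everything
#' before the first underscore of the file id), computes per-patient
#' confusion counts with [matchEvents()] and the six metrics, and appends
#' the dataset summary: unweighted means of the per-patient metrics plus
#' pooled counts. The full parameter provenance of the detections (when
#' present) is carried through as an attribute.
#'
#' @param detections detections data.frame (see [runDetect()]).
#' @param truth an [AnnotationSet-class] whose roster covers the corpus.
#' @param patientOf function mapping file ids to patient ids.
#' @return list with `perPatient` (data.frame, one row per patient),
#'   `summary` (see [aggregateMetrics()]) and `provenance`.
#' @export
runReport <- function(detections, truth,
                      patientOf = function(f) sub("_.*$", "", f)) {
  roster <- annotationRoster(truth)
  if (nrow(detections) && !all(detections$file_id %in% roster))
    stop("detections reference files missing from the roster")
  hoursAll <- totalHours(truth)
  pats <- sort(unique(patientOf(roster)))
  rows <- lapply(pats, function(p) {
    files <- roster[patientOf(roster) == p]
    sub <- AnnotationSet(
      annotationEntries(truth)[annotationEntries(truth)$fileId %in% files, ,
                               drop = FALSE],
      roster = files)
    cnt <- matchEvents(detections[detections$file_id %in% files, ,
                                  drop = FALSE], sub)
    cbind(data.frame(patient = p, trials = length(files)),
          metricsReport(cnt))
  })
  perPatient <- do.call(rbind, rows)
  list(perPatient = perPatient,
       summary = aggregateMetrics(perPatient, hoursAll),
       provenance = attr(detections, "provenance"))
}
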