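test_that("EDF round-trip is identity within the 16-bit quantization step", {
  sim <- simulateRecording(seed = 7, nChannels = 4, durationS = 10)
  rec <- sim$recording
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_equal(nChannels(back), 4L)
  expect_equal(nSamples(back), 2560L)  # duration x fs
  expect_equal(samplingRate(back), 256)
  expect_equal(channelLabels(back), channelLabels(rec))
  range <- 2 * apply(abs(channelData(rec)), 1, max)
  err <- abs(channelData(back) - channelData(rec))
  expect_true(all(err <= range / 2^15 + 1e-12))
})

test_that("constant-zero recording survives EDF round-trip exactly", {
  rec <- EEGRecording(matrix(0, nrow = 1, ncol = 512), fs = 256)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  expect_identical(unname(channelData(readEDF(path))[1, ]), rep(0, 512))
})

test_that("degenerate recordings are rejected", {
  expect_error(EEGRecording(matrix(c(1, NaN), nrow = 1), fs = 256),
               "non-finite")
  empty <- EEGRecording(matrix(numeric(0), nrow = 1, ncol = 0), fs = 256,
                        channelLabels = "A")
  expect_error(writeEDF(empty, tempfile()), "empty")
  expect_error(readEDF(tempfile("nope")), "not found")
})

test_that("corrupt EDF headers are reported as format errors", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", path)
  expect_error(readEDF(path))
})

test_that("non-EEG channels are dropped and duplicate labels deduplicated", {
  expect_identical(seizefeat:::dedupLabels(c("T8-P8", "C3-P3", "T8-P8")),
                   c("T8-P8-1", "C3-P3", "T8-P8-2"))
  rec <- EEGRecording(matrix(rnorm(4 * 512), nrow = 4), fs = 256,
                      channelLabels = c("FP1-F7", "-", "ECG", "T7-P7"))
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_identical(channelLabels(back), c("FP1-F7", "T7-P7"))
  # order preserved from header
  expect_equal(channelData(back)[2, ], channelData(rec)[4, ],
               tolerance = 1e-3)
})

test_that("csv annotation dialect parses and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("file_id,onset_s,end_s", "chb01_03.edf,2996,3036"), path)
  ann <- readAnnotations(path, "csv")
  e <- annotationEntries(ann)
  expect_equal(nrow(e), 1L)
  expect_equal(e$endS - e$onsetS, 40)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("file_id,onset_s,end_s", "a.edf,10,20", "b.edf,30,30"), bad)
  expect_error(readAnnotations(bad, "csv"), "line 2")
})

test_that("summary dialect keeps seizure-free files on the roster", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "File Name: chb01_01.edf",
    "Number of Seizures in File: 0",
    "",
    "File Name: chb01_03.edf",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 2996 seconds",
    "Seizure End Time: 3036 seconds"), path)
  ann <- readAnnotations(path, "chbmit_summary")
  expect_equal(nrow(annotationEntries(ann)), 1L)
  expect_setequal(annotationRoster(ann), c("chb01_01.edf", "chb01_03.edf"))
})

test_that("a seven-seizure patient summary yields seven entries", {
  # per-file seizure layout of the first benchmark patient
  files <- c("chb01_03" = "2996 3036", "chb01_04" = "1467 1494",
             "chb01_15" = "1732 1772", "chb01_16" = "1015 1066",
             "chb01_18" = "1720 1810", "chb01_21" = "327 420",
             "chb01_26" = "1862 1963")
  lines <- unlist(lapply(names(files), function(f) {
    se <- strsplit(files[[f]], " ")[[1]]
    c(paste0("File Name: ", f, ".edf"),
      "Number of Seizures in File: 1",
      paste0("Seizure Start Time: ", se[1], " seconds"),
      paste0("Seizure End Time: ", se[2], " seconds"))
  }))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)
  ann <- readAnnotations(path, "chbmit_summary")
  expect_equal(nrow(annotationEntries(ann)), 7L)
})

test_that("overlapping raw annotations merge without losing coverage", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    on <- runif(k, 0, 100)
    raw <- data.frame(fileId = "f.edf", onsetS = on,
                      endS = on + runif(k, 1, 30))
    ann <- AnnotationSet(raw)
    e <- annotationEntries(ann)
    # merged intervals are disjoint and sorted
    if (nrow(e) > 1) expect_true(all(e$onsetS[-1] >= e$endS[-nrow(e)]))
    # coverage oracle on a fine grid
    grid <- seq(0, 131, by = 0.01)
    rawCov <- Reduce(`|`, lapply(seq_len(k), function(i)
      grid >= raw$onsetS[i] & grid < raw$endS[i]))
    mrgCov <- Reduce(`|`, lapply(seq_len(nrow(e)), function(i)
      grid >= e$onsetS[i] & grid < e$endS[i]))
    expect_identical(mrgCov, rawCov)
  }
})

test_that("json annotations round-trip through the same schema", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(file_id = "x.edf", onset_s = 5,
                                  end_s = 25), path)
  ann <- readAnnotations(path, "json")
  expect_equal(annotationEntries(ann)$endS, 25)
})

test_that("detection tables write sorted, rounded, header-complete files", {
  ir <- IRanges::IRanges(start = c(3000 * 256 + 1), end = 3040 * 256)
  eset <- SeizureEpochSet(ir, nSamples = 3600 * 256, fs = 256)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDetections(list("chb01_03.edf" = eset), path)
  tab <- readDetections(path)
  expect_equal(tab$onset_s, 3000)
  expect_equal(tab$end_s, 3040)
  expect_equal(tab$file_id, "chb01_03.edf")

  # empty set -> header-only file
  writeDetections(list(), path)
  tab0 <- readDetections(path)
  expect_equal(nrow(tab0), 0L)
  expect_true(all(c("file_id", "onset_s", "end_s") %in% names(tab0)))

  # two epochs come back sorted by onset
  ir2 <- IRanges::IRanges(start = c(1, 2001), end = c(500, 2500))
  es2 <- SeizureEpochSet(ir2, nSamples = 4000, fs = 256)
  writeDetections(list("a.edf" = es2), path)
  tab2 <- readDetections(path)
  expect_equal(nrow(tab2), 2L)
  expect_true(!is.unsorted(tab2$onset_s))
})
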