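test_that("event matching follows the any-overlap rule", {
  truth <- AnnotationSet(data.frame(fileId = "chb01_03.edf", onsetS = 2996,
                                    endS = 3036),
                         roster = c("chb01_03.edf", "chb01_01.edf"))
  det <- data.frame(file_id = "chb01_03.edf", onset_s = 3000, end_s = 3040)
  expect_equal(matchEvents(det, truth),
               c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  none <- det[0, ]
  expect_equal(matchEvents(none, truth),
               c(tp = 0L, fp = 0L, fn = 1L, tn = 1L))

  # detection in an unannotated record: FP, and that record is not a TN
  stray <- data.frame(file_id = "chb01_01.edf", onset_s = 5, end_s = 70)
  expect_equal(matchEvents(stray, truth),
               c(tp = 0L, fp = 1L, fn = 1L, tn = 0L))

  unknown <- data.frame(file_id = "zz.edf", onset_s = 1, end_s = 2)
  expect_error(matchEvents(unknown, truth), "roster")
})

test_that("matching partitions events and detections exhaustively", {
  set.seed(55)
  for (rep in 1:25) {
    files <- paste0("f", 1:5, ".edf")
    nA <- sample(0:3, 5, replace = TRUE)
    ann <- do.call(rbind, lapply(1:5, function(i) {
      if (nA[i] == 0) return(NULL)
      on <- sort(runif(nA[i], 0, 500))
      data.frame(fileId = files[i], onsetS = on,
                 endS = on + runif(nA[i], 5, 40))
    }))
    truth <- if (is.null(ann)) AnnotationSet(roster = files)
             else AnnotationSet(ann, roster = files)
    annN <- annotationEntries(truth)
    nD <- sample(0:3, 5, replace = TRUE)
    det <- do.call(rbind, lapply(1:5, function(i) {
      if (nD[i] == 0) return(NULL)
      on <- runif(nD[i], 0, 550)
      data.frame(file_id = files[i], onset_s = on,
                 end_s = on + runif(nD[i], 5, 40))
    }))
    if (is.null(det))
      det <- data.frame(file_id = character(0), onset_s = numeric(0),
                        end_s = numeric(0))
    got <- matchEvents(det, truth)

    # brute-force oracle over the 4-way partition
    overlaps <- function(d, a) d["onset_s"] < a$endS & d["end_s"] > a$onsetS
    tp <- 0L; fn <- 0L
    for (i in seq_len(nrow(annN))) {
      a <- annN[i, ]
      dd <- det[det$file_id == a$fileId, , drop = FALSE]
      any_ov <- FALSE
      for (j in seq_len(nrow(dd)))
        if (dd$onset_s[j] < a$endS && dd$end_s[j] > a$onsetS) any_ov <- TRUE
      if (any_ov) tp <- tp + 1L else fn <- fn + 1L
    }
    fp <- 0L
    for (j in seq_len(nrow(det))) {
      aa <- annN[annN$fileId == det$file_id[j], , drop = FALSE]
      any_ov <- FALSE
      for (i in seq_len(nrow(aa)))
        if (det$onset_s[j] < aa$endS[i] && det$end_s[j] > aa$onsetS[i])
          any_ov <- TRUE
      if (!any_ov) fp <- fp + 1L
    }
    tn <- sum(!(files %in% annN$fileId) & !(files %in% det$file_id))
    expect_equal(got, c(tp = tp, fp = fp, fn = fn, tn = as.integer(tn)))
    expect_equal(got["tp"] + got["fn"], c(tp = nrow(annN)))
  }
})

test_that("sensitivity and specificity reproduce the worked percentages", {
  expect_equal(sensitivityPct(c(tp = 7, fp = 0, fn = 0, tn = 49)), 100)
  expect_equal(specificityPct(c(tp = 7, fp = 0, fn = 0, tn = 49)), 100)
  expect_equal(round(sensitivityPct(c(tp = 8, fp = 8, fn = 4, tn = 48)), 2),
               66.67)
  expect_equal(round(specificityPct(c(tp = 8, fp = 8, fn = 4, tn = 48)), 2),
               85.71)
  expect_equal(sensitivityPct(c(tp = 0, fp = 0, fn = 5, tn = 0)), 0)
  expect_equal(specificityPct(c(tp = 1, fp = 1, fn = 0, tn = 0)), 0)
  expect_true(is.na(sensitivityPct(c(tp = 0, fp = 3, fn = 0, tn = 2))))
  expect_true(is.na(specificityPct(c(tp = 1, fp = 0, fn = 1, tn = 0))))
})

test_that("precision, accuracy, F-measure and G-mean agree with the table", {
  cnt <- c(tp = 8, fp = 8, fn = 4, tn = 48)
  expect_equal(round(precisionPct(cnt), 2), 50.00)
  expect_equal(round(accuracyPct(cnt), 2), 82.35)
  expect_equal(round(fMeasurePct(cnt), 2), 57.14)
  expect_equal(round(gMeanPct(cnt), 2), 75.59)
  expect_equal(round(accuracyPct(c(tp = 31, fp = 6, fn = 9, tn = 61)), 2),
               85.98)
  perfect <- c(tp = 5, fp = 0, fn = 0, tn = 5)
  expect_equal(c(precisionPct(perfect), accuracyPct(perfect),
                 fMeasurePct(perfect), gMeanPct(perfect)),
               rep(100, 4))
})

test_that("metric identities hold for arbitrary counts", {
  set.seed(66)
  for (rep in 1:30) {
    cnt <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
             fn = sample(0:30, 1), tn = sample(0:60, 1))
    s <- sensitivityPct(cnt); sp <- specificityPct(cnt)
    p <- precisionPct(cnt)
    if (!is.na(s) && !is.na(sp)) {
      expect_equal(gMeanPct(cnt)^2, s * sp, tolerance = 1e-9)
      expect_lte(gMeanPct(cnt), max(s, sp) + 1e-9)
    }
    fm <- fMeasurePct(cnt)
    if (!is.na(fm)) expect_lte(fm, max(p, s) + 1e-9)
  }
})

test_that("false positives per hour is a plain rate", {
  expect_equal(fpPerHour(46, 980), 46 / 980, tolerance = 1e-12)
  expect_lt(abs(fpPerHour(46, 980) - 0.04), 0.01)  # "around 0.04"
  expect_equal(fpPerHour(0, 10), 0)
  expect_equal(fpPerHour(3, 1.5), 2)
  expect_error(fpPerHour(1, 0), "positive")
})

test_that("aggregation reproduces the benchmark footer averages", {
  m <- chbmitPublishedCounts("manual")
  reports <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    metricsReport(c(tp = m$tp[i], fp = m$fp[i], fn = m$fn[i],
                    tn = m$tn[i]))))
  agg <- aggregateMetrics(reports, hours = 980)
  expect_equal(round(agg$means[["sensitivity"]]), 93)
  expect_equal(round(agg$means[["specificity"]]), 96)
  expect_equal(agg$pooledCounts[["tp"]], 174)
  expect_equal(agg$pooledCounts[["fp"]], 46)

  single <- aggregateMetrics(reports[3, , drop = FALSE])
  expect_equal(single$means[["sensitivity"]], reports$sensitivity[3])
  expect_equal(unname(single$pooledCounts["tp"]), reports$tp[3])
})
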