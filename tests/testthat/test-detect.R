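test_that("peak finding measures half-prominence width correctly", {
  fs <- 256
  n <- 20 * fs
  # flat envelope: no peaks
  flat <- syntheticFeature(rep(0.2, n))
  expect_equal(nrow(findOnsetPeaks(flat)), 0L)

  # Gaussian bump, height 0.95, FWHM 1.0 s: one onset candidate of width ~1 s
  env <- gaussBump(n, fs, centerS = 10, height = 0.95, fwhmS = 1.0)
  pk <- findOnsetPeaks(syntheticFeature(env))
  pk <- pk[pk$onset, ]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$index / fs, 10, tolerance = 0.01)
  expect_equal(pk$widthS, 1.0, tolerance = 0.05)

  # two identical bumps 10 s apart: two candidates at the centers
  env2 <- gaussBump(n, fs, 5, 0.95, 1) + gaussBump(n, fs, 15, 0.95, 1)
  pk2 <- findOnsetPeaks(syntheticFeature(env2))
  pk2 <- pk2[pk2$onset, ]
  expect_equal(nrow(pk2), 2L)
  expect_equal(sort(pk2$index) / fs, c(5, 15), tolerance = 0.01)
})

test_that("plateau peaks resolve to the leftmost sample", {
  env <- c(rep(0, 100), rep(0.95, 50), rep(0, 100))
  pk <- findOnsetPeaks(syntheticFeature(env, fs = 256))
  expect_equal(pk$index, 101L)
})

test_that("the width rule keeps 0.4-1.8 s discontinuities only", {
  cand <- data.frame(index = 1:3, height = 0.95,
                     widthS = c(1.0, 0.3, 2.5), prominence = 0.9,
                     supportLo = 1L, supportHi = 2L, onset = TRUE)
  kept <- widthFilter(cand)
  expect_equal(kept$widthS, 1.0)
})

test_that("epoch power integrates squared in-band amplitude over time", {
  fs <- 256
  expect_equal(epochPower(rep(0, 1000), 1, 1000, fs), 0)
  expect_equal(epochPower(rep(1, 2 * fs), 1, 2 * fs, fs), 2)
  s <- sin(2 * pi * 4 * seq_len(2 * fs) / fs)
  expect_equal(epochPower(s, 1, 2 * fs, fs), 1, tolerance = 1e-3)
  expect_error(epochPower(rep(1, 100), 50, 20, fs), "interval")
})

test_that("epochs grow to the supra-threshold region and merge across gaps", {
  fs <- 256
  n <- 60 * fs
  env <- rep(0.01, n)
  env[(10 * fs):(50 * fs)] <- 0.3          # 40 s supra-threshold region
  env[(12 * fs)] <- 1                       # onset peak inside it
  cand <- data.frame(index = 12 * fs, height = 1, widthS = 1,
                     prominence = 0.99, supportLo = 12 * fs - 100,
                     supportHi = 12 * fs + 100, onset = TRUE)
  es <- growAndMerge(cand, syntheticFeature(env, fs))
  expect_equal(nEpochs(es), 1L)
  tab <- epochTable(es)
  expect_equal(tab$endS - tab$onsetS, 40, tolerance = 0.1)

  # two supra-threshold regions 0.5 s apart merge into one epoch
  env2 <- rep(0.01, n)
  env2[(10 * fs):(20 * fs)] <- 0.4
  env2[(20.5 * fs):(30 * fs)] <- 0.4
  env2[11 * fs] <- 1; env2[21 * fs] <- 1
  cand2 <- data.frame(index = c(11, 21) * fs, height = 1, widthS = 1,
                      prominence = 0.9, supportLo = c(11, 21) * fs - 50,
                      supportHi = c(11, 21) * fs + 50, onset = TRUE)
  expect_equal(nEpochs(growAndMerge(cand2, syntheticFeature(env2, fs))), 1L)

  # a supra-threshold region shorter than the minimum epoch is discarded
  env3 <- rep(0.01, n)
  env3[(10 * fs):(10.5 * fs)] <- 0.95
  cand3 <- data.frame(index = round(10.2 * fs), height = 0.95, widthS = 0.5,
                      prominence = 0.9, supportLo = 10 * fs,
                      supportHi = round(10.5 * fs), onset = TRUE)
  expect_equal(nEpochs(growAndMerge(cand3, syntheticFeature(env3, fs))), 0L)
})

test_that("detection finds an injected seizure and nothing else", {
  featZero <- syntheticFeature(rep(0, 30 * 256))
  expect_equal(nEpochs(detectSeizures(featZero)), 0L)

  sim <- simulateRecording(seed = 13, nChannels = 23, durationS = 180,
                           seizures = data.frame(onsetS = 60,
                                                 durationS = 60))
  det <- detectSeizures(buildFeatureSignal(sim$recording))
  expect_equal(nEpochs(det), 1L)
  tab <- epochTable(det)
  expect_lt(tab$onsetS, 120)
  expect_gt(tab$endS, 60)

  # an artefact-only record must stay empty (power/width rules)
  quiet <- simulateRecording(seed = 5, nChannels = 23, durationS = 180,
                             emgRatePerHour = 120)
  det0 <- detectSeizures(buildFeatureSignal(quiet$recording))
  expect_equal(nEpochs(det0), 0L)
})

test_that("masks and epoch sets are mutually inverse", {
  empty <- SeizureEpochSet(IRanges::IRanges(), nSamples = 100, fs = 256)
  expect_identical(epochsToMask(empty), integer(100))

  one <- SeizureEpochSet(IRanges::IRanges(11, 20), nSamples = 30, fs = 256)
  m <- epochsToMask(one)
  expect_equal(sum(m), 10L)
  expect_equal(which(m == 1L), 11:20)

  set.seed(31)
  for (rep in 1:20) {
    mask <- as.integer(runif(500) < 0.2)
    back <- epochsToMask(maskToEpochs(mask, 256))
    expect_identical(back, mask)
  }
})

test_that("manual picks become epochs under the duration rule", {
  fs <- 256
  feat <- syntheticFeature(rep(0.1, 450 * fs))
  es <- picksToEpochs(c(326, 421), feat)
  expect_equal(nEpochs(es), 1L)
  tab <- epochTable(es)
  expect_equal(tab$endS - tab$onsetS, 95, tolerance = 1 / fs)

  expect_equal(nEpochs(picksToEpochs(numeric(0), feat)), 0L)
  # picks shorter than the minimum discontinuity are not seizures
  expect_equal(nEpochs(picksToEpochs(c(10, 10.2), feat)), 0L)
  expect_error(picksToEpochs(c(1, 2, 3), feat), "pairs")
  expect_error(picksToEpochs(c(5, 3), feat), "ascending")
})

test_that("raising thresholds never yields more epochs", {
  for (i in c(1, 2, 4)) {
    sim <- simulateCorpusRecord(seed = 7, index = i, durationS = 300)
    feat <- buildFeatureSignal(sim$recording)
    nAmp <- vapply(c(0.075, 0.2, 0.4), function(a)
      nEpochs(detectSeizures(feat, DetectionParams(ampLower = a))),
      numeric(1))
    expect_true(all(diff(nAmp) <= 0))
    nPow <- vapply(c(200, 2000, 2e5), function(p)
      nEpochs(detectSeizures(feat, DetectionParams(powerThreshold = p))),
      numeric(1))
    expect_true(all(diff(nPow) <= 0))
  }
})

test_that("detection shifts with the signal and ignores global gain", {
  fs <- 256
  n <- 120 * fs
  base <- rep(0.02, n)
  env <- base
  env[(30 * fs):(70 * fs)] <- 0.3
  env <- env + gaussBump(n, fs, 30.2, 0.7, 0.8)
  env <- pmin(env / max(env), 1)
  feat <- syntheticFeature(env, fs)
  d0 <- epochTable(detectSeizures(feat))
  k <- 1000L
  envShift <- c(rep(0.02, k), env[1:(n - k)])
  dS <- epochTable(detectSeizures(syntheticFeature(envShift, fs)))
  expect_equal(dS$startSample, d0$startSample + k)
  expect_equal(dS$endSample, d0$endSample + k)

  # global gain on all channels: identical epochs once the power test is off
  sim <- simulateRecording(seed = 17, nChannels = 8, durationS = 120,
                           seizures = data.frame(onsetS = 40,
                                                 durationS = 40))
  scaled <- EEGRecording(5 * channelData(sim$recording), fs = fs,
                         channelLabels = channelLabels(sim$recording))
  pNoPow <- DetectionParams(powerThreshold = 0)
  e1 <- epochTable(detectSeizures(buildFeatureSignal(sim$recording), pNoPow))
  e2 <- epochTable(detectSeizures(buildFeatureSignal(scaled), pNoPow))
  expect_equal(e1$startSample, e2$startSample)
  expect_equal(e1$endSample, e2$endSample)
})
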