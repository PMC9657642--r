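# frequency-response oracle: squared magnitude of b/a at f Hz, evaluated
# directly on the unit circle (squared because zero-phase application runs
# the filter forward and backward)
freqGainSq <- function(b, a = 1, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- sum(b * z^(seq_along(b) - 1))
  den <- sum(a * z^(seq_along(a) - 1))
  Mod(num / den)^2
}

# amplitude of the f Hz component of x, least-squares fit over the middle
# half of the signal (avoids filter edge effects)
midAmp <- function(x, f, fs) {
  n <- length(x)
  idx <- seq.int(floor(n / 4) + 1, floor(3 * n / 4))
  t <- idx / fs
  co <- stats::coef(stats::lm(x[idx] ~ sin(2 * pi * f * t) +
                                cos(2 * pi * f * t)))
  unname(sqrt(co[2]^2 + co[3]^2))
}

# single- or multi-channel sinusoid recording
sineRecording <- function(f, fs = 256, durS = 10, nch = 1, amp = 1) {
  t <- seq_len(round(durS * fs)) / fs
  EEGRecording(matrix(rep(amp * sin(2 * pi * f * t), each = nch),
                      nrow = nch, byrow = FALSE), fs = fs)
}

# hand-built feature signal (envelope plus proportional unnormalized trace)
syntheticFeature <- function(envelope, fs = 256, scale = 100) {
  FeatureSignal(envelope = envelope, filteredAverage = envelope * scale,
                normFactor = scale, fs = fs)
}

# Gaussian bump with given FWHM (seconds) centered at centerS
gaussBump <- function(n, fs, centerS, height, fwhmS) {
  sigma <- fwhmS / (2 * sqrt(2 * log(2)))
  t <- seq_len(n) / fs
  height * exp(-(t - centerS)^2 / (2 * sigma^2))
}

# overlap bookkeeping for corpus scoring in tests
scoreRecord <- function(detTab, ann) {
  hit <- logical(nrow(ann))
  used <- if (nrow(detTab)) logical(nrow(detTab)) else logical(0)
  if (nrow(ann) && nrow(detTab)) for (r in seq_len(nrow(ann))) {
    ov <- detTab$onset_s < ann$endS[r] & detTab$end_s > ann$onsetS[r]
    hit[r] <- any(ov)
    used <- used | ov
  }
  c(tp = sum(hit), fn = sum(!hit), fp = sum(!used))
}
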