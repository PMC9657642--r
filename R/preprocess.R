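#' @include filters.R
NULL

#' Per-channel denoising cascade
#'
#' Three zero-phase stages applied to every channel before averaging:
#' \enumerate{
#'   \item `powerlineNotch()` — narrow biquad notches at the power-line
#'     fundamental and its harmonics below Nyquist (skippable);
#'   \item `lowpassFIR()` — 50th-order Hamming-windowed FIR low-pass at
#'     35 Hz, removing EMG and other high-frequency noise;
#'   \item `dcNotch()` — the first-order recursive DC-removal notch
#'     H(z) = (1 - z^-1)/(1 - lambda z^-1) with lambda = 0.9991, which has
#'     exactly zero gain at DC and removes per-channel offsets and drift so
#'     that channel averaging is meaningful.
#' }
#' All stages are applied forward-backward (zero phase) by default so epoch
#' timing is unbiased; `zeroPhase = FALSE` in the params gives the causal
#' single-pass variant.
#'
#' @param recording an [EEGRecording-class].
#' @param params a [PreprocessParams()] object.
#' @return a filtered [EEGRecording-class] of identical dimensions.
#' @examples
#' rec <- simulateRecording(seed = 1, durationS = 20, nChannels = 4)$recording
#' pre <- preprocessRecording(rec)
#' @export
preprocessRecording <- function(recording, params = PreprocessParams()) {
  methods::validObject(params)
  rec <- powerlineNotch(recording, params)
  rec <- lowpassFIR(rec, params)
  dcNotch(rec, params)
}

#' @rdname preprocessRecording
#' @export
lowpassFIR <- function(recording, params = PreprocessParams()) {
  fs <- samplingRate(recording)
  if (params@lpCutoff >= fs / 2)
    stop("low-pass cutoff must be below Nyquist")
  if (nSamples(recording) <= 3L * (params@lpOrder + 1L))
    stop("record too short for the requested filter order")
  b <- designLowpass(params@lpOrder, params@lpCutoff, fs)
  filterRecording(recording, b, 1, zeroPhase = params@zeroPhase)
}

#' @rdname preprocessRecording
#' @export
powerlineNotch <- function(recording, params = PreprocessParams()) {
  if (!params@powerlineEnabled) return(recording)
  fs <- samplingRate(recording)
  if (params@powerlineFreq >= fs / 2)
    stop("power-line frequency must be below Nyquist")
  nh <- if (is.na(params@powerlineHarmonics))
    floor((fs / 2 - 1e-9) / params@powerlineFreq)
  else min(params@powerlineHarmonics,
           floor((fs / 2 - 1e-9) / params@powerlineFreq))
  rec <- recording
  for (k in seq_len(max(nh, 1L))) {
    f0 <- k * params@powerlineFreq
    if (f0 >= fs / 2) break
    flt <- designNotch(f0, fs, params@notchQ)
    rec <- filterRecording(rec, flt$b, flt$a, zeroPhase = params@zeroPhase)
  }
  rec
}

#' @rdname preprocessRecording
#' @export
dcNotch <- function(recording, params = PreprocessParams()) {
  if (params@dcLambda <= 0 || params@dcLambda >= 1)
    stop("dcLambda must lie strictly in (0, 1)")
  flt <- designDCNotch(params@dcLambda)
  filterRecording(recording, flt$b, flt$a, zeroPhase = params@zeroPhase)
}
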