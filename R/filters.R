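#' @include AllClasses.R
NULL

# Direct-form IIR/FIR filtering with zero initial conditions: moving-average
# part as a causal convolution, recursive part via stats::filter (both C).
applyFilter <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  if (nb > 1L) {
    y <- stats::filter(c(numeric(nb - 1L), x), b, sides = 1)
    y <- as.numeric(y)[nb:(n + nb - 1L)]
  } else {
    y <- b[1] * x
  }
  if (length(a) > 1L) {
    if (a[1] != 1) { b <- b / a[1]; y <- y / a[1]; a <- a / a[1] }
    y <- as.numeric(stats::filter(y, -a[-1], method = "recursive"))
  }
  y
}

# Effective impulse-response length: for FIR this is the coefficient count;
# for IIR, the time for the slowest pole to decay to 1e-6 (capped so short
# test signals stay usable).
effectiveLength <- function(b, a) {
  nfir <- max(length(b), length(a))
  if (length(a) > 1L) {
    p <- tryCatch(Mod(polyroot(rev(a))), error = function(e) numeric(0))
    p <- p[p < 1 & p > 0]
    if (length(p)) {
      settle <- ceiling(log(1e-6) / log(max(p)))
      return(max(nfir, min(settle, 30000L)))
    }
  }
  nfir
}

#' Zero-phase (forward-backward) filtering with reflected edge padding
#'
#' Applies the rational filter b/a forward and then backward so the net
#' phase response is zero and the magnitude response is squared. Edge
#' transients are suppressed by odd-reflection padding: the signal is
#' continued at both ends by its point reflection about the end sample,
#' using 3x the effective filter length (for recursive filters, the
#' settling time of the slowest pole).
#'
#' @param x numeric signal.
#' @param b,a filter numerator and denominator coefficients (a = 1 for FIR).
#' @param zeroPhase if FALSE, a single causal forward pass is applied
#'   (no padding), for real-time style processing.
#' @return filtered signal, same length as `x`.
#' @examples
#' b <- signal::fir1(50, 35 / 128)
#' y <- zeroPhaseFilter(sin(2 * pi * 10 * (0:999) / 256), b)
#' @export
zeroPhaseFilter <- function(x, b, a = 1, zeroPhase = TRUE) {
  if (!zeroPhase) return(applyFilter(b, a, x))
  n <- length(x)
  npad <- min(n - 1L, 3L * effectiveLength(b, a))
  if (npad < 1L) stop("signal too short for zero-phase filtering")
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- applyFilter(b, a, c(pre, x, post))
  y <- rev(applyFilter(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

# Hamming-windowed FIR designs (via signal::fir1).
designLowpass <- function(order, cutoffHz, fs) {
  stopifnot(cutoffHz > 0, cutoffHz < fs / 2)
  as.numeric(signal::fir1(order, cutoffHz / (fs / 2), type = "low"))
}

designHighpass <- function(order, cutoffHz, fs) {
  stopifnot(cutoffHz > 0, cutoffHz < fs / 2)
  if (order %% 2L == 1L) order <- order + 1L  # high-pass needs even order
  as.numeric(signal::fir1(order, cutoffHz / (fs / 2), type = "high"))
}

# Constrained biquad notch (unit gain at DC and Nyquist, zero at f0).
designNotch <- function(f0, fs, Q) {
  stopifnot(f0 > 0, f0 < fs / 2, Q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# First-order recursive DC-removal notch H(z) = (1 - z^-1)/(1 - lambda z^-1).
designDCNotch <- function(lambda) {
  stopifnot(lambda > 0, lambda < 1)
  list(b = c(1, -1), a = c(1, -lambda))
}

# Apply a filter to every channel of a recording, preserving metadata.
filterRecording <- function(recording, b, a = 1, zeroPhase = TRUE) {
  dat <- channelData(recording)
  out <- t(apply(dat, 1L, zeroPhaseFilter, b = b, a = a,
                 zeroPhase = zeroPhase))
  if (nrow(dat) == 1L) out <- matrix(out, nrow = 1L)
  EEGRecording(out, fs = samplingRate(recording),
               channelLabels = channelLabels(recording),
               startTime = recording@startTime, source = recordSource(recording))
}
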