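#' Synthesize the linear-FM chirp excitation
#'
#' Linear frequency sweep from sweepLow to sweepHigh over chirpDuration,
#' amplitude-tapered with a Tukey window to suppress spectral ripple, unit
#' peak amplitude. With sweepLow == sweepHigh the waveform degenerates to a
#' windowed tone burst.
#'
#' @param params an \linkS4class{AcquisitionParams}; samplingRate must exceed
#'   twice sweepHigh.
#' @param tukeyAlpha taper fraction of the Tukey window (0 = rectangular).
#' @return numeric waveform sampled at params@samplingRate, with attribute
#'   \code{fs} (MHz).
#' @export
synthesizeChirp <- function(params, tukeyAlpha = 0.25) {
  fs <- params@samplingRate
  if (fs <= 2 * params@sweepHigh)
    stop(sprintf(
      "samplingRate %.3g MHz violates the Nyquist bound: need > %.3g MHz",
      fs, 2 * params@sweepHigh))
  n <- max(2L, round(params@chirpDuration * fs))
  t <- (seq_len(n) - 1) / fs
  k <- (params@sweepHigh - params@sweepLow) / params@chirpDuration # MHz/us
  phase <- 2 * pi * (params@sweepLow * t + k / 2 * t^2)
  w <- cos(phase) * .tukeyWindow(n, tukeyAlpha)
  w <- w / max(abs(w))
  attr(w, "fs") <- fs
  w
}

#' Conventional short excitation pulse
#'
#' A windowed sinusoid of a given number of cycles at the centre frequency,
#' unit peak amplitude; the single-angle short-pulse reference against which
#' the chirp's SNR advantage is measured.
#'
#' @param params an \linkS4class{AcquisitionParams}.
#' @param cycles number of cycles (default 1).
#' @return numeric waveform with attribute \code{fs}.
#' @export
shortPulse <- function(params, cycles = 1) {
  fs <- params@samplingRate
  f0 <- params@centerFrequency
  if (fs <= 2 * f0)
    stop(sprintf(
      "samplingRate %.3g MHz violates the Nyquist bound: need > %.3g MHz",
      fs, 2 * f0))
  n <- max(2L, round(cycles / f0 * fs))
  t <- (seq_len(n) - 1) / fs
  w <- sin(2 * pi * f0 * t)
  m <- max(abs(w))
  if (m > 0) w <- w / m
  attr(w, "fs") <- fs
  w
}

.tukeyWindow <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  alpha <- min(alpha, 1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}
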