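#' Construct acquisition parameters
#'
#' Defaults describe the low-frequency compounded-chirp sequence used
#' throughout the package: a 128-element, 0.3 mm pitch linear array at 2 MHz
#' centre frequency, a 1.3--2.7 MHz linear-FM chirp of 6 us, five steering
#' angles (-6, -3, 0, 3, 6 degrees), a compounded frame rate of 1500 Hz and
#' 20 MHz sampling.
#'
#' @param nChannels number of array elements.
#' @param pitch element pitch (mm).
#' @param centerFrequency centre frequency (MHz).
#' @param sweepLow,sweepHigh chirp band edges (MHz).
#' @param chirpDuration chirp duration (us).
#' @param angles steering angles (degrees).
#' @param prf compounded frame rate (Hz).
#' @param nFrames number of compounded frames.
#' @param samplingRate RF sampling rate (MHz).
#' @param speedOfSound speed of sound (m/s).
#' @param noiseSigma channel-noise standard deviation (linear amplitude).
#' @param attenuation bulk attenuation, dB/(cm*MHz).
#' @param skullAttenuationDb extra global (skull) attenuation, dB.
#' @param channelJitterSd per-channel phase jitter (radians at the centre
#'   frequency).
#' @param seed integer seed recorded with the acquisition.
#' @return an \linkS4class{AcquisitionParams} object.
#' @export
acquisitionParams <- function(nChannels = 128L, pitch = 0.3,
                              centerFrequency = 2.0, sweepLow = 1.3,
                              sweepHigh = 2.7, chirpDuration = 6,
                              angles = c(-6, -3, 0, 3, 6), prf = 1500,
                              nFrames = 600L, samplingRate = 20,
                              speedOfSound = 1540, noiseSigma = 0.01,
                              attenuation = 0.5, skullAttenuationDb = 0,
                              channelJitterSd = 0, seed = 1L) {
  new("AcquisitionParams", nChannels = as.integer(nChannels), pitch = pitch,
      centerFrequency = centerFrequency, sweepLow = sweepLow,
      sweepHigh = sweepHigh, chirpDuration = chirpDuration, angles = angles,
      prf = prf, nFrames = as.integer(nFrames), samplingRate = samplingRate,
      speedOfSound = speedOfSound, noiseSigma = noiseSigma,
      attenuation = attenuation, skullAttenuationDb = skullAttenuationDb,
      channelJitterSd = channelJitterSd, seed = as.integer(seed))
}

#' Named acquisition presets
#'
#' \describe{
#'   \item{paper_sim}{full simulation protocol: 128 channels, 5 chirp angles,
#'     PRF 1500 Hz, 600 frames.}
#'   \item{desk}{reduced protocol for desk-scale runs: 32 channels,
#'     150 frames, otherwise identical.}
#'   \item{in_vivo}{transcranial protocol: 128 channels, frame rate 300 Hz,
#'     4 s of data, i.e. 1200 frames.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to \code{\link{acquisitionParams}}.
#' @export
acquisitionPreset <- function(name = c("paper_sim", "desk", "in_vivo"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    paper_sim = list(),
    desk = list(nChannels = 32L, nFrames = 150L),
    in_vivo = list(prf = 300, nFrames = framesForDuration(300, 4))
  )
  do.call(acquisitionParams, utils::modifyList(base, list(...)))
}

#' Number of compounded frames in an acquisition of a given duration
#'
#' @param prf compounded frame rate (Hz).
#' @param durationS acquisition duration (s).
#' @return integer frame count.
#' @examples framesForDuration(300, 4)  # 1200
#' @export
framesForDuration <- function(prf, durationS) {
  stopifnot(prf > 0, durationS > 0)
  as.integer(round(prf * durationS))
}

#' Lateral element-centre positions of the array (mm), centred on x = 0
#' @param params an \linkS4class{AcquisitionParams}.
#' @export
elementPositions <- function(params) {
  n <- params@nChannels
  (seq_len(n) - 1 - (n - 1) / 2) * params@pitch
}

# speed of sound in mm/us
.cMmUs <- function(params) params@speedOfSound / 1000

# wavelength at the centre frequency (mm)
.lambdaMm <- function(params) .cMmUs(params) / params@centerFrequency

# transmit time reference so plane-wave delays stay positive over the aperture
.t0Us <- function(params, angleDeg) {
  abs(sin(angleDeg * pi / 180)) * max(abs(elementPositions(params))) /
    .cMmUs(params)
}

# per-channel delay jitter (us) equivalent to the configured phase jitter
.channelJitterUs <- function(params) {
  if (params@channelJitterSd <= 0) return(rep(0, params@nChannels))
  stats::rnorm(params@nChannels, 0,
               params@channelJitterSd / (2 * pi * params@centerFrequency))
}
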