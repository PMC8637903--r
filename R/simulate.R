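# Point-scatterer RF synthesis: far-field delay model with 1/r spreading and
# bulk attenuation at the centre frequency; a deliberately simple stand-in
# for a full acoustic field simulation that preserves the geometry, timing
# and SNR structure every downstream stage depends on.

# record length (samples) covering two-way travel to zMax across the aperture
.recordLength <- function(params, zMax, waveformLength) {
  c0 <- .cMmUs(params)
  ap <- max(abs(elementPositions(params)))
  xmax <- ap + abs(zMax) * tan(max(abs(params@angles)) * pi / 180)
  t0 <- max(vapply(params@angles, function(a) .t0Us(params, a), numeric(1)))
  tmax <- t0 + (zMax + sqrt(zMax^2 + (ap + xmax)^2)) / c0
  as.integer(ceiling(tmax * params@samplingRate) + waveformLength + 8)
}

#' Simulate one steered-transmit channel-RF frame
#'
#' Each bubble contributes the excitation waveform delayed by the plane-wave
#' transmit path plus the receive element path, scaled by its amplitude, 1/r
#' spherical spreading and bulk attenuation at the centre frequency; white
#' Gaussian noise of standard deviation params@noiseSigma is added.
#'
#' @param bubbles data.frame with columns x, z, amplitude (and optionally
#'   alive); bubbles at z <= 0 (behind the array) are excluded with a warning.
#' @param elementPositions lateral element coordinates (mm).
#' @param angle steering angle (degrees), |angle| < 90.
#' @param waveform excitation waveform (from \code{\link{synthesizeChirp}} or
#'   \code{\link{shortPulse}}).
#' @param params \linkS4class{AcquisitionParams}.
#' @param nTime record length in samples; computed from the bubble depths if
#'   omitted.
#' @param channelDelaysUs optional per-channel delay jitter (us).
#' @param addNoise add channel noise (default TRUE).
#' @return nTime x nChannels numeric matrix.
#' @export
simulateRFFrame <- function(bubbles, elementPositions, angle, waveform,
                            params, nTime = NULL, channelDelaysUs = NULL,
                            addNoise = TRUE) {
  if (abs(angle) >= 90) stop("|angle| must be < 90 degrees")
  if (!is.null(bubbles$alive)) bubbles <- bubbles[bubbles$alive, , drop = FALSE]
  behind <- bubbles$z <= 0
  if (any(behind)) {
    warning(sprintf("%d bubble(s) behind the array (z <= 0) excluded",
                    sum(behind)))
    bubbles <- bubbles[!behind, , drop = FALSE]
  }
  if (is.null(nTime))
    nTime <- .recordLength(params, max(c(bubbles$z, 1)), length(waveform))
  if (is.null(channelDelaysUs)) channelDelaysUs <- rep(0, length(elementPositions))
  rf <- simulateEchoesCpp(
    as.numeric(bubbles$x), as.numeric(bubbles$z), as.numeric(bubbles$amplitude),
    elementPositions, angle * pi / 180, as.numeric(waveform), .cMmUs(params),
    params@samplingRate, as.integer(nTime), params@attenuation,
    params@centerFrequency, params@skullAttenuationDb, .t0Us(params, angle),
    channelDelaysUs)
  if (addNoise && params@noiseSigma > 0)
    rf <- rf + matrix(stats::rnorm(length(rf), 0, params@noiseSigma),
                      nrow(rf), ncol(rf))
  rf
}

# Shared acquisition loop. Seeds bubbles and optional static background
# scatterers, then per compounded frame: records ground truth, emits every
# steering angle against the same bubble configuration (static echoes are
# precomputed once and reused -- they are time-invariant), then advances the
# bubbles by 1/prf and applies optional destruction/replenishment.
# callback(frame, rfPerAngle, truth) consumes each frame.
.acquisitionLoop <- function(phantom, params, concentration, seed,
                             nStatic = 0, staticAmplitude = 10,
                             lifetimeFrames = Inf, radialDiffusion = 0,
                             flowProfile = c("plug", "parabolic"),
                             waveform = NULL, callback) {
  flowProfile <- match.arg(flowProfile)
  bubbles <- seedBubbles(phantom, concentration, seed = seed,
                         flowProfile = flowProfile)
  # RNG continues deterministically from the seeding stream
  if (is.null(waveform)) waveform <- synthesizeChirp(params)
  elems <- elementPositions(params)
  chDelays <- .channelJitterUs(params)
  fe <- phantom@fieldExtent
  nTime <- .recordLength(params, fe[4], length(waveform))
  staticRF <- NULL
  if (nStatic > 0) {
    sc <- data.frame(
      x = stats::runif(nStatic, fe[1], fe[2]),
      z = stats::runif(nStatic, max(fe[3], 1), fe[4]),
      amplitude = staticAmplitude * exp(stats::rnorm(nStatic, 0, 0.3)))
    staticRF <- lapply(params@angles, function(a)
      simulateRFFrame(sc, elems, a, waveform, params, nTime = nTime,
                      channelDelaysUs = chDelays, addNoise = FALSE))
  }
  dtFrame <- 1 / params@prf
  for (f in seq_len(params@nFrames)) {
    truth <- bubbles[bubbles$alive, c("id", "x", "z")]
    rownames(truth) <- NULL
    rfPerAngle <- vector("list", length(params@angles))
    for (ai in seq_along(params@angles)) {
      rf <- simulateRFFrame(bubbles, elems, params@angles[ai], waveform,
                            params, nTime = nTime,
                            channelDelaysUs = chDelays, addNoise = FALSE)
      if (!is.null(staticRF)) rf <- rf + staticRF[[ai]]
      if (params@noiseSigma > 0)
        rf <- rf + matrix(stats::rnorm(length(rf), 0, params@noiseSigma),
                          nrow(rf), ncol(rf))
      rfPerAngle[[ai]] <- rf
    }
    callback(f, rfPerAngle, truth)
    if (f < params@nFrames) {
      bubbles <- advanceBubbles(bubbles, phantom, dtFrame,
                                radialDiffusion = radialDiffusion)
      bubbles <- .respawnBubbles(bubbles, phantom, lifetimeFrames)
    }
  }
  invisible(list(waveform = waveform, nTime = nTime,
                 elementPositions = elems))
}

#' Simulate a full multi-frame, multi-angle chirp acquisition
#'
#' Loops nFrames compounded frames; within each frame every steering angle is
#' emitted against the same bubble configuration, then the bubbles advance by
#' 1/prf (with recycling at segment entrances). Ground-truth bubble positions
#' are recorded per frame. Fully reproducible given the seed.
#'
#' For long acquisitions the in-memory 4-D array becomes large; use
#' \code{\link{simulateAndBeamform}} to stream frames through beamforming
#' instead.
#'
#' @param phantom a \linkS4class{VesselPhantom}.
#' @param params \linkS4class{AcquisitionParams}.
#' @param concentration bubbles per mm of vessel length.
#' @param seed integer RNG seed.
#' @param nStatic number of static background scatterers (tissue/skull
#'   clutter for the spatiotemporal filter); 0 disables them.
#' @param staticAmplitude amplitude of static scatterers relative to bubbles.
#' @param lifetimeFrames mean bubble lifetime in frames before destruction
#'   and replenishment at a random vessel position; Inf (default) disables.
#' @param radialDiffusion per-frame radial dispersion (mm), see
#'   \code{\link{advanceBubbles}}.
#' @param flowProfile "plug" or "parabolic".
#' @return an \linkS4class{RFSequence}.
#' @export
simulateAcquisition <- function(phantom, params, concentration, seed = 1L,
                                nStatic = 0, staticAmplitude = 10,
                                lifetimeFrames = Inf, radialDiffusion = 0,
                                flowProfile = c("plug", "parabolic")) {
  flowProfile <- match.arg(flowProfile)
  waveform <- synthesizeChirp(params)
  nTime <- .recordLength(params, phantom@fieldExtent[4], length(waveform))
  nAngles <- length(params@angles)
  total <- as.numeric(params@nFrames) * nAngles * nTime * params@nChannels
  if (total > 2.5e8)
    stop("acquisition too large to hold in memory; use simulateAndBeamform()")
  samples <- array(0, dim = c(params@nFrames, nAngles, nTime,
                              params@nChannels))
  truthTracks <- vector("list", params@nFrames)
  .acquisitionLoop(
    phantom, params, concentration, seed, nStatic, staticAmplitude,
    lifetimeFrames, radialDiffusion, flowProfile, waveform,
    callback = function(f, rfPerAngle, truth) {
      for (ai in seq_len(nAngles)) samples[f, ai, , ] <<- rfPerAngle[[ai]]
      truthTracks[[f]] <<- truth
    })
  new("RFSequence", samples = samples, params = params,
      elementPositions = elementPositions(params), truthTracks = truthTracks)
}

#' Simulate and beamform an acquisition frame-by-frame
#'
#' Streams the acquisition through pulse compression, delay-and-sum and
#' coherent compounding without materializing the 4-D RF array; this is the
#' scalable path used by \code{\link{runPipeline}}.
#'
#' @inheritParams simulateAcquisition
#' @param grid \linkS4class{ImageGrid} to beamform onto; default from
#'   \code{\link{defaultImageGrid}} over the phantom extent.
#' @param fNumber receive f-number (default 1.5).
#' @param compressionWeighting range-sidelobe control of the compression
#'   filter, see \code{\link{pulseCompress}}; the equalized "hamming"
#'   filter is the default imaging chain.
#' @return list with elements \code{stack} (complex \linkS4class{ImageStack}
#'   of compounded frames) and \code{truthTracks}.
#' @export
simulateAndBeamform <- function(phantom, params, concentration, seed = 1L,
                                grid = NULL, fNumber = 1.5, nStatic = 0,
                                staticAmplitude = 10, lifetimeFrames = Inf,
                                radialDiffusion = 0,
                                flowProfile = c("plug", "parabolic"),
                                compressionWeighting = "hamming") {
  flowProfile <- match.arg(flowProfile)
  if (is.null(grid)) grid <- defaultImageGrid(params, phantom@fieldExtent)
  waveform <- synthesizeChirp(params)
  nz <- length(grid@z); nx <- length(grid@x)
  frames <- array(complex(real = 0), dim = c(nz, nx, params@nFrames))
  truthTracks <- vector("list", params@nFrames)
  elems <- elementPositions(params)
  .acquisitionLoop(
    phantom, params, concentration, seed, nStatic, staticAmplitude,
    lifetimeFrames, radialDiffusion, flowProfile, waveform,
    callback = function(f, rfPerAngle, truth) {
      imgs <- lapply(seq_along(params@angles), function(ai) {
        ca <- .compressAnalytic(rfPerAngle[[ai]], waveform,
                                weighting = compressionWeighting)
        dasBeamform(ca, elems, params@angles[ai], grid,
                    params, fNumber = fNumber)
      })
      frames[, , f] <<- coherentCompound(imgs)
      truthTracks[[f]] <<- truth
    })
  list(stack = new("ImageStack", frames = frames, grid = grid,
                   frameRate = params@prf),
       truthTracks = truthTracks)
}
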