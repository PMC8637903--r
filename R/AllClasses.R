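#' @import methods
NULL

#' Acquisition parameters for a compounded chirp plane-wave sequence
#'
#' Describes a linear-array plane-wave acquisition: array geometry, linear-FM
#' chirp excitation, steering angles, frame rate and noise/attenuation model.
#' Lengths are millimetres, frequencies MHz, durations microseconds, the
#' frame rate (PRF of compounded frames) Hz and the speed of sound m/s.
#'
#' @slot nChannels number of array elements.
#' @slot pitch element pitch (mm).
#' @slot centerFrequency array centre frequency (MHz).
#' @slot sweepLow,sweepHigh chirp sweep band edges (MHz).
#' @slot chirpDuration chirp duration (us).
#' @slot angles plane-wave steering angles (degrees).
#' @slot prf compounded frame rate (Hz).
#' @slot nFrames number of compounded frames.
#' @slot samplingRate RF sampling rate (MHz).
#' @slot speedOfSound speed of sound (m/s).
#' @slot noiseSigma additive white Gaussian channel-noise standard deviation
#'   (linear amplitude).
#' @slot attenuation bulk attenuation coefficient, dB/(cm*MHz), applied at
#'   the centre frequency over the round-trip path.
#' @slot skullAttenuationDb extra global attenuation (dB) standing in for the
#'   skull; 0 disables it.
#' @slot channelJitterSd per-channel random phase jitter (radians at the
#'   centre frequency), a crude aberration stand-in; 0 disables it.
#' @slot seed integer RNG seed recorded with the acquisition.
#' @export
setClass("AcquisitionParams",
  slots = c(
    nChannels = "integer", pitch = "numeric", centerFrequency = "numeric",
    sweepLow = "numeric", sweepHigh = "numeric", chirpDuration = "numeric",
    angles = "numeric", prf = "numeric", nFrames = "integer",
    samplingRate = "numeric", speedOfSound = "numeric",
    noiseSigma = "numeric", attenuation = "numeric",
    skullAttenuationDb = "numeric", channelJitterSd = "numeric",
    seed = "integer"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@pitch <= 0) msg <- c(msg, "pitch must be > 0")
  if (object@sweepLow > object@sweepHigh)
    msg <- c(msg, "sweepLow must be <= sweepHigh")
  if (length(object@angles) == 0) msg <- c(msg, "angles must be non-empty")
  if (any(abs(object@angles) >= 90)) msg <- c(msg, "|angles| must be < 90")
  for (f in c("centerFrequency", "sweepLow", "sweepHigh", "chirpDuration",
              "prf", "samplingRate", "speedOfSound")) {
    if (slot(object, f) <= 0) msg <- c(msg, paste(f, "must be > 0"))
  }
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@attenuation < 0) msg <- c(msg, "attenuation must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single vessel segment: centerline, lumen diameter, flow
#'
#' @slot centerline n x 2 matrix of (lateral x, depth z) points in mm,
#'   ordered along the vessel; at least two points.
#' @slot diameter lumen diameter (mm).
#' @slot flowSpeed flow speed along the centerline (mm/s).
#' @slot flowDirection +1 to flow from first to last centerline point,
#'   -1 for the reverse.
#' @export
setClass("VesselSegment",
  slots = c(centerline = "matrix", diameter = "numeric",
            flowSpeed = "numeric", flowDirection = "numeric")
)

setValidity("VesselSegment", function(object) {
  msg <- character()
  cl <- object@centerline
  if (!is.numeric(cl) || ncol(cl) != 2 || nrow(cl) < 2)
    msg <- c(msg, "centerline must be a numeric matrix with >= 2 rows and 2 columns")
  if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
  if (object@flowSpeed < 0) msg <- c(msg, "flowSpeed must be >= 0")
  if (!object@flowDirection %in% c(-1, 1))
    msg <- c(msg, "flowDirection must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Vessel phantom: segments plus a rendered ground-truth occupancy map
#'
#' The truth map is a binary image on the super-resolution grid (cell size
#' \code{srSpacing} mm, default 10 um): 1 exactly where a cell centre lies
#' inside some segment's lumen.
#'
#' @slot segments list of \linkS4class{VesselSegment}.
#' @slot fieldExtent numeric(4): (xmin, xmax, zmin, zmax) mm.
#' @slot srSpacing super-resolution cell size (mm).
#' @slot truthMap nz x nx binary matrix (rows = depth cells).
#' @slot truthX,truthZ cell-centre coordinates (mm).
#' @export
setClass("VesselPhantom",
  slots = c(segments = "list", fieldExtent = "numeric", srSpacing = "numeric",
            truthMap = "matrix", truthX = "numeric", truthZ = "numeric")
)

setValidity("VesselPhantom", function(object) {
  msg <- character()
  if (length(object@fieldExtent) != 4) msg <- c(msg, "fieldExtent must have 4 values")
  if (length(object@segments) == 0) msg <- c(msg, "phantom needs at least one segment")
  if (object@srSpacing <= 0) msg <- c(msg, "srSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' Multi-frame, multi-angle channel RF data
#'
#' @slot samples 4-D array indexed [frame, angle, time, channel].
#' @slot params the \linkS4class{AcquisitionParams} used.
#' @slot elementPositions lateral element coordinates (mm).
#' @slot truthTracks list (one per frame) of data.frames with ground-truth
#'   bubble id, x, z; evaluation only.
#' @export
setClass("RFSequence",
  slots = c(samples = "array", params = "AcquisitionParams",
            elementPositions = "numeric", truthTracks = "list")
)

setValidity("RFSequence", function(object) {
  d <- dim(object@samples)
  p <- object@params
  msg <- character()
  if (length(d) != 4) msg <- c(msg, "samples must be a 4-D array")
  else {
    if (d[1] != p@nFrames) msg <- c(msg, "frame dimension != nFrames")
    if (d[2] != length(p@angles)) msg <- c(msg, "angle dimension != length(angles)")
    if (d[4] != p@nChannels) msg <- c(msg, "channel dimension != nChannels")
  }
  if (length(object@truthTracks) != p@nFrames)
    msg <- c(msg, "truthTracks length != nFrames")
  if (length(object@elementPositions) != p@nChannels)
    msg <- c(msg, "elementPositions length != nChannels")
  if (length(msg)) msg else TRUE
})

#' Regular beamforming pixel grid
#'
#' @slot x,z strictly increasing, uniformly spaced pixel-centre coordinates (mm).
#' @export
setClass("ImageGrid", slots = c(x = "numeric", z = "numeric"))

setValidity("ImageGrid", function(object) {
  ok <- function(v) {
    length(v) >= 2 && all(diff(v) > 0) &&
      diff(range(diff(v))) < 1e-9 * max(diff(v))
  }
  msg <- character()
  if (!ok(object@x)) msg <- c(msg, "x must be increasing and uniformly spaced")
  if (!ok(object@z)) msg <- c(msg, "z must be increasing and uniformly spaced")
  if (length(msg)) msg else TRUE
})

#' Beamformed image stack
#'
#' @slot frames nz x nx x nFrames array, complex (beamformed analytic signal)
#'   or real (envelope).
#' @slot grid the shared \linkS4class{ImageGrid}.
#' @slot frameRate compounded frame rate (Hz).
#' @export
setClass("ImageStack",
  slots = c(frames = "array", grid = "ImageGrid", frameRate = "numeric")
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3) msg <- c(msg, "frames must be nz x nx x nFrames")
  else if (d[1] != length(object@grid@z) || d[2] != length(object@grid@x))
    msg <- c(msg, "frame dimensions do not match the grid")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Singular-component band removed by the spatiotemporal clutter filter
#'
#' @slot lowRankCut number of leading (tissue/clutter) singular components
#'   discarded.
#' @slot highRankCut number of trailing (noise) components discarded; 0 keeps
#'   them all.
#' @export
setClass("FilterBand",
  slots = c(lowRankCut = "integer", highRankCut = "integer"))

setValidity("FilterBand", function(object) {
  msg <- character()
  if (object@lowRankCut < 0L) msg <- c(msg, "lowRankCut must be >= 0")
  if (object@highRankCut < 0L) msg <- c(msg, "highRankCut must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Constant-velocity motion / association model for microbubble tracking
#'
#' @slot processNoiseSigma per-frame position diffusion (mm).
#' @slot measurementNoiseSigma localization noise (mm).
#' @slot maxSpeed hard speed gate (mm/s).
#' @slot pDetect per-frame detection probability of a live bubble.
#' @slot clutterRate expected false detections per frame.
#' @slot birthRate expected new tracks per frame (prior).
#' @slot fieldArea imaging-field area (mm^2) giving the spatial density of
#'   clutter and track births.
#' @slot maxGap maximum number of consecutive missed frames inside a track.
#' @slot minTrackLength minimum detections per reported track.
#' @slot frameRate compounded frame rate (Hz).
#' @slot velocityKappa velocity-diffusion fraction of the Kalman model.
#' @export
setClass("MotionModel",
  slots = c(processNoiseSigma = "numeric", measurementNoiseSigma = "numeric",
            maxSpeed = "numeric", pDetect = "numeric", clutterRate = "numeric",
            birthRate = "numeric", fieldArea = "numeric", maxGap = "integer",
            minTrackLength = "integer", frameRate = "numeric",
            velocityKappa = "numeric")
)

setValidity("MotionModel", function(object) {
  msg <- character()
  if (object@processNoiseSigma <= 0) msg <- c(msg, "processNoiseSigma must be > 0")
  if (object@measurementNoiseSigma <= 0)
    msg <- c(msg, "measurementNoiseSigma must be > 0")
  if (object@maxSpeed <= 0) msg <- c(msg, "maxSpeed must be > 0")
  if (object@pDetect <= 0 || object@pDetect > 1)
    msg <- c(msg, "pDetect must be in (0, 1]")
  if (object@clutterRate < 0) msg <- c(msg, "clutterRate must be >= 0")
  if (object@birthRate <= 0) msg <- c(msg, "birthRate must be > 0")
  if (object@fieldArea <= 0) msg <- c(msg, "fieldArea must be > 0")
  if (object@maxGap < 0L) msg <- c(msg, "maxGap must be >= 0")
  if (object@minTrackLength < 2L) msg <- c(msg, "minTrackLength must be >= 2")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' A set of microbubble trajectories
#'
#' Each track is a data.frame with columns \code{frame}, \code{x}, \code{z},
#' \code{intensity}, \code{vx}, \code{vz} (velocities mm/s), frames strictly
#' increasing.
#'
#' @slot tracks list of track data.frames.
#' @slot frameRate frame rate (Hz) the frame indices refer to.
#' @export
setClass("TrackSet", slots = c(tracks = "list", frameRate = "numeric"))

setValidity("TrackSet", function(object) {
  for (tr in object@tracks) {
    if (!is.data.frame(tr) || !all(c("frame", "x", "z") %in% names(tr)))
      return("each track must be a data.frame with frame, x, z")
    if (nrow(tr) >= 2 && any(diff(tr$frame) <= 0))
      return("frame indices within a track must strictly increase")
  }
  TRUE
})

#' Super-resolution density and velocity maps
#'
#' @slot density nz x nx matrix of track-sample counts per cell.
#' @slot velocity nz x nx matrix of mean speed (mm/s); 0 where density is 0.
#' @slot x,z cell-centre coordinates (mm).
#' @slot cellSize cell edge length (mm).
#' @export
setClass("SRMap",
  slots = c(density = "matrix", velocity = "matrix", x = "numeric",
            z = "numeric", cellSize = "numeric")
)

setValidity("SRMap", function(object) {
  msg <- character()
  if (!identical(dim(object@density), dim(object@velocity)))
    msg <- c(msg, "density and velocity must have identical dimensions")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (any(object@velocity[object@density == 0] != 0))
    msg <- c(msg, "velocity must be 0 where density is 0")
  if (length(msg)) msg else TRUE
})
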