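# Accessor generics and show methods.

#' Number of frames in a container
#' @param x an object with frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3])

#' @rdname nFrames
#' @export
setMethod("nFrames", "RFSequence", function(x) x@params@nFrames)

#' Pixel/cell coordinates
#' @param x an object on a spatial grid
#' @export
setGeneric("xCoords", function(x) standardGeneric("xCoords"))

#' @rdname xCoords
#' @export
setGeneric("zCoords", function(x) standardGeneric("zCoords"))

#' @rdname xCoords
#' @export
setMethod("xCoords", "ImageGrid", function(x) x@x)
#' @rdname xCoords
#' @export
setMethod("zCoords", "ImageGrid", function(x) x@z)
#' @rdname xCoords
#' @export
setMethod("xCoords", "ImageStack", function(x) x@grid@x)
#' @rdname xCoords
#' @export
setMethod("zCoords", "ImageStack", function(x) x@grid@z)
#' @rdname xCoords
#' @export
setMethod("xCoords", "SRMap", function(x) x@x)
#' @rdname xCoords
#' @export
setMethod("zCoords", "SRMap", function(x) x@z)
#' @rdname xCoords
#' @export
setMethod("xCoords", "VesselPhantom", function(x) x@truthX)
#' @rdname xCoords
#' @export
setMethod("zCoords", "VesselPhantom", function(x) x@truthZ)

#' Frames array of an image stack
#' @param x an \linkS4class{ImageStack}
#' @export
stackFrames <- function(x) {
  stopifnot(is(x, "ImageStack"))
  x@frames
}

#' Frame rate (Hz)
#' @param x an object with a frame rate
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname frameRate
#' @export
setMethod("frameRate", "ImageStack", function(x) x@frameRate)
#' @rdname frameRate
#' @export
setMethod("frameRate", "TrackSet", function(x) x@frameRate)
#' @rdname frameRate
#' @export
setMethod("frameRate", "RFSequence", function(x) x@params@prf)

#' Tracks of a TrackSet
#' @param x a \linkS4class{TrackSet}
#' @export
trackList <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@tracks
}

#' Ground-truth occupancy map of a phantom
#' @param x a \linkS4class{VesselPhantom}
#' @export
truthMap <- function(x) {
  stopifnot(is(x, "VesselPhantom"))
  x@truthMap
}

#' Vessel segments of a phantom
#' @param x a \linkS4class{VesselPhantom}
#' @export
vesselSegments <- function(x) {
  stopifnot(is(x, "VesselPhantom"))
  x@segments
}

#' Density / velocity matrices of an SRMap
#' @param x an \linkS4class{SRMap}
#' @export
densityMap <- function(x) {
  stopifnot(is(x, "SRMap"))
  x@density
}

#' @rdname densityMap
#' @export
velocityMap <- function(x) {
  stopifnot(is(x, "SRMap"))
  x@velocity
}

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %d channels (pitch %.3g mm), chirp %.3g-%.3g MHz / %.3g us\n",
    object@nChannels, object@pitch, object@sweepLow, object@sweepHigh,
    object@chirpDuration))
  cat(sprintf("  angles: %s deg; PRF %.6g Hz; %d frames; fs %.3g MHz; c %.5g m/s\n",
              paste(object@angles, collapse = ", "), object@prf,
              object@nFrames, object@samplingRate, object@speedOfSound))
  cat(sprintf("  noise sigma %.3g; attenuation %.3g dB/(cm MHz); skull %.3g dB\n",
              object@noiseSigma, object@attenuation, object@skullAttenuationDb))
})

setMethod("show", "VesselPhantom", function(object) {
  d <- vapply(object@segments, function(s) s@diameter, numeric(1))
  cat(sprintf("VesselPhantom: %d segment(s), diameters %s mm\n",
              length(object@segments), paste(signif(d, 3), collapse = ", ")))
  cat(sprintf("  field extent x [%g, %g] mm, z [%g, %g] mm; SR cell %.3g um\n",
              object@fieldExtent[1], object@fieldExtent[2],
              object@fieldExtent[3], object@fieldExtent[4],
              1000 * object@srSpacing))
  cat(sprintf("  truth map %d x %d cells, %.3g%% lumen\n",
              nrow(object@truthMap), ncol(object@truthMap),
              100 * mean(object@truthMap)))
})

setMethod("show", "RFSequence", function(object) {
  d <- dim(object@samples)
  cat(sprintf("RFSequence: %d frame(s) x %d angle(s) x %d samples x %d channels\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d x %d pixels x %d frame(s) (%s), frame rate %.6g Hz\n",
              d[1], d[2], d[3],
              if (is.complex(object@frames)) "complex" else "envelope",
              object@frameRate))
  cat(sprintf("  x [%.3g, %.3g] mm (dx %.3g), z [%.3g, %.3g] mm (dz %.3g)\n",
              min(object@grid@x), max(object@grid@x), diff(object@grid@x[1:2]),
              min(object@grid@z), max(object@grid@z), diff(object@grid@z[1:2])))
})

setMethod("show", "FilterBand", function(object) {
  cat(sprintf("FilterBand: discard %d leading, %d trailing singular component(s)\n",
              object@lowRankCut, object@highRankCut))
})

setMethod("show", "MotionModel", function(object) {
  cat(sprintf(
    "MotionModel: sigma_p %.3g mm/frame, sigma_m %.3g mm, max speed %.4g mm/s\n",
    object@processNoiseSigma, object@measurementNoiseSigma, object@maxSpeed))
  cat(sprintf("  p_detect %.3g, clutter %.3g/frame, max gap %d, min length %d, %g Hz\n",
              object@pDetect, object@clutterRate, object@maxGap,
              object@minTrackLength, object@frameRate))
})

setMethod("show", "TrackSet", function(object) {
  n <- length(object@tracks)
  nd <- sum(vapply(object@tracks, nrow, integer(1)))
  cat(sprintf("TrackSet: %d track(s), %d detections, frame rate %.6g Hz\n",
              n, nd, object@frameRate))
})

setMethod("show", "SRMap", function(object) {
  cat(sprintf("SRMap: %d x %d cells of %.3g um, %d occupied\n",
              nrow(object@density), ncol(object@density),
              1000 * object@cellSize, sum(object@density > 0)))
})
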