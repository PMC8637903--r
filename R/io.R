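# Persistence: RDS for array containers (image stacks, RF sequences, SR
# maps), CSV for detections and tracks, JSON sidecars for settings, and an
# optional multipage TIFF export of envelope stacks.

#' Write / read an image stack
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path file path (.rds).
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "ImageStack"))
  validObject(obj)
  obj
}

#' Write / read an RF sequence
#'
#' @param rfseq an \linkS4class{RFSequence}.
#' @param path file path (.rds).
#' @export
writeRFSequence <- function(rfseq, path) {
  stopifnot(is(rfseq, "RFSequence"))
  saveRDS(rfseq, path)
  invisible(path)
}

#' @rdname writeRFSequence
#' @export
readRFSequence <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "RFSequence"))
  validObject(obj)
  obj
}

#' Write / read detections as CSV
#'
#' Columns: frame, x_mm, z_mm, intensity, snr_db.
#'
#' @param detections data.frame from \code{\link{localizeStack}}.
#' @param path CSV path.
#' @export
writeDetections <- function(detections, path) {
  out <- data.frame(frame = detections$frame, x_mm = detections$x,
                    z_mm = detections$z, intensity = detections$intensity,
                    snr_db = detections$snr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  d <- utils::read.csv(path)
  data.frame(frame = d$frame, x = d$x_mm, z = d$z_mm,
             intensity = d$intensity, snr = d$snr_db)
}

#' Write / read a track set as CSV (+ JSON sidecar)
#'
#' Columns: track_id, frame, x_mm, z_mm, vx_mm_s, vz_mm_s. The sidecar
#' (same path with .json appended) records the frame rate and, when given,
#' the motion-model settings.
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @param path CSV path.
#' @param model optional \linkS4class{MotionModel} recorded in the sidecar.
#' @export
writeTrackSet <- function(tracks, path, model = NULL) {
  tl <- trackList(tracks)
  rows <- lapply(seq_along(tl), function(i) {
    tr <- tl[[i]]
    data.frame(track_id = i, frame = tr$frame, x_mm = tr$x, z_mm = tr$z,
               vx_mm_s = tr$vx, vz_mm_s = tr$vz)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), x_mm = numeric(),
               z_mm = numeric(), vx_mm_s = numeric(), vz_mm_s = numeric())
  utils::write.csv(out, path, row.names = FALSE)
  side <- list(frameRate = frameRate(tracks))
  if (!is.null(model))
    side$model <- list(
      processNoiseSigma = model@processNoiseSigma,
      measurementNoiseSigma = model@measurementNoiseSigma,
      maxSpeed = model@maxSpeed, pDetect = model@pDetect,
      clutterRate = model@clutterRate, birthRate = model@birthRate,
      maxGap = model@maxGap, minTrackLength = model@minTrackLength)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrackSet
#' @export
readTrackSet <- function(path) {
  d <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  tl <- lapply(split(d, d$track_id), function(tr)
    data.frame(frame = tr$frame, x = tr$x_mm, z = tr$z_mm,
               intensity = NA_real_, vx = tr$vx_mm_s, vz = tr$vz_mm_s))
  names(tl) <- NULL
  new("TrackSet", tracks = tl, frameRate = as.numeric(side$frameRate))
}

#' Write / read a super-resolution map
#'
#' @param srmap an \linkS4class{SRMap}.
#' @param path file path (.rds).
#' @export
writeSRMap <- function(srmap, path) {
  stopifnot(is(srmap, "SRMap"))
  saveRDS(srmap, path)
  invisible(path)
}

#' @rdname writeSRMap
#' @export
readSRMap <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "SRMap"))
  validObject(obj)
  obj
}

#' Export an envelope stack as multipage TIFF
#'
#' Frames are enveloped, normalized to the stack maximum and written as
#' 32-bit float pages. Requires the tiff package.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path TIFF path.
#' @export
writeEnvelopeTIFF <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for TIFF export")
  fr <- Mod(stackFrames(stack))
  m <- max(fr)
  if (m > 0) fr <- fr / m
  pages <- lapply(seq_len(dim(fr)[3]), function(f) fr[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
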