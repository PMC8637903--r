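#' Super-resolution grid of a phantom
#'
#' @param phantom a \linkS4class{VesselPhantom}.
#' @return list(x, z, cellSize) matching the phantom's truth map.
#' @export
srGrid <- function(phantom) {
  list(x = phantom@truthX, z = phantom@truthZ, cellSize = phantom@srSpacing)
}

#' Accumulate tracks into super-resolution density and velocity maps
#'
#' Each track is densified by linear interpolation between consecutive
#' detections at steps of at most one cell; every visited cell's density
#' increments and accumulates the interpolated speed, and the final velocity
#' is the accumulated speed divided by the count. Interpolated samples
#' falling outside the grid are dropped.
#'
#' @param tracks a \linkS4class{TrackSet} (with velocities).
#' @param grid list(x, z, cellSize) as from \code{\link{srGrid}}, or an
#'   extent list(xlim, zlim, cellSize).
#' @return an \linkS4class{SRMap}.
#' @export
accumulateMaps <- function(tracks, grid) {
  if (is.null(grid[["x"]])) {
    cs <- grid[["cellSize"]]
    grid <- list(x = seq(grid[["xlim"]][1] + cs / 2, grid[["xlim"]][2],
                         by = cs),
                 z = seq(grid[["zlim"]][1] + cs / 2, grid[["zlim"]][2],
                         by = cs),
                 cellSize = cs)
  }
  nx <- length(grid[["x"]]); nz <- length(grid[["z"]])
  cs <- grid[["cellSize"]]
  x0 <- grid[["x"]][1] - cs / 2
  z0 <- grid[["z"]][1] - cs / 2
  density <- matrix(0, nz, nx)
  accum <- matrix(0, nz, nx)
  for (tr in trackList(tracks)) {
    if (nrow(tr) < 2) next
    speed <- sqrt(tr$vx^2 + tr$vz^2)
    px <- numeric(0); pz <- numeric(0); ps <- numeric(0)
    for (k in seq_len(nrow(tr) - 1)) {
      d <- sqrt((tr$x[k + 1] - tr$x[k])^2 + (tr$z[k + 1] - tr$z[k])^2)
      m <- max(2L, ceiling(d / cs) + 1L)
      t <- seq(0, 1, length.out = m)
      # drop the segment end to avoid double counting shared detections
      t <- t[-m]
      px <- c(px, tr$x[k] + t * (tr$x[k + 1] - tr$x[k]))
      pz <- c(pz, tr$z[k] + t * (tr$z[k + 1] - tr$z[k]))
      ps <- c(ps, speed[k] + t * (speed[k + 1] - speed[k]))
    }
    px <- c(px, tr$x[nrow(tr)])
    pz <- c(pz, tr$z[nrow(tr)])
    ps <- c(ps, speed[nrow(tr)])
    ix <- floor((px - x0) / cs) + 1
    iz <- floor((pz - z0) / cs) + 1
    ok <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz
    if (!any(ok)) next
    lin <- iz[ok] + nz * (ix[ok] - 1)
    counts <- tabulate(lin, nbins = nz * nx)
    density <- density + counts
    sp <- rowsum(ps[ok], lin)
    idx <- as.integer(rownames(sp))
    accum[idx] <- accum[idx] + sp[, 1]
  }
  velocity <- matrix(0, nz, nx)
  nzc <- density > 0
  velocity[nzc] <- accum[nzc] / density[nzc]
  new("SRMap", density = density, velocity = velocity, x = grid[["x"]],
      z = grid[["z"]], cellSize = cs)
}

#' Normalized mean squared error against the phantom truth map
#'
#' Both maps are brought to [0, 1] -- the density by its maximum ("max"
#' mode) or by thresholding occupancy ("binary" mode); the truth map is
#' already binary -- and the MSE is the mean squared per-cell difference
#' over the evaluation region: either the truth bounding box dilated by
#' \code{dilateMm} ("bbox") or the full shared grid ("full", the convention
#' under which whole-image reconstruction errors are reported). An all-zero
#' density map yields mean(truth^2) over the region, the valid worst case.
#'
#' @param sr an \linkS4class{SRMap}.
#' @param phantom the \linkS4class{VesselPhantom} ground truth on the same
#'   grid.
#' @param mode density normalization, "max" or "binary".
#' @param region "full" or "bbox".
#' @param dilateMm bounding-box dilation for region = "bbox" (mm).
#' @return scalar MSE in [0, 1].
#' @export
computeMSE <- function(sr, phantom, mode = c("max", "binary"),
                       region = c("full", "bbox"), dilateMm = 0.5) {
  mode <- match.arg(mode)
  region <- match.arg(region)
  truth <- phantom@truthMap
  if (!identical(dim(sr@density), dim(truth)))
    stop("SRMap and phantom truth map are not on the same grid")
  if (max(abs(sr@x - phantom@truthX)) > 1e-6 ||
      max(abs(sr@z - phantom@truthZ)) > 1e-6)
    stop("SRMap and phantom truth map are not on the same grid")
  d <- sr@density
  d <- if (mode == "binary") (d > 0) + 0
       else if (max(d) > 0) d / max(d) else d
  if (region == "bbox") {
    occ <- which(truth > 0, arr.ind = TRUE)
    if (nrow(occ) == 0) stop("truth map is empty")
    pad <- ceiling(dilateMm / sr@cellSize)
    zi <- max(1, min(occ[, 1]) - pad):min(nrow(truth), max(occ[, 1]) + pad)
    xi <- max(1, min(occ[, 2]) - pad):min(ncol(truth), max(occ[, 2]) + pad)
    d <- d[zi, xi]
    truth <- truth[zi, xi]
  }
  mean((d - truth)^2)
}

#' Vessel diameter as the FWHM of a density cross-section
#'
#' Extracts the density profile along a cut line, averaging over a band
#' along the perpendicular (vessel) direction, optionally smoothing with a
#' small Gaussian kernel, and returns the full width at half maximum with
#' linear interpolation between cells. With profile = "occupancy" (the
#' default) cells count as occupied-or-not, so the width is not distorted
#' by a few heavily traversed cells; "density" uses the raw counts.
#'
#' @param sr an \linkS4class{SRMap}.
#' @param center cut centre c(x, z) mm, on the vessel.
#' @param direction cut direction (2-vector, need not be normalized),
#'   perpendicular to the vessel.
#' @param halfLength half-length of the cut (mm).
#' @param bandHalfLength half-length of the averaging band along the vessel
#'   (mm).
#' @param smoothSigma Gaussian smoothing of the profile (mm); 0 disables.
#' @param profile "occupancy" (default) or "density".
#' @return FWHM (mm).
#' @export
measureFWHMDiameter <- function(sr, center, direction = c(1, 0),
                                halfLength = 2, bandHalfLength = 3,
                                smoothSigma = 0.02,
                                profile = c("occupancy", "density")) {
  profile <- match.arg(profile)
  dmap <- if (profile == "occupancy") (sr@density > 0) + 0 else sr@density
  cs <- sr@cellSize
  dirn <- direction / sqrt(sum(direction^2))
  perp <- c(-dirn[2], dirn[1])
  s <- seq(-halfLength, halfLength, by = cs)
  b <- seq(-bandHalfLength, bandHalfLength, by = cs)
  nx <- length(sr@x); nz <- length(sr@z)
  x0 <- sr@x[1] - cs / 2
  z0 <- sr@z[1] - cs / 2
  prof <- vapply(s, function(si) {
    px <- center[1] + si * dirn[1] + b * perp[1]
    pz <- center[2] + si * dirn[2] + b * perp[2]
    ix <- floor((px - x0) / cs) + 1
    iz <- floor((pz - z0) / cs) + 1
    ok <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz
    if (!any(ok)) return(0)
    mean(dmap[cbind(iz[ok], ix[ok])])
  }, numeric(1))
  if (smoothSigma > 0) {
    hk <- ceiling(3 * smoothSigma / cs)
    kern <- stats::dnorm(seq(-hk, hk) * cs, sd = smoothSigma)
    kern <- kern / sum(kern)
    prof <- stats::filter(c(rep(0, hk), prof, rep(0, hk)), kern,
                          sides = 2)[(hk + 1):(hk + length(s))]
  }
  m <- which.max(prof)
  pk <- prof[m]
  if (!is.finite(pk) || pk <= 0) stop("density profile has no peak")
  half <- pk / 2
  below <- prof < half
  if (!any(below[seq_len(m)]) || !any(below[m:length(prof)]))
    stop("density profile does not fall to half maximum inside the cut")
  li <- max(which(below[seq_len(m)]))
  ri <- m - 1 + min(which(below[m:length(prof)]))
  # linear interpolation of the half-max crossings
  sl <- s[li] + (half - prof[li]) / (prof[li + 1] - prof[li]) * cs
  sr_ <- s[ri - 1] + (half - prof[ri - 1]) /
    (prof[ri] - prof[ri - 1]) * cs
  sr_ - sl
}

#' Image signal-to-noise ratio between two regions
#'
#' 20 log10(peak |signal ROI| / RMS |background ROI|).
#'
#' @param image real or complex matrix.
#' @param signalMask,backgroundMask disjoint logical masks of the same
#'   dimension as the image (see \code{\link{roiMask}}).
#' @return SNR in dB.
#' @export
computeSNR <- function(image, signalMask, backgroundMask) {
  if (any(signalMask & backgroundMask)) stop("ROIs must be disjoint")
  if (!any(signalMask) || !any(backgroundMask)) stop("empty ROI")
  a <- Mod(image)
  rms <- sqrt(mean(a[backgroundMask]^2))
  if (rms <= 0) stop("background RMS is zero")
  20 * log10(max(a[signalMask]) / rms)
}

#' Rectangular region-of-interest mask on an image grid
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param xlim,zlim region bounds (mm).
#' @return logical nz x nx matrix.
#' @export
roiMask <- function(grid, xlim, zlim) {
  outer(grid@z >= zlim[1] & grid@z <= zlim[2],
        grid@x >= xlim[1] & grid@x <= xlim[2], `&`)
}

#' Resolution gain of localization over conventional imaging
#'
#' Ratio of the lateral -6 dB FWHM of the conventional compounded
#' point-target image to the effective localization FWHM, 2.355 x the
#' standard deviation of replicate sub-pixel localizations of the same
#' target.
#'
#' @param conventionalStack \linkS4class{ImageStack} of the point target
#'   (frames are averaged as envelopes).
#' @param replicates data.frame of replicate localizations with columns x, z
#'   (>= 10 rows).
#' @return list(gain, fwhmMm, locSdMm).
#' @export
resolutionGain <- function(conventionalStack, replicates) {
  if (nrow(replicates) < 10) stop("need at least 10 localization replicates")
  env <- apply(Mod(stackFrames(conventionalStack)), c(1, 2), mean)
  grid <- conventionalStack@grid
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  prof <- env[pk[1], ]
  fwhm <- .profileFWHM(grid@x, prof)
  locSd <- stats::sd(replicates$x)
  if (locSd <= 0) stop("replicate localizations have zero spread")
  list(gain = fwhm / (2.355 * locSd), fwhmMm = fwhm, locSdMm = locSd)
}

# FWHM of a sampled profile with linear interpolation of the crossings
.profileFWHM <- function(coords, profile) {
  m <- which.max(profile)
  half <- profile[m] / 2
  if (profile[m] <= 0) stop("profile has no peak")
  below <- profile < half
  if (!any(below[seq_len(m)]) || !any(below[m:length(profile)]))
    stop("profile does not fall to half maximum")
  li <- max(which(below[seq_len(m)]))
  ri <- m - 1 + min(which(below[m:length(profile)]))
  d <- diff(coords[1:2])
  left <- coords[li] + (half - profile[li]) /
    (profile[li + 1] - profile[li]) * d
  right <- coords[ri - 1] + (half - profile[ri - 1]) /
    (profile[ri] - profile[ri - 1]) * d
  right - left
}

#' Maximum depth reached by any tracked detection
#'
#' @param tracks a \linkS4class{TrackSet}.
#' @return depth (mm); 0 for an empty set.
#' @export
maxTrackedDepth <- function(tracks) {
  tl <- trackList(tracks)
  if (!length(tl)) return(0)
  max(vapply(tl, function(tr) max(tr$z), numeric(1)))
}
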