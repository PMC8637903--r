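#' Create a vessel segment
#'
#' @param centerline n x 2 matrix (or 2-column object coercible to one) of
#'   (x, z) points in mm, ordered along the vessel.
#' @param diameter lumen diameter (mm).
#' @param flowSpeed flow speed (mm/s).
#' @param flowDirection +1 (first to last point) or -1.
#' @return a \linkS4class{VesselSegment}.
#' @export
vesselSegment <- function(centerline, diameter, flowSpeed = 30,
                          flowDirection = 1) {
  cl <- as.matrix(centerline)
  storage.mode(cl) <- "double"
  new("VesselSegment", centerline = cl, diameter = diameter,
      flowSpeed = flowSpeed, flowDirection = flowDirection)
}

# cumulative arc length (first entry 0) of a segment centerline
.segCumArc <- function(seg) {
  d <- diff(seg@centerline)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

.segLength <- function(seg) {
  ca <- .segCumArc(seg)
  ca[length(ca)]
}

# point, tangent and inward normal at arc coordinates (vectorized);
# arcs are clamped to [0, L]
.segPoint <- function(seg, arc) {
  ca <- .segCumArc(seg)
  cl <- seg@centerline
  arc <- pmin(pmax(arc, 0), ca[length(ca)])
  x <- stats::approx(ca, cl[, 1], arc, rule = 2)$y
  z <- stats::approx(ca, cl[, 2], arc, rule = 2)$y
  i <- pmin(pmax(findInterval(arc, ca, rightmost.closed = TRUE), 1),
            nrow(cl) - 1)
  tx <- cl[i + 1, 1] - cl[i, 1]
  tz <- cl[i + 1, 2] - cl[i, 2]
  tn <- sqrt(tx^2 + tz^2)
  list(x = x, z = z, tx = tx / tn, tz = tz / tn,
       nx = -tz / tn, nz = tx / tn)
}

# rasterize segment lumens onto the SR grid: 1 where a cell centre is within
# diameter/2 of a centerline
.renderTruthMap <- function(segments, extent, spacing) {
  nx <- max(1L, round((extent[2] - extent[1]) / spacing))
  nz <- max(1L, round((extent[4] - extent[3]) / spacing))
  gx <- extent[1] + (seq_len(nx) - 0.5) * spacing
  gz <- extent[3] + (seq_len(nz) - 0.5) * spacing
  tm <- matrix(0, nz, nx)
  for (seg in segments) {
    r <- seg@diameter / 2
    cl <- seg@centerline
    # densify curved centerlines so the piecewise-linear distance is accurate
    L <- .segLength(seg)
    npts <- max(nrow(cl), ceiling(L / 0.25) + 1)
    p <- .segPoint(seg, seq(0, L, length.out = npts))
    px <- p$x; pz <- p$z
    ix <- which(gx >= min(px) - r - spacing & gx <= max(px) + r + spacing)
    iz <- which(gz >= min(pz) - r - spacing & gz <= max(pz) + r + spacing)
    if (!length(ix) || !length(iz)) next
    cx <- rep(gx[ix], each = length(iz))
    cz <- rep(gz[iz], times = length(ix))
    dmin <- rep(Inf, length(cx))
    for (k in seq_len(npts - 1)) {
      ax <- px[k]; az <- pz[k]
      bx <- px[k + 1] - ax; bz <- pz[k + 1] - az
      b2 <- bx^2 + bz^2
      if (b2 == 0) next
      t <- pmin(pmax(((cx - ax) * bx + (cz - az) * bz) / b2, 0), 1)
      d2 <- (cx - (ax + t * bx))^2 + (cz - (az + t * bz))^2
      dmin <- pmin(dmin, d2)
    }
    inside <- matrix(dmin <= r^2, length(iz), length(ix))
    tm[iz, ix] <- pmax(tm[iz, ix], inside + 0)
  }
  list(map = tm, x = gx, z = gz)
}

#' Build a vessel phantom
#'
#' Either a named preset or an explicit list of \linkS4class{VesselSegment}s.
#' Presets:
#' \describe{
#'   \item{two_tube}{two parallel depth-oriented tubes, inner diameters
#'     1.0 mm (at x = -3 mm) and 0.7 mm (at x = +3 mm), spanning depths
#'     15--40 mm, flow 30 mm/s towards increasing depth.}
#'   \item{bifurcation}{a 1.0 mm parent tube splitting into two curved 0.7 mm
#'     branches.}
#'   \item{depth_ladder}{four horizontal 1.0 mm tubes at depths 10, 25, 40
#'     and 55 mm, alternating flow direction.}
#' }
#'
#' @param spec preset name or list of segments.
#' @param fieldExtent numeric(4) (xmin, xmax, zmin, zmax) mm; defaults per
#'   preset, and to the segment bounding box dilated by 2 mm for explicit
#'   segment lists.
#' @param srSpacing super-resolution cell size (mm), default 0.01 (10 um).
#' @param flowSpeed optional override of every segment's flow speed (mm/s).
#' @return a \linkS4class{VesselPhantom} with rendered truth map.
#' @export
buildVesselPhantom <- function(spec = "two_tube", fieldExtent = NULL,
                               srSpacing = 0.01, flowSpeed = NULL) {
  if (is.character(spec)) {
    spec <- match.arg(spec, c("two_tube", "bifurcation", "depth_ladder"))
    built <- switch(spec,
      two_tube = list(
        segments = list(
          vesselSegment(rbind(c(-3, 15), c(-3, 40)), diameter = 1.0),
          vesselSegment(rbind(c(3, 15), c(3, 40)), diameter = 0.7)),
        extent = c(-10, 10, 10, 45)),
      bifurcation = {
        th <- seq(0, pi / 2, length.out = 25)
        left <- cbind(-5 + 5 * cos(th), 25 + 8 * sin(th))
        right <- cbind(5 - 5 * cos(th), 25 + 8 * sin(th))
        list(segments = list(
          vesselSegment(rbind(c(0, 14), c(0, 25)), diameter = 1.0),
          vesselSegment(left, diameter = 0.7, flowSpeed = 20),
          vesselSegment(right, diameter = 0.7, flowSpeed = 20)),
          extent = c(-10, 10, 10, 38))
      },
      depth_ladder = list(
        segments = list(
          vesselSegment(rbind(c(-12, 10), c(12, 10)), diameter = 1.0),
          vesselSegment(rbind(c(-12, 25), c(12, 25)), diameter = 1.0,
                        flowDirection = -1),
          vesselSegment(rbind(c(-12, 40), c(12, 40)), diameter = 1.0),
          vesselSegment(rbind(c(-12, 55), c(12, 55)), diameter = 1.0,
                        flowDirection = -1)),
        extent = c(-16, 16, 5, 58))
    )
    segments <- built$segments
    if (is.null(fieldExtent)) fieldExtent <- built$extent
  } else {
    segments <- spec
    if (length(segments) == 0)
      stop("phantom specification contains no segments")
    for (s in segments) {
      if (!is(s, "VesselSegment")) stop("segments must be VesselSegment objects")
      validObject(s)
    }
    if (is.null(fieldExtent)) {
      xs <- unlist(lapply(segments, function(s) s@centerline[, 1]))
      zs <- unlist(lapply(segments, function(s) s@centerline[, 2]))
      r <- max(vapply(segments, function(s) s@diameter / 2, numeric(1)))
      fieldExtent <- c(min(xs) - r - 2, max(xs) + r + 2,
                       max(0, min(zs) - r - 2), max(zs) + r + 2)
    }
  }
  if (!is.null(flowSpeed)) {
    segments <- lapply(segments, function(s) {
      s@flowSpeed <- flowSpeed
      s
    })
  }
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    r <- s@diameter / 2
    cl <- s@centerline
    if (min(cl[, 1]) - r < fieldExtent[1] || max(cl[, 1]) + r > fieldExtent[2] ||
        min(cl[, 2]) - r < fieldExtent[3] || max(cl[, 2]) + r > fieldExtent[4])
      stop(sprintf("segment %d extends outside the field extent", i))
  }
  tm <- .renderTruthMap(segments, fieldExtent, srSpacing)
  new("VesselPhantom", segments = segments, fieldExtent = fieldExtent,
      srSpacing = srSpacing, truthMap = tm$map, truthX = tm$x, truthZ = tm$z)
}

# cartesian positions from (segment, arc, offset) coordinates
.bubbleXZ <- function(bubbles, phantom) {
  if (nrow(bubbles) == 0) return(bubbles)
  for (sid in unique(bubbles$segment)) {
    idx <- bubbles$segment == sid
    p <- .segPoint(phantom@segments[[sid]], bubbles$arc[idx])
    bubbles$x[idx] <- p$x + bubbles$offset[idx] * p$nx
    bubbles$z[idx] <- p$z + bubbles$offset[idx] * p$nz
  }
  bubbles
}

#' Seed flowing microbubbles along the phantom vessels
#'
#' Bubble count per segment is Poisson with mean concentration x length;
#' positions are uniform along the centerline with a uniform radial offset
#' inside the lumen. Scattering amplitudes are mildly log-normal (sd 0.2)
#' around 1.
#'
#' @param phantom a \linkS4class{VesselPhantom}.
#' @param concentration bubbles per mm of vessel length (line density).
#' @param seed integer RNG seed.
#' @param flowProfile "plug" (uniform speed over the lumen, default) or
#'   "parabolic" (Poiseuille, peak at the centerline).
#' @return data.frame with columns id, segment, arc, offset, amplitude,
#'   alive, x, z.
#' @export
seedBubbles <- function(phantom, concentration, seed = 1L,
                        flowProfile = c("plug", "parabolic")) {
  flowProfile <- match.arg(flowProfile)
  if (concentration < 0) stop("concentration must be >= 0")
  set.seed(as.integer(seed))
  out <- list()
  for (sid in seq_along(phantom@segments)) {
    seg <- phantom@segments[[sid]]
    L <- .segLength(seg)
    n <- stats::rpois(1, concentration * L)
    if (n == 0) next
    out[[length(out) + 1]] <- data.frame(
      segment = sid,
      arc = stats::runif(n, 0, L),
      offset = stats::runif(n, -seg@diameter / 2, seg@diameter / 2),
      amplitude = exp(stats::rnorm(n, 0, 0.2)))
  }
  if (!length(out)) {
    b <- data.frame(id = integer(), segment = integer(), arc = numeric(),
                    offset = numeric(), amplitude = numeric(),
                    alive = logical(), x = numeric(), z = numeric())
    attr(b, "flowProfile") <- flowProfile
    return(b)
  }
  b <- do.call(rbind, out)
  b <- data.frame(id = seq_len(nrow(b)), b, alive = TRUE, x = NA_real_,
                  z = NA_real_)
  b <- .bubbleXZ(b, phantom)
  attr(b, "flowProfile") <- flowProfile
  b
}

# per-bubble advection speed under the configured flow profile
.bubbleSpeed <- function(bubbles, phantom) {
  sp <- numeric(nrow(bubbles))
  profile <- attr(bubbles, "flowProfile")
  if (is.null(profile)) profile <- "plug"
  for (sid in unique(bubbles$segment)) {
    idx <- bubbles$segment == sid
    seg <- phantom@segments[[sid]]
    v <- seg@flowSpeed
    if (profile == "parabolic") {
      r <- seg@diameter / 2
      sp[idx] <- v * (1 - (bubbles$offset[idx] / r)^2)
    } else {
      sp[idx] <- v
    }
  }
  sp
}

#' Advance bubbles along their vessels
#'
#' Each bubble moves flowSpeed * dt along its segment's centerline (plug flow
#' by default). Bubbles leaving a segment are recycled at its entrance with a
#' fresh random radial offset, so the population size is conserved.
#'
#' @param bubbles data.frame from \code{\link{seedBubbles}}.
#' @param phantom the \linkS4class{VesselPhantom}.
#' @param dt time step (s), must be > 0.
#' @param radialDiffusion standard deviation (mm) of a per-step random
#'   radial displacement modelling hydrodynamic dispersion across the lumen,
#'   reflected at the walls; 0 (default) disables it.
#' @return the advanced bubble data.frame.
#' @export
advanceBubbles <- function(bubbles, phantom, dt, radialDiffusion = 0) {
  if (dt <= 0) stop("dt must be > 0")
  if (nrow(bubbles) == 0) return(bubbles)
  sp <- .bubbleSpeed(bubbles, phantom)
  for (sid in unique(bubbles$segment)) {
    idx <- which(bubbles$segment == sid)
    seg <- phantom@segments[[sid]]
    L <- .segLength(seg)
    arc <- bubbles$arc[idx] + seg@flowDirection * sp[idx] * dt
    # recycle at the entrance, preserving overshoot, with a new offset
    out <- if (seg@flowDirection > 0) arc > L else arc < 0
    if (any(out)) {
      arc[out] <- if (seg@flowDirection > 0) arc[out] - L else arc[out] + L
      arc[out] <- pmin(pmax(arc[out], 0), L)
      bubbles$offset[idx[out]] <-
        stats::runif(sum(out), -seg@diameter / 2, seg@diameter / 2)
    }
    bubbles$arc[idx] <- arc
    if (radialDiffusion > 0) {
      r <- seg@diameter / 2
      off <- bubbles$offset[idx] +
        stats::rnorm(length(idx), 0, radialDiffusion)
      # reflect at the lumen walls (triangle wave of period 4r)
      off <- (2 * r - abs(((off + r) %% (4 * r)) - 2 * r)) - r
      bubbles$offset[idx] <- off
    }
  }
  .bubbleXZ(bubbles, phantom)
}

# kill bubbles with per-frame probability 1/lifetimeFrames and re-seed them
# uniformly (destruction/replenishment); keeps the population size constant
.respawnBubbles <- function(bubbles, phantom, lifetimeFrames) {
  if (!is.finite(lifetimeFrames) || nrow(bubbles) == 0) return(bubbles)
  die <- stats::runif(nrow(bubbles)) < 1 / lifetimeFrames
  if (!any(die)) return(bubbles)
  for (i in which(die)) {
    sid <- bubbles$segment[i]
    seg <- phantom@segments[[sid]]
    L <- .segLength(seg)
    bubbles$arc[i] <- stats::runif(1, 0, L)
    bubbles$offset[i] <- stats::runif(1, -seg@diameter / 2, seg@diameter / 2)
    bubbles$id[i] <- max(bubbles$id) + 1L
  }
  .bubbleXZ(bubbles, phantom)
}
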