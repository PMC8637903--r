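#' Detect microbubble candidates in an envelope frame
#'
#' Regional maxima exceeding median + thresholdSigma x robust standard
#' deviation (MAD) of the frame, separated by at least minSeparation
#' (intensity-ordered greedy suppression; the default separation should be
#' about one PSF half-width).
#'
#' @param frame real (envelope) nz x nx matrix.
#' @param grid the \linkS4class{ImageGrid} of the frame.
#' @param thresholdSigma robust-sigma multiplier (default 4).
#' @param minSeparation minimum distance between detections (mm).
#' @return data.frame with columns x, z, ix, iz, intensity, snr (dB);
#'   zero rows when nothing exceeds the threshold.
#' @export
detectCandidates <- function(frame, grid, thresholdSigma = 4,
                             minSeparation = 0.5) {
  if (is.complex(frame)) stop("detectCandidates expects an envelope frame")
  nz <- nrow(frame); nx <- ncol(frame)
  noise <- stats::mad(frame)
  thr <- stats::median(frame) + thresholdSigma * noise
  empty <- data.frame(x = numeric(), z = numeric(), ix = integer(),
                      iz = integer(), intensity = numeric(), snr = numeric())
  if (nz < 3 || nx < 3) return(empty)
  core <- frame[2:(nz - 1), 2:(nx - 1)]
  isMax <- core > thr
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    isMax <- isMax &
      core >= frame[2:(nz - 1) + dz, 2:(nx - 1) + dx]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  iz <- idx[, 1] + 1L; ix <- idx[, 2] + 1L
  val <- frame[cbind(iz, ix)]
  o <- order(val, decreasing = TRUE)
  iz <- iz[o]; ix <- ix[o]; val <- val[o]
  x <- grid@x[ix]; z <- grid@z[iz]
  keep <- rep(TRUE, length(val))
  for (i in seq_along(val)) {
    if (!keep[i]) next
    if (i < length(val)) {
      j <- (i + 1):length(val)
      close <- keep[j] &
        ((x[j] - x[i])^2 + (z[j] - z[i])^2 < minSeparation^2)
      keep[j[close]] <- FALSE
    }
  }
  snr <- 20 * log10(val[keep] / max(noise, .Machine$double.eps))
  data.frame(x = x[keep], z = z[keep], ix = ix[keep], iz = iz[keep],
             intensity = val[keep], snr = snr)
}

#' Refine a detection to sub-pixel precision
#'
#' Background-subtracted intensity-weighted centroid over a square window
#' (default), or a 2-D Gaussian least-squares fit. When the window is clipped
#' by the frame border the unrefined position is returned with a warning.
#'
#' @param frame real (envelope) nz x nx matrix.
#' @param grid the \linkS4class{ImageGrid}.
#' @param detection one row of \code{\link{detectCandidates}} output (needs
#'   ix, iz).
#' @param windowHalfwidth half-width of the window in pixels; either a
#'   scalar or c(z, x) for an anisotropic window (the window should cover
#'   most of the point-spread function in each direction, which is usually
#'   much wider laterally than axially).
#' @param method "centroid" (default) or "gaussian".
#' @return the detection row with refined x, z.
#' @export
refineSubpixel <- function(frame, grid, detection, windowHalfwidth = 3L,
                           method = c("centroid", "gaussian")) {
  method <- match.arg(method)
  h <- as.integer(windowHalfwidth)
  if (length(h) == 1L) h <- c(h, h)
  hz <- h[1]; hx <- h[2]
  iz <- detection$iz[1]; ix <- detection$ix[1]
  nz <- nrow(frame); nx <- ncol(frame)
  if (iz - hz < 1 || iz + hz > nz || ix - hx < 1 || ix + hx > nx) {
    warning("refinement window clipped at the frame border; position unrefined")
    return(detection)
  }
  zi <- (iz - hz):(iz + hz); xi <- (ix - hx):(ix + hx)
  w <- frame[zi, xi]
  # planar background fitted on the window border: a constant offset alone
  # leaves interference tilts that drag the centroid sideways
  nzw <- nrow(w); nxw <- ncol(w)
  bi <- rbind(cbind(1, seq_len(nxw)), cbind(nzw, seq_len(nxw)),
              cbind(seq_len(nzw), 1), cbind(seq_len(nzw), nxw))
  bfit <- stats::lm.fit(cbind(1, bi[, 1], bi[, 2]), w[bi])
  plane <- matrix(bfit$coefficients[1], nzw, nxw) +
    outer(seq_len(nzw) * bfit$coefficients[2],
          seq_len(nxw) * bfit$coefficients[3], `+`)
  w <- pmax(w - plane, 0)
  if (sum(w) <= 0) return(detection)
  gx <- grid@x[xi]; gz <- grid@z[zi]
  if (method == "centroid") {
    detection$x <- sum(colSums(w) * gx) / sum(w)
    detection$z <- sum(rowSums(w) * gz) / sum(w)
  } else {
    cz <- sum(rowSums(w) * gz) / sum(w)
    cx <- sum(colSums(w) * gx) / sum(w)
    amp <- max(w)
    sig <- diff(range(gx)) / 4
    obj <- function(p) {
      mu <- p[1] * exp(-((outer(gz, rep(1, length(gx))) - p[2])^2 / (2 * p[4]^2) +
                         (outer(rep(1, length(gz)), gx) - p[3])^2 / (2 * p[5]^2)))
      sum((w - mu)^2)
    }
    fit <- stats::optim(c(amp, cz, cx, sig, sig), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    detection$z <- fit$par[2]
    detection$x <- fit$par[3]
  }
  # never move more than one pixel from the detected maximum
  dx <- diff(grid@x[1:2]); dz <- diff(grid@z[1:2])
  detection$x <- min(max(detection$x, grid@x[ix] - dx), grid@x[ix] + dx)
  detection$z <- min(max(detection$z, grid@z[iz] - dz), grid@z[iz] + dz)
  detection
}

#' Localize microbubbles in every frame of a stack
#'
#' Envelope detection plus sub-pixel refinement per frame.
#'
#' @param stack \linkS4class{ImageStack} (complex stacks are enveloped).
#' @param thresholdSigma robust threshold multiplier.
#' @param minSeparation minimum detection separation (mm).
#' @param windowHalfwidth refinement window half-width (pixels), scalar or
#'   c(z, x).
#' @param method "centroid" or "gaussian".
#' @return data.frame with columns frame, x, z, intensity, snr.
#' @export
localizeStack <- function(stack, thresholdSigma = 4, minSeparation = 0.5,
                          windowHalfwidth = 3L,
                          method = c("centroid", "gaussian")) {
  method <- match.arg(method)
  nf <- dim(stack@frames)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- stack@frames[, , f]
    if (is.complex(fr)) fr <- Mod(fr)
    det <- detectCandidates(fr, stack@grid, thresholdSigma, minSeparation)
    if (nrow(det) == 0) next
    refined <- do.call(rbind, lapply(seq_len(nrow(det)), function(i)
      suppressWarnings(
        refineSubpixel(fr, stack@grid, det[i, ], windowHalfwidth, method))))
    refined$frame <- f
    out[[f]] <- refined[, c("frame", "x", "z", "intensity", "snr")]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(), x = numeric(), z = numeric(),
                      intensity = numeric(), snr = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
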