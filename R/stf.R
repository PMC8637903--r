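#' Construct a filter band
#'
#' @param lowRankCut number of leading singular components to discard
#'   (slow, spatially coherent tissue/clutter signal).
#' @param highRankCut number of trailing components to discard (noise);
#'   default 0.
#' @return a \linkS4class{FilterBand}.
#' @export
filterBand <- function(lowRankCut, highRankCut = 0L) {
  new("FilterBand", lowRankCut = as.integer(lowRankCut),
      highRankCut = as.integer(highRankCut))
}

# eigen-decomposition of the Casorati Gram matrix X^H X; singular values are
# the square roots of its eigenvalues and right singular vectors its
# eigenvectors (computed on nFrames x nFrames, never on pixels x pixels)
.casoratiEigen <- function(stack) {
  d <- dim(stack@frames)
  X <- stack@frames
  dim(X) <- c(d[1] * d[2], d[3])
  H <- Conj(t(X)) %*% X
  eg <- eigen(H, symmetric = TRUE)
  list(X = X, values = pmax(Re(eg$values), 0), vectors = eg$vectors, dims = d)
}

#' Singular-value spectrum of the Casorati matrix
#'
#' @param stack an \linkS4class{ImageStack} with >= 2 frames.
#' @return numeric vector of singular values, decreasing.
#' @export
singularSpectrum <- function(stack) {
  if (dim(stack@frames)[3] < 2) stop("stack must have >= 2 frames")
  sqrt(.casoratiEigen(stack)$values)
}

#' SVD spatiotemporal clutter filtering
#'
#' Reshapes the stack to a (pixels x frames) Casorati matrix, removes the
#' banded singular components (leading = tissue/clutter, optional trailing =
#' noise) by projection, and reconstructs. Operates on the complex stack so
#' phase is preserved for localization.
#'
#' @param stack complex \linkS4class{ImageStack} with >= 2 frames.
#' @param band a \linkS4class{FilterBand}, e.g. from
#'   \code{\link{selectRankThreshold}}.
#' @return filtered \linkS4class{ImageStack} on the same grid.
#' @export
svdClutterFilter <- function(stack, band) {
  d <- dim(stack@frames)
  if (d[3] < 2) stop("stack must have >= 2 frames")
  rank <- min(d[1] * d[2], d[3])
  lo <- band@lowRankCut
  hi <- band@highRankCut
  if (lo + hi >= rank)
    stop(sprintf("filter band (%d + %d) exceeds the matrix rank %d",
                 lo, hi, rank))
  if (lo == 0L && hi == 0L) return(stack)
  ce <- .casoratiEigen(stack)
  drop <- c(seq_len(lo), if (hi > 0) seq(d[3] - hi + 1, d[3]))
  V <- ce$vectors[, drop, drop = FALSE]
  Xf <- ce$X - (ce$X %*% V) %*% Conj(t(V))
  dim(Xf) <- d
  new("ImageStack", frames = Xf, grid = stack@grid,
      frameRate = stack@frameRate)
}

#' Automatic clutter-rank selection
#'
#' Places the low-rank cut at the elbow of the log singular-value curve (the
#' largest second difference). When the spectrum has no pronounced elbow
#' (e.g. pure noise, or an all-equal degenerate spectrum) a cut of 1 is
#' returned with a warning. Deterministic.
#'
#' @param stack complex \linkS4class{ImageStack} with >= 8 frames.
#' @param minDrop minimum log10 second difference regarded as a real elbow.
#' @return a \linkS4class{FilterBand}.
#' @export
selectRankThreshold <- function(stack, minDrop = 0.5) {
  if (dim(stack@frames)[3] < 8) stop("need >= 8 frames for rank selection")
  s <- singularSpectrum(stack)
  s <- s[s > max(s) * 1e-12]
  if (length(s) < 3) {
    warning("degenerate singular spectrum; defaulting to low-rank cut 1")
    return(filterBand(1L))
  }
  ls <- log10(s)
  k <- 2:(length(s) - 1)
  d2 <- ls[k + 1] - 2 * ls[k] + ls[k - 1]
  if (max(d2) < minDrop) {
    warning("no pronounced elbow in the singular spectrum; low-rank cut 1")
    return(filterBand(1L))
  }
  filterBand(k[which.max(d2)] - 1L)
}
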