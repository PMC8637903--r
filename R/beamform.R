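#' Construct a beamforming pixel grid
#'
#' @param xlim,zlim lateral and depth ranges (mm).
#' @param dx,dz pixel spacing (mm).
#' @return an \linkS4class{ImageGrid}.
#' @export
imageGrid <- function(xlim, zlim, dx, dz = dx) {
  new("ImageGrid",
      x = seq(xlim[1] + dx / 2, xlim[2], by = dx),
      z = seq(zlim[1] + dz / 2, zlim[2], by = dz))
}

#' Default beamforming grid for an acquisition
#'
#' Lateral spacing lambda/4 at the centre frequency (~0.19 mm at 2 MHz),
#' axial spacing lambda/8 so the compressed pulse envelope is well sampled
#' for sub-pixel localization.
#'
#' @param params \linkS4class{AcquisitionParams}.
#' @param extent numeric(4) (xmin, xmax, zmin, zmax) mm.
#' @export
defaultImageGrid <- function(params, extent) {
  lambda <- .lambdaMm(params)
  imageGrid(extent[1:2], extent[3:4], dx = lambda / 4, dz = lambda / 8)
}

#' Matched-filter pulse compression
#'
#' Cross-correlates each channel with the excitation waveform (matched
#' filter), normalized by the waveform energy. The output time axis is
#' aligned so that an echo whose waveform starts at two-way delay tau has its
#' compressed peak at tau.
#'
#' @param channelRF nTime x nChannels numeric (or complex) matrix.
#' @param waveform the transmitted waveform (needs attribute \code{fs} in
#'   MHz when band weighting is requested).
#' @param weighting "none" for the pure matched filter; "hamming" or "hann"
#'   use a regularized inverse (mismatched) filter that equalizes the
#'   occupied band to the named window, trading a little SNR and mainlobe
#'   width for strongly suppressed range sidelobes. At this chirp's small
#'   time-bandwidth product the pure matched filter leaves axial sidelobes
#'   near -17 dB (spectral Fresnel ripple) that masquerade as spurious
#'   scatterers; the equalized filter removes them.
#' @param band optional c(low, high) MHz band of the weighting window;
#'   defaults to the waveform's occupied band estimated from its spectrum.
#' @return compressed matrix of the same dimensions.
#' @export
pulseCompress <- function(channelRF, waveform,
                          weighting = c("none", "hamming", "hann"),
                          band = NULL) {
  weighting <- match.arg(weighting)
  channelRF <- as.matrix(channelRF)
  if (length(waveform) == 0) stop("waveform must be non-empty")
  nt <- nrow(channelRF)
  lw <- length(waveform)
  if (lw > nt) stop("waveform longer than the RF record")
  n2 <- stats::nextn(nt + lw)
  pad <- function(m, n) rbind(m, matrix(0, n - nrow(m), ncol(m)))
  RF <- stats::mvfft(pad(channelRF, n2))
  W <- stats::fft(c(as.numeric(waveform), rep(0, n2 - lw)))
  filt <- Conj(W)
  norm <- sum(waveform^2)
  if (weighting != "none") {
    fs <- attr(waveform, "fs")
    if (is.null(fs)) stop("band weighting needs the waveform 'fs' attribute")
    if (is.null(band)) {
      # occupied band: where the spectrum exceeds -20 dB of its peak
      mag <- Mod(W[seq_len(n2 %/% 2)])
      f <- (seq_len(n2 %/% 2) - 1) / n2 * fs
      occ <- f[mag > max(mag) / 10]
      band <- range(occ)
    }
    f <- c(seq(0, n2 %/% 2), seq(-(n2 - n2 %/% 2 - 1), -1)) / n2 * fs
    u <- (abs(f) - band[1]) / max(band[2] - band[1], 1e-9)
    win <- ifelse(u >= 0 & u <= 1,
                  if (weighting == "hamming")
                    0.54 - 0.46 * cos(2 * pi * pmin(pmax(u, 0), 1))
                  else 0.5 - 0.5 * cos(2 * pi * pmin(pmax(u, 0), 1)),
                  0)
    # regularized inverse: in-band response equalized to the window shape
    eps <- 0.01 * max(Mod(W))^2
    filt <- win * Conj(W) / (Mod(W)^2 + eps)
    # unit response to the waveform itself
    norm <- Re(sum(W * filt)) / n2
  }
  cc <- stats::mvfft(RF * filt, inverse = TRUE) / n2
  Re(cc[seq_len(nt), , drop = FALSE]) / norm
}

#' Analytic signal along the time axis
#'
#' One-sided spectrum (Hilbert) transform of each column, so sub-sample
#' delays interpolate smoothly during beamforming.
#'
#' @param x numeric matrix (time x channels) or vector.
#' @return complex matrix/vector of the same shape.
#' @export
analyticSignal <- function(x) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  out <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  if (v) out[, 1] else out
}

# fused pulse compression + analytic conversion on a power-of-two padded
# length (one FFT pass; the separate public functions are exact but slower)
.compressAnalytic <- function(channelRF, waveform,
                              weighting = c("none", "hamming", "hann")) {
  weighting <- match.arg(weighting)
  channelRF <- as.matrix(channelRF)
  nt <- nrow(channelRF)
  lw <- length(waveform)
  if (lw > nt) stop("waveform longer than the RF record")
  n2 <- stats::nextn(nt + lw)
  RF <- stats::mvfft(rbind(channelRF, matrix(0, n2 - nt, ncol(channelRF))))
  W <- stats::fft(c(as.numeric(waveform), rep(0, n2 - lw)))
  filt <- Conj(W)
  norm <- sum(waveform^2)
  if (weighting != "none") {
    fs <- attr(waveform, "fs")
    mag <- Mod(W[seq_len(n2 %/% 2)])
    f <- (seq_len(n2 %/% 2) - 1) / n2 * fs
    band <- range(f[mag > max(mag) / 10])
    fall <- c(seq(0, n2 %/% 2), seq(-(n2 - n2 %/% 2 - 1), -1)) / n2 * fs
    u <- (abs(fall) - band[1]) / max(band[2] - band[1], 1e-9)
    win <- ifelse(u >= 0 & u <= 1,
                  if (weighting == "hamming")
                    0.54 - 0.46 * cos(2 * pi * pmin(pmax(u, 0), 1))
                  else 0.5 - 0.5 * cos(2 * pi * pmin(pmax(u, 0), 1)),
                  0)
    eps <- 0.01 * max(mag)^2
    filt <- win * Conj(W) / (Mod(W)^2 + eps)
    norm <- Re(sum(W * filt)) / n2
  }
  h <- rep(0, n2)
  h[1] <- 1; h[n2 / 2 + 1] <- 1; h[2:(n2 / 2)] <- 2
  out <- stats::mvfft(RF * (filt * h), inverse = TRUE) / n2
  out[seq_len(nt), , drop = FALSE] / norm
}

#' Delay-and-sum plane-wave beamforming
#'
#' For each pixel, sums analytic-signal channel samples at the geometric
#' delay (plane-wave transmit path + element receive path) / c, with receive
#' f-number aperture control and Hann apodization, normalized by the
#' apodization sum. Delays beyond the record contribute zero.
#'
#' @param channelRF nTime x nChannels matrix, ideally the analytic signal of
#'   compressed RF; a real matrix is converted via \code{analyticSignal}.
#' @param elementPositions lateral element coordinates (mm).
#' @param angle steering angle (degrees).
#' @param grid \linkS4class{ImageGrid}.
#' @param params \linkS4class{AcquisitionParams}.
#' @param fNumber receive f-number (default 1.5); 0 uses the full aperture.
#' @param channelDelaysUs optional per-channel delay corrections (us).
#' @return nz x nx complex matrix.
#' @export
dasBeamform <- function(channelRF, elementPositions, angle, grid, params,
                        fNumber = 1.5, channelDelaysUs = NULL) {
  if (!is.complex(channelRF)) channelRF <- analyticSignal(channelRF)
  if (is.null(channelDelaysUs))
    channelDelaysUs <- rep(0, length(elementPositions))
  nz <- length(grid@z); nx <- length(grid@x)
  px <- rep(grid@x, each = nz)
  pz <- rep(grid@z, times = nx)
  img <- dasBeamformCpp(channelRF, elementPositions, angle * pi / 180, px, pz,
                        .cMmUs(params), params@samplingRate,
                        .t0Us(params, angle), fNumber, channelDelaysUs)
  matrix(img, nz, nx)
}

#' Coherent plane-wave compounding
#'
#' Complex mean of per-angle beamformed images sharing the same grid.
#'
#' @param perAngleImages list of complex matrices with identical dimensions.
#' @return complex matrix.
#' @export
coherentCompound <- function(perAngleImages) {
  if (length(perAngleImages) < 1) stop("need at least one image")
  d <- dim(perAngleImages[[1]])
  for (img in perAngleImages)
    if (!identical(dim(img), d)) stop("images are not on the same grid")
  Reduce(`+`, perAngleImages) / length(perAngleImages)
}

#' Pixelwise envelope (magnitude)
#'
#' @param image complex matrix or array.
#' @return real object of the same shape.
#' @export
envelopeImage <- function(image) Mod(image)

#' Eigenspace-based minimum-variance beamforming (optional mode)
#'
#' Per-pixel spatial-smoothing covariance over a sliding subaperture;
#' the minimum-variance (Capon) weight vector is projected onto the signal
#' subspace spanned by eigenvectors whose eigenvalues reach delta times the
#' largest. Falls back to delay-and-sum when the covariance is degenerate.
#' An eigenspace-projected minimum-variance approximation, substantially
#' slower than \code{\link{dasBeamform}} and excluded from the package's
#' quantitative evaluation protocol.
#'
#' @inheritParams dasBeamform
#' @param subaperture sliding subaperture length (default half the channels).
#' @param delta signal-subspace eigenvalue threshold relative to the largest
#'   eigenvalue; 0 keeps the full space (pure minimum variance).
#' @param loading diagonal loading relative to the mean eigenvalue.
#' @return nz x nx complex matrix.
#' @export
esbBeamform <- function(channelRF, elementPositions, angle, grid, params,
                        subaperture = NULL, delta = 0.1, loading = 1e-2,
                        channelDelaysUs = NULL) {
  if (!is.complex(channelRF)) channelRF <- analyticSignal(channelRF)
  nch <- length(elementPositions)
  if (is.null(subaperture)) subaperture <- max(2L, floor(nch / 2))
  if (subaperture > nch) stop("subaperture larger than channel count")
  if (is.null(channelDelaysUs)) channelDelaysUs <- rep(0, nch)
  nz <- length(grid@z); nx <- length(grid@x)
  px <- rep(grid@x, each = nz)
  pz <- rep(grid@z, times = nx)
  D <- delayChannelsCpp(channelRF, elementPositions, angle * pi / 180, px, pz,
                        .cMmUs(params), params@samplingRate,
                        .t0Us(params, angle), channelDelaysUs)
  L <- subaperture
  K <- nch - L + 1
  a <- rep(1, L)
  out <- complex(length(px))
  for (p in seq_along(px)) {
    v <- D[p, ]
    subs <- vapply(seq_len(K), function(k) v[k:(k + L - 1)],
                   complex(L))
    subs <- matrix(subs, nrow = L)
    R <- tcrossprod(subs, Conj(subs)) / K
    trR <- Re(sum(diag(R)))
    if (trR <= .Machine$double.eps) {
      out[p] <- mean(v)
      next
    }
    R <- R + diag(L) * (loading * trR / L)
    w <- tryCatch(solve(R, a), error = function(e) NULL)
    if (is.null(w)) {
      out[p] <- mean(v)  # rank-deficient: DAS fallback
      next
    }
    w <- w / sum(Conj(a) * w)
    if (delta > 0) {
      eg <- eigen(R, symmetric = TRUE)
      keep <- eg$values >= delta * eg$values[1]
      Es <- eg$vectors[, keep, drop = FALSE]
      w <- Es %*% (Conj(t(Es)) %*% w)
    }
    out[p] <- sum(Conj(w) * rowMeans(subs))
  }
  matrix(out, nz, nx)
}
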