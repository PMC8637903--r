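# Shared test oracles and fixture builders.

# Exhaustively enumerate every valid partition of detections into
# frame-ordered chains under the model's gate (chains of length 1 are
# clutter). Independent of the sampler: a plain recursion over detections
# in frame order, appending each to an existing chain tail or opening a new
# one.
enumeratePartitions <- function(det, model) {
  n <- nrow(det)
  gateOK <- function(i, j) {
    df <- det$frame[j] - det$frame[i]
    df >= 1 && df <= model@maxGap + 1 &&
      sqrt((det$x[i] - det$x[j])^2 + (det$z[i] - det$z[j])^2) <=
        model@maxSpeed / model@frameRate * df +
        3 * model@measurementNoiseSigma
  }
  ord <- order(det$frame, seq_len(n))
  parts <- list()
  rec <- function(k, chains) {
    if (k > n) {
      parts[[length(parts) + 1]] <<- chains
      return(invisible())
    }
    i <- ord[k]
    rec(k + 1, c(chains, list(i)))
    for (ci in seq_along(chains)) {
      tail <- chains[[ci]][length(chains[[ci]])]
      if (gateOK(tail, i)) {
        ch2 <- chains
        ch2[[ci]] <- c(ch2[[ci]], i)
        rec(k + 1, ch2)
      }
    }
  }
  rec(1, list())
  parts
}

# best log-posterior over all enumerated partitions
oracleBestScore <- function(det, model) {
  parts <- enumeratePartitions(det, model)
  sc <- vapply(parts, function(pt) {
    partitionLogPosterior(pt[vapply(pt, length, integer(1)) >= 2], det, model)
  }, numeric(1))
  max(sc)
}

# canonical string for a partition (sorted chains) for set comparison
partitionKey <- function(partition) {
  chains <- vapply(partition, function(ch) paste(ch, collapse = "-"),
                   character(1))
  paste(sort(chains), collapse = "|")
}

# frame with one or more Gaussian blobs at sub-pixel positions (in pixel
# units) on an ImageGrid
blobFrame <- function(grid, centersPx, amplitude = 1, sigmaPx = 1.5,
                      noiseSd = 0) {
  nz <- length(grid@z)
  nx <- length(grid@x)
  fr <- matrix(0, nz, nx)
  for (k in seq_len(nrow(centersPx))) {
    cz <- centersPx[k, 1]
    cx <- centersPx[k, 2]
    fr <- fr + amplitude *
      outer(exp(-(seq_len(nz) - cz)^2 / (2 * sigmaPx^2)),
            exp(-(seq_len(nx) - cx)^2 / (2 * sigmaPx^2)))
  }
  if (noiseSd > 0) fr <- fr + matrix(rnorm(nz * nx, 0, noiseSd), nz, nx)
  fr
}

testGrid <- function(nz = 41, nx = 41, dx = 0.1, dz = 0.1) {
  imageGrid(c(0, nx * dx), c(0, nz * dz), dx = dx, dz = dz)
}

# small acquisition used across simulator tests
testParams <- function(...) {
  acquisitionParams(nChannels = 16L, nFrames = 4L, noiseSigma = 0, ...)
}

# complex stack with given per-frame images
stackFrom <- function(frames, grid, frameRate = 1500) {
  arr <- array(complex(real = 0), c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  new("ImageStack", frames = arr, grid = grid, frameRate = frameRate)
}

# phase unwrapping for instantaneous-frequency oracles
unwrapPhase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}
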