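emptyTrackSet <- function() new("TrackSet", tracks = list(), frameRate = 1500)

makeTrack <- function(frame, x, z, vx, vz) {
  data.frame(frame = frame, x = x, z = z, intensity = 1, vx = vx, vz = vz)
}

smallGrid <- list(xlim = c(0, 2), zlim = c(0, 2), cellSize = 0.01)

test_that("map accumulation averages speeds and conserves samples", {
  # one straight track at constant 30 mm/s; segment lengths chosen off the
  # cell-size multiples so the interpolation count is unambiguous
  tr <- makeTrack(1:3, c(0.5, 0.705, 0.91), 1, vx = 30, vz = 0)
  ts <- new("TrackSet", tracks = list(tr), frameRate = 1500)
  sr <- accumulateMaps(ts, smallGrid)
  expect_true(all(sr@velocity[sr@density > 0] == 30))
  # conservation: total density = number of interpolated samples
  # (each 0.205 mm segment densifies to ceiling(20.5) + 1 = 22 points, the
  # last of which is shared with the next segment)
  expect_equal(sum(sr@density), 2 * 21 + 1)
  # two overlapping tracks at 20 and 40 read 30 in shared cells
  trA <- makeTrack(1:2, c(0.5, 0.7), 1, vx = 20, vz = 0)
  trB <- makeTrack(1:2, c(0.5, 0.7), 1, vx = 40, vz = 0)
  sr2 <- accumulateMaps(new("TrackSet", tracks = list(trA, trB),
                            frameRate = 1500), smallGrid)
  shared <- sr2@density == 2
  expect_true(any(shared))
  expect_true(all(sr2@velocity[shared] == 30))
  # velocity values bounded by the contributing speeds
  expect_true(all(sr2@velocity[sr2@density > 0] >= 20 - 1e-9))
  expect_true(all(sr2@velocity[sr2@density > 0] <= 40 + 1e-9))
  # empty input
  sr0 <- accumulateMaps(emptyTrackSet(), smallGrid)
  expect_true(all(sr0@density == 0) && all(sr0@velocity == 0))
})

test_that("normalized MSE has its closed-form limits", {
  seg <- vesselSegment(rbind(c(0, 1), c(0, 3)), diameter = 0.5)
  ph <- buildVesselPhantom(list(seg), fieldExtent = c(-1, 1, 0, 4),
                          srSpacing = 0.01)
  grid <- srGrid(ph)
  # identical map: zero error
  perfect <- new("SRMap", density = truthMap(ph), velocity = truthMap(ph) * 0,
                 x = grid$x, z = grid$z, cellSize = grid$cellSize)
  expect_equal(computeMSE(perfect, ph), 0)
  # all-zero map: mean(truth^2) = occupancy fraction
  zero <- new("SRMap", density = truthMap(ph) * 0,
              velocity = truthMap(ph) * 0,
              x = grid$x, z = grid$z, cellSize = grid$cellSize)
  expect_equal(computeMSE(zero, ph), mean(truthMap(ph)))
  expect_equal(computeMSE(zero, ph, region = "bbox"),
               {
                 occ <- which(truthMap(ph) > 0, arr.ind = TRUE)
                 pad <- 50
                 zi <- max(1, min(occ[, 1]) - pad):min(nrow(truthMap(ph)),
                                                       max(occ[, 1]) + pad)
                 xi <- max(1, min(occ[, 2]) - pad):min(ncol(truthMap(ph)),
                                                       max(occ[, 2]) + pad)
                 mean(truthMap(ph)[zi, xi])
               })
  expect_error(computeMSE(new("SRMap", density = matrix(0, 2, 2),
                              velocity = matrix(0, 2, 2), x = 1:2, z = 1:2,
                              cellSize = 0.01), ph), "same grid")
  # bounded in [0, 1]
  mseVals <- c(computeMSE(perfect, ph), computeMSE(zero, ph))
  expect_true(all(mseVals >= 0 & mseVals <= 1))
})

test_that("FWHM diameter readout matches analytic profiles", {
  nz <- 300; nx <- 300
  x <- (seq_len(nx) - 0.5) * 0.01
  d <- matrix(0, nz, nx)
  rect <- abs(x - 1.5) <= 0.5            # 1.0 mm wide rectangle
  d[100:200, rect] <- 7
  sr <- new("SRMap", density = d, velocity = d * 0,
            x = x, z = (seq_len(nz) - 0.5) * 0.01, cellSize = 0.01)
  fw <- measureFWHMDiameter(sr, center = c(1.5, 1.5), direction = c(1, 0),
                            halfLength = 1.2, bandHalfLength = 0.4,
                            smoothSigma = 0)
  expect_equal(fw, 1.0, tolerance = 0.02)
  # smoothing preserves the edge half-maxima of a wide profile
  fwS <- measureFWHMDiameter(sr, center = c(1.5, 1.5), direction = c(1, 0),
                             halfLength = 1.2, bandHalfLength = 0.4,
                             smoothSigma = 0.05)
  expect_equal(fwS, 1.0, tolerance = 0.05)
  # single-cell impulse reads one cell width
  d2 <- matrix(0, nz, nx)
  d2[150, 150] <- 1
  sr2 <- new("SRMap", density = d2, velocity = d2 * 0, x = x,
             z = (seq_len(nz) - 0.5) * 0.01, cellSize = 0.01)
  fw2 <- measureFWHMDiameter(sr2, center = c(x[150], x[150]),
                             direction = c(1, 0), halfLength = 0.3,
                             bandHalfLength = 0.004, smoothSigma = 0)
  expect_equal(fw2, 0.01, tolerance = 1e-6)
  # flat zero profile has no peak
  sr3 <- new("SRMap", density = d2 * 0, velocity = d2 * 0, x = x,
             z = (seq_len(nz) - 0.5) * 0.01, cellSize = 0.01)
  expect_error(measureFWHMDiameter(sr3, center = c(1.5, 1.5)), "peak")
})

test_that("image SNR is the peak-over-background-RMS in dB", {
  img <- matrix(1, 20, 20)
  img[5, 5] <- 10
  sig <- matrix(FALSE, 20, 20); sig[1:10, 1:10] <- TRUE
  bg <- !sig
  expect_equal(computeSNR(img, sig, bg), 20)
  expect_equal(computeSNR(matrix(1, 4, 4),
                          diag(4) == 1, diag(4) != 1), 0)
  expect_error(computeSNR(matrix(0, 4, 4), diag(4) == 1, diag(4) != 1),
               "zero")
  expect_error(computeSNR(img, sig, sig), "disjoint")
})

test_that("resolution gain is the PSF-to-localization width ratio", {
  grid <- testGrid(61, 61, dx = 0.05, dz = 0.05)
  env <- blobFrame(grid, cbind(31, 31), sigmaPx = 8)  # fwhm = 2.355*8*0.05
  stack <- stackFrom(list(env + 0i), grid)
  set.seed(5)
  reps <- data.frame(x = rnorm(50, 1.5, 0.01), z = rnorm(50, 1.5, 0.01))
  rg <- resolutionGain(stack, reps)
  expect_equal(rg$fwhmMm, 2.355 * 8 * 0.05, tolerance = 0.02)
  expect_equal(rg$gain, rg$fwhmMm / (2.355 * sd(reps$x)), tolerance = 1e-9)
  expect_error(resolutionGain(stack, reps[1:5, ]), "10")
  expect_error(resolutionGain(stack, data.frame(x = rep(1, 20),
                                                z = rep(1, 20))),
               "zero")
})

test_that("maximum tracked depth over all detections", {
  expect_equal(maxTrackedDepth(emptyTrackSet()), 0)
  tr <- makeTrack(1:2, c(0, 0), c(30, 40), 0, 30)
  ts <- new("TrackSet", tracks = list(tr), frameRate = 1500)
  expect_equal(maxTrackedDepth(ts), 40)
})
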