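test_that("isolated blobs are detected at their peak pixels", {
  grid <- testGrid(41, 41)
  fr <- blobFrame(grid, cbind(21, 21))
  det <- detectCandidates(fr, grid, minSeparation = 0.3)
  expect_equal(nrow(det), 1L)
  expect_equal(c(det$iz, det$ix), c(21, 21))
  # blank frame
  expect_equal(nrow(detectCandidates(matrix(0, 41, 41), grid)), 0L)
  # two blobs separated by ~3 PSF widths
  fr2 <- blobFrame(grid, rbind(c(12, 12), c(30, 30)))
  det2 <- detectCandidates(fr2, grid, minSeparation = 0.3)
  det2 <- det2[order(det2$iz), ]
  expect_equal(nrow(det2), 2L)
  expect_equal(det2$iz, c(12, 30))
  expect_equal(det2$ix, c(12, 30))
})

test_that("minimum separation suppresses the weaker of close maxima", {
  grid <- testGrid(41, 41)
  fr <- blobFrame(grid, cbind(18, 20), amplitude = 1) +
    blobFrame(grid, cbind(24, 20), amplitude = 0.6)
  near <- detectCandidates(fr, grid, minSeparation = 1.0)
  expect_equal(nrow(near), 1L)
  both <- detectCandidates(fr, grid, minSeparation = 0.3)
  expect_gte(nrow(both), 2L)
})

test_that("sub-pixel refinement recovers planted fractional positions", {
  grid <- testGrid(41, 41)
  # symmetric blob exactly on a pixel centre: refinement is the identity
  fr <- blobFrame(grid, cbind(21, 21))
  det <- detectCandidates(fr, grid, minSeparation = 0.3)
  ref <- refineSubpixel(fr, grid, det)
  expect_equal(ref$x, xCoords(grid)[21], tolerance = 1e-10)
  expect_equal(ref$z, zCoords(grid)[21], tolerance = 1e-10)
  # plant-and-recover over 100 noise draws at (20.70, 10.30) pixels
  set.seed(11)
  errs <- matrix(NA_real_, 100, 2)
  for (k in 1:100) {
    frk <- blobFrame(grid, cbind(20.70, 10.30), noiseSd = 0.01)
    dk <- detectCandidates(frk, grid, minSeparation = 0.5)
    dk <- dk[which.max(dk$intensity), ]
    rk <- refineSubpixel(frk, grid, dk)
    errs[k, ] <- c(rk$z - zCoords(grid)[1] - 19.70 * 0.1,
                   rk$x - xCoords(grid)[1] - 9.30 * 0.1)
  }
  # within 0.1 pixel (0.01 mm here) on average, both axes
  expect_lt(abs(mean(errs[, 1])), 0.01)
  expect_lt(abs(mean(errs[, 2])), 0.01)
  expect_lt(sd(errs[, 1]), 0.01)
})

test_that("gaussian-fit refinement matches the planted centre", {
  grid <- testGrid(41, 41)
  fr <- blobFrame(grid, cbind(20.6, 10.4))
  det <- detectCandidates(fr, grid, minSeparation = 0.3)
  ref <- refineSubpixel(fr, grid, det[1, ], method = "gaussian")
  expect_equal(ref$z, zCoords(grid)[1] + 19.6 * 0.1, tolerance = 0.01)
  expect_equal(ref$x, xCoords(grid)[1] + 9.4 * 0.1, tolerance = 0.01)
})

test_that("border windows fall back to the unrefined position", {
  grid <- testGrid(21, 21)
  fr <- blobFrame(grid, cbind(2, 2), sigmaPx = 1)
  det <- data.frame(x = xCoords(grid)[2], z = zCoords(grid)[2], ix = 2L,
                    iz = 2L, intensity = 1, snr = 10)
  expect_warning(ref <- refineSubpixel(fr, grid, det, windowHalfwidth = 4),
                 "clipped")
  expect_equal(ref$x, det$x)
})

test_that("localization is translation-equivariant over whole pixels", {
  grid <- testGrid(41, 41)
  set.seed(12)
  base <- blobFrame(grid, cbind(15.3, 12.7), noiseSd = 0.005)
  shifted <- matrix(0, 41, 41)
  shifted[6:41, 9:41] <- base[1:36, 1:33]  # shift +5 rows, +8 cols
  d1 <- localizeStack(stackFrom(list(base + 0i), grid))
  d2 <- localizeStack(stackFrom(list(shifted + 0i), grid))
  d1 <- d1[which.max(d1$intensity), ]
  d2 <- d2[which.max(d2$intensity), ]
  expect_equal(d2$z - d1$z, 5 * 0.1, tolerance = 1e-6)
  expect_equal(d2$x - d1$x, 8 * 0.1, tolerance = 1e-6)
})
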