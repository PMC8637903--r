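test_that("rank-1 static background is removed almost entirely", {
  grid <- testGrid(20, 20)
  set.seed(2)
  static <- matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 20, 20)
  stack <- stackFrom(rep(list(static), 12), grid)
  filt <- svdClutterFilter(stack, filterBand(1))
  expect_lt(sum(Mod(filt@frames)^2) / sum(Mod(stack@frames)^2), 1e-10)
})

test_that("the identity band returns the stack unchanged", {
  grid <- testGrid(10, 10)
  set.seed(3)
  frames <- lapply(1:6, function(i)
    matrix(complex(real = rnorm(100), imaginary = rnorm(100)), 10, 10))
  stack <- stackFrom(frames, grid)
  expect_identical(svdClutterFilter(stack, filterBand(0)), stack)
  expect_error(svdClutterFilter(stack, filterBand(4, 2)), "rank")
})

test_that("a moving bubble survives the clutter cut while background dies", {
  grid <- testGrid(40, 40)
  set.seed(4)
  static <- 10 * blobFrame(grid, cbind(c(8, 30), c(30, 8)), sigmaPx = 3)
  frames <- lapply(1:16, function(f)
    static + blobFrame(grid, cbind(4 + 2 * f, 20), amplitude = 1))
  stack <- stackFrom(frames, grid)
  filt <- svdClutterFilter(stack, filterBand(1))
  # bubble pixels: the moving blob path; background: static blob cores
  pathMask <- matrix(FALSE, 40, 40)
  for (f in 1:16) pathMask[4 + 2 * f + (-1:1), 19:21] <- TRUE
  bgMask <- matrix(FALSE, 40, 40)
  bgMask[7:9, 29:31] <- TRUE
  bgMask[29:31, 7:9] <- TRUE
  inB <- sum(Mod(stack@frames[rep(pathMask, 16)])^2)
  outB <- sum(Mod(filt@frames[rep(pathMask, 16)])^2)
  inS <- sum(Mod(stack@frames[rep(bgMask, 16)])^2)
  outS <- sum(Mod(filt@frames[rep(bgMask, 16)])^2)
  expect_gt(outB / inB, 0.5)
  expect_lt(outS / inS, 0.01)
})

test_that("singular energy is conserved by the projection split", {
  grid <- testGrid(15, 15)
  set.seed(5)
  frames <- lapply(1:10, function(i)
    matrix(complex(real = rnorm(225), imaginary = rnorm(225)), 15, 15))
  stack <- stackFrom(frames, grid)
  band <- filterBand(2, 1)
  filt <- svdClutterFilter(stack, band)
  removed <- sum(Mod(stack@frames - filt@frames)^2)
  retained <- sum(Mod(filt@frames)^2)
  total <- sum(Mod(stack@frames)^2)
  expect_equal(removed + retained, total, tolerance = 1e-10)
  # the removed energy equals the dropped singular values' energy
  s <- singularSpectrum(stack)
  expect_equal(removed, sum(s[c(1, 2, 10)]^2), tolerance = 1e-8)
  # the filter is the projection off the removed temporal subspace: the
  # output carries no energy along the dropped right singular vectors
  X <- stack@frames; dim(X) <- c(225, 10)
  Xf <- filt@frames; dim(Xf) <- c(225, 10)
  H <- Conj(t(X)) %*% X
  V <- eigen(H, symmetric = TRUE)$vectors[, c(1, 2, 10)]
  expect_lt(sum(Mod(Xf %*% V)^2), 1e-16 * sum(Mod(X)^2))
  # re-projecting the output off the same subspace changes nothing
  reproj <- Xf - (Xf %*% V) %*% Conj(t(V))
  expect_equal(reproj, Xf, tolerance = 1e-10)
})

test_that("rank selection finds a planted spectral elbow", {
  set.seed(6)
  npix <- 400; nf <- 16
  U <- qr.Q(qr(matrix(rnorm(npix * nf), npix, nf)))
  V <- qr.Q(qr(matrix(rnorm(nf * nf), nf, nf)))
  d <- c(100, 85, 70, 0.6, 0.55, 0.5, 0.45, 0.4, 0.35, 0.3, 0.25, 0.2,
         0.15, 0.12, 0.1, 0.08)
  X <- U %*% (d * t(V))
  stack <- new("ImageStack",
               frames = array(as.complex(X), c(20, 20, nf)),
               grid = testGrid(20, 20), frameRate = 1000)
  band <- selectRankThreshold(stack)
  expect_equal(band@lowRankCut, 3L)
  # rank-1-dominant spectrum cuts a single component
  d1 <- c(100, rep(0.5, nf - 1)) * (1 - seq(0, 0.05, length.out = nf))
  X1 <- U %*% (d1 * t(V))
  stack1 <- new("ImageStack",
                frames = array(as.complex(X1), c(20, 20, nf)),
                grid = testGrid(20, 20), frameRate = 1000)
  expect_equal(selectRankThreshold(stack1)@lowRankCut, 1L)
})

test_that("spectra without an elbow fall back to cut 1 with a warning", {
  set.seed(7)
  frames <- lapply(1:12, function(i)
    matrix(complex(real = rnorm(400), imaginary = rnorm(400)), 20, 20))
  stack <- stackFrom(frames, testGrid(20, 20))
  expect_warning(band <- selectRankThreshold(stack), "elbow")
  expect_equal(band@lowRankCut, 1L)
})
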