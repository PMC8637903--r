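test_that("matched filtering concentrates the chirp and gains SNR", {
  p <- acquisitionParams(noiseSigma = 0)
  w <- synthesizeChirp(p)
  nt <- 1024L
  s0 <- 301L
  clean <- matrix(0, nt, 1)
  clean[s0:(s0 + length(w) - 1), 1] <- w
  # Monte-Carlo SNR oracle: peak amplitude over noise sd, before vs after
  set.seed(1)
  rawSnr <- cmpSnr <- numeric(40)
  for (k in 1:40) {
    x <- clean + matrix(rnorm(nt, 0, 0.05), nt, 1)
    rawSnr[k] <- max(abs(x)) / 0.05
    pc <- pulseCompress(x, w)
    noiseSd <- sd(pc[700:1000, 1])
    cmpSnr[k] <- max(abs(pc[, 1])) / noiseSd
  }
  gainDb <- 20 * log10(mean(cmpSnr) / mean(rawSnr))
  # at least the time-bandwidth compression gain, 10 log10(1.4 MHz x 6 us)
  expect_gt(gainDb, 10 * log10(8.4))
  # peak location unbiased under noise: matches the noiseless peak
  pk0 <- which.max(Mod(analyticSignal(pulseCompress(clean, w)[, 1])))
  expect_equal(pk0, s0)
})

test_that("compressed mainlobe width matches the autocorrelation oracle", {
  p <- acquisitionParams(noiseSigma = 0)
  w <- synthesizeChirp(p)
  nt <- 1024L
  x <- matrix(0, nt, 1)
  x[301:(300 + length(w)), 1] <- w
  env <- Mod(analyticSignal(pulseCompress(x, w)[, 1]))
  # -3 dB width on the compressed envelope, in us at 20 MHz
  half <- max(env) / sqrt(2)
  wSamples <- sum(env > half)
  widthUs <- wSamples / 20
  # oracle: width measured on the waveform's own autocorrelation envelope
  ac <- stats::convolve(as.numeric(w), as.numeric(w), type = "open")
  acEnv <- Mod(analyticSignal(ac))
  acWidth <- sum(acEnv > max(acEnv) / sqrt(2)) / 20
  expect_equal(widthUs, acWidth, tolerance = 0.15)
  # on the order of 1/bandwidth (0.71 us for the 1.4 MHz sweep)
  expect_lt(widthUs, 2 / 1.4)
  expect_gt(widthUs, 0.25 / 1.4)
})

test_that("pulse compression edge cases", {
  p <- acquisitionParams()
  w <- synthesizeChirp(p)
  expect_true(all(pulseCompress(matrix(0, 400, 3), w) == 0))
  expect_error(pulseCompress(matrix(0, 50, 2), w), "longer")
})

test_that("delay-and-sum focuses a point scatterer at its true position", {
  p <- acquisitionParams(nChannels = 64L, noiseSigma = 0)
  w <- synthesizeChirp(p)
  elems <- elementPositions(p)
  grid <- imageGrid(c(-6, 6), c(20, 30), dx = 0.2, dz = 0.1)
  img1 <- NULL
  for (bx in c(0, 2)) {
    bub <- data.frame(x = bx, z = 25, amplitude = 1)
    rf <- simulateRFFrame(bub, elems, 0, w, p, nTime = 1100)
    img <- dasBeamform(analyticSignal(pulseCompress(rf, w)), elems, 0, grid, p)
    e <- Mod(img)
    pk <- which(e == max(e), arr.ind = TRUE)[1, ]
    expect_lt(abs(xCoords(grid)[pk[2]] - bx), 0.21)
    expect_lt(abs(zCoords(grid)[pk[1]] - 25), 0.11)
    if (bx == 0) img1 <- img
  }
  # all-zero RF gives an all-zero image
  expect_true(all(dasBeamform(matrix(complex(real = 0), 1100, 64), elems, 0,
                              grid, p) == 0))
  # linearity of DAS
  rfA <- simulateRFFrame(data.frame(x = 0, z = 25, amplitude = 1), elems, 0,
                         w, p, nTime = 1100)
  rfB <- simulateRFFrame(data.frame(x = -3, z = 22, amplitude = 1), elems, 0,
                         w, p, nTime = 1100)
  iA <- dasBeamform(analyticSignal(rfA), elems, 0, grid, p)
  iB <- dasBeamform(analyticSignal(rfB), elems, 0, grid, p)
  iAB <- dasBeamform(analyticSignal(rfA + rfB), elems, 0, grid, p)
  expect_equal(iAB, iA + iB, tolerance = 1e-8)
})

test_that("coherent compounding narrows the lateral point spread", {
  p <- acquisitionParams(nChannels = 64L, noiseSigma = 0)
  w <- synthesizeChirp(p)
  elems <- elementPositions(p)
  grid <- imageGrid(c(-6, 6), c(23, 27), dx = 0.1, dz = 0.1)
  bub <- data.frame(x = 0, z = 25, amplitude = 1)
  imgs <- lapply(p@angles, function(a) {
    rf <- simulateRFFrame(bub, elems, a, w, p, nTime = 1100)
    dasBeamform(analyticSignal(pulseCompress(rf, w)), elems, a, grid, p)
  })
  lat <- function(img) {
    e <- Mod(img)
    pk <- which(e == max(e), arr.ind = TRUE)[1, ]
    prof <- e[pk[1], ]
    sum(prof > max(prof) / 2) * 0.1
  }
  wide <- lat(imgs[[3]])            # single 0-degree transmit
  narrow <- lat(coherentCompound(imgs))
  expect_lte(narrow, wide + 1e-9)
  # compounding identities
  expect_equal(coherentCompound(list(imgs[[1]])), imgs[[1]])
  expect_equal(coherentCompound(imgs[c(3, 3, 3)]), imgs[[3]])
  expect_error(coherentCompound(list(imgs[[1]], imgs[[1]][1:10, 1:10])),
               "same grid")
})

test_that("envelope is the pixelwise magnitude", {
  m <- matrix(complex(real = c(3, 0, 1), imaginary = c(4, 0, 0)), 1, 3)
  expect_equal(envelopeImage(m), matrix(c(5, 0, 1), 1, 3))
})

test_that("eigenspace beamformer agrees with DAS on a point and suppresses noise", {
  p <- acquisitionParams(nChannels = 16L, noiseSigma = 0, samplingRate = 20)
  w <- synthesizeChirp(p)
  elems <- elementPositions(p)
  grid <- imageGrid(c(-2, 2), c(14, 17), dx = 0.2, dz = 0.15)
  bub <- data.frame(x = 0, z = 15.5, amplitude = 1)
  rf <- analyticSignal(pulseCompress(
    simulateRFFrame(bub, elems, 0, w, p, nTime = 700), w))
  das <- Mod(dasBeamform(rf, elems, 0, grid, p, fNumber = 0))
  esb <- Mod(esbBeamform(rf, elems, 0, grid, p, subaperture = 8))
  pkD <- which(das == max(das), arr.ind = TRUE)[1, ]
  pkE <- which(esb == max(esb), arr.ind = TRUE)[1, ]
  # peak within one pixel of the DAS peak
  expect_lte(max(abs(unname(pkE) - unname(pkD))), 1)
  expect_error(esbBeamform(rf, elems, 0, grid, p, subaperture = 40),
               "subaperture")
  # noise-only input: eigenspace output energy below DAS energy
  set.seed(4)
  eD <- eE <- numeric(5)
  for (k in 1:5) {
    nz <- analyticSignal(matrix(rnorm(700 * 16), 700, 16))
    eD[k] <- sum(Mod(dasBeamform(nz, elems, 0, grid, p, fNumber = 0))^2)
    eE[k] <- sum(Mod(esbBeamform(nz, elems, 0, grid, p, subaperture = 8))^2)
  }
  expect_lt(mean(eE), mean(eD))
})

test_that("delta = 0 keeps the full space and reproduces minimum variance", {
  p <- acquisitionParams(nChannels = 12L, noiseSigma = 0)
  w <- synthesizeChirp(p)
  elems <- elementPositions(p)
  grid <- imageGrid(c(-1, 1), c(14.5, 16), dx = 0.25, dz = 0.25)
  rf <- analyticSignal(pulseCompress(
    simulateRFFrame(data.frame(x = 0, z = 15, amplitude = 1), elems, 0, w, p,
                    nTime = 700), w))
  esb0 <- esbBeamform(rf, elems, 0, grid, p, subaperture = 6, delta = 0)
  # independent minimum-variance oracle on the delayed channel matrix
  D <- ChirpULM:::delayChannelsCpp(
    rf, elems, 0, rep(xCoords(grid), each = length(zCoords(grid))),
    rep(zCoords(grid), times = length(xCoords(grid))), 1.54, 20, 0,
    rep(0, 12))
  L <- 6; K <- 12 - L + 1; a <- rep(1, L)
  mv <- complex(nrow(D))
  for (q in seq_len(nrow(D))) {
    subs <- vapply(seq_len(K), function(k) D[q, k:(k + L - 1)], complex(L))
    subs <- matrix(subs, nrow = L)
    R <- tcrossprod(subs, Conj(subs)) / K
    R <- R + diag(L) * (1e-2 * Re(sum(diag(R))) / L)
    wv <- solve(R, a)
    wv <- wv / sum(Conj(a) * wv)
    mv[q] <- sum(Conj(wv) * rowMeans(subs))
  }
  expect_equal(as.vector(esb0), mv, tolerance = 1e-8)
})
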