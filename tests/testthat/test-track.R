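test_that("partition posterior has the closed-form clutter score", {
  m <- motionModel(frameRate = 100, fieldArea = 50, clutterRate = 2,
                   minTrackLength = 2)
  det <- data.frame(frame = 1:6, x = runif(6), z = runif(6))
  expect_equal(partitionLogPosterior(list(), det, m),
               6 * (log(2) - log(50)))
  expect_equal(partitionLogPosterior(list(),
                                     det[0, ], m), 0)
})

test_that("a linear detection sequence scores higher as one track", {
  m <- motionModel(frameRate = 100, fieldArea = 50, maxSpeed = 30,
                   measurementNoiseSigma = 0.05, processNoiseSigma = 0.05,
                   minTrackLength = 2)
  det <- data.frame(frame = 1:5, x = 0.1 * (1:5), z = 2)
  asTrack <- partitionLogPosterior(list(1:5), det, m)
  asClutter <- partitionLogPosterior(list(), det, m)
  expect_gt(asTrack, asClutter)
})

test_that("partition validation rejects invariant violations", {
  m <- motionModel(frameRate = 100, maxGap = 1, minTrackLength = 2)
  det <- data.frame(frame = c(1, 2, 2, 5), x = c(0, 0.1, 0.5, 0.2), z = 1)
  expect_error(partitionLogPosterior(list(c(2, 1)), det, m), "increase")
  expect_error(partitionLogPosterior(list(c(2, 4)), det, m), "gap")
  mWide <- motionModel(frameRate = 100, maxGap = 5, minTrackLength = 2)
  expect_error(partitionLogPosterior(list(c(1, 2), c(2, 4)), det, mWide),
               "disjoint")
  expect_error(partitionLogPosterior(list(3L), det, m), "at least 2")
})

test_that("unambiguous motion yields a single complete track", {
  m <- motionModel(frameRate = 100, fieldArea = 100, maxSpeed = 50,
                   minTrackLength = 5)
  det <- data.frame(frame = 1:10, x = seq(0, 2, length.out = 10), z = 5)
  r <- mcmcdaTrack(det, m, nIterations = 2000, seed = 3)
  expect_length(trackList(r$tracks), 1)
  expect_equal(nrow(trackList(r$tracks)[[1]]), 10)
  # empty input
  r0 <- mcmcdaTrack(det[0, ], m, seed = 1)
  expect_length(trackList(r0$tracks), 0)
  # invalid move probabilities
  expect_error(mcmcdaTrack(det, m, seed = 1,
                           moveProbabilities = c(toggle = 0.5, switch = 0.2)),
               "distribution")
})

test_that("the MCMC MAP matches exhaustive partition enumeration", {
  set.seed(42)
  for (trial in 1:6) {
    nf <- 4
    det <- rbind(
      data.frame(frame = 1:nf, x = 0.1 * (1:nf) + rnorm(nf, 0, 0.03),
                 z = 2 + rnorm(nf, 0, 0.03)),
      data.frame(frame = sample(1:nf, 3), x = runif(3, 0, 1),
                 z = runif(3, 1.5, 2.5)))
    det <- det[order(det$frame), ]
    rownames(det) <- NULL
    m <- motionModel(frameRate = 100, maxSpeed = 30, minTrackLength = 2,
                     fieldArea = 10, measurementNoiseSigma = 0.04,
                     processNoiseSigma = 0.03)
    best <- oracleBestScore(det, m)
    r <- mcmcdaTrack(det, m, nIterations = 5000, seed = trial,
                     init = "clutter")
    expect_equal(r$logPosterior, best, tolerance = 1e-9)
  }
})

test_that("crossing targets: MCMC matches the oracle, greedy linking swaps", {
  # two constant-velocity bubbles crossing mid-sequence
  n <- 4
  t1 <- data.frame(frame = 1:n, x = seq(0.1, 0.85, length.out = n), z = 2,
                   id = 1)
  t2 <- data.frame(frame = 1:n, x = seq(0.9, 0.15, length.out = n),
                   z = 2.02, id = 2)
  det <- rbind(t1, t2)
  det <- det[order(det$frame, det$x), ]
  rownames(det) <- NULL
  m <- motionModel(frameRate = 10, maxSpeed = 4, minTrackLength = 2,
                   fieldArea = 10, measurementNoiseSigma = 0.03,
                   processNoiseSigma = 0.02, velocityKappa = 0.02)
  best <- oracleBestScore(det, m)
  r <- mcmcdaTrack(det, m, nIterations = 20000, seed = 5, init = "clutter")
  expect_equal(r$logPosterior, best, tolerance = 1e-9)
  # the MAP keeps each bubble's identity: every track is one id
  pureMap <- vapply(r$partition, function(ch)
    length(unique(det$id[ch])) == 1, logical(1))
  expect_true(all(pureMap))
  # greedy nearest-neighbour linking mixes identities at the crossing
  nn <- nnTrack(det, m, minLength = 2)
  mixed <- vapply(attr(nn, "chains"), function(ch)
    length(unique(det$id[ch])) > 1, logical(1))
  expect_true(any(mixed))
})

test_that("nearest-neighbour baseline solves easy scenes like the sampler", {
  m <- motionModel(frameRate = 100, fieldArea = 100, maxSpeed = 50,
                   minTrackLength = 5)
  det <- rbind(
    data.frame(frame = 1:10, x = seq(0, 2, length.out = 10), z = 5),
    data.frame(frame = 1:10, x = seq(0, -2, length.out = 10), z = 15))
  det <- det[order(det$frame), ]
  nn <- nnTrack(det, m)
  mc <- mcmcdaTrack(det, m, nIterations = 3000, seed = 2)
  expect_length(trackList(nn), 2)
  expect_equal(partitionKey(attr(nn, "chains")), partitionKey(mc$partition))
})

test_that("the chain's stationary distribution matches the posterior", {
  det <- data.frame(frame = c(1, 2, 3), x = c(0, 0.15, 0.32),
                    z = c(1, 1.05, 0.95))
  m <- motionModel(frameRate = 100, maxSpeed = 40, minTrackLength = 2,
                   fieldArea = 10, measurementNoiseSigma = 0.08,
                   processNoiseSigma = 0.05)
  parts <- enumeratePartitions(det, m)
  lp <- vapply(parts, function(pt)
    partitionLogPosterior(pt[vapply(pt, length, integer(1)) >= 2], det, m),
    numeric(1))
  # canonical form drops singleton (clutter) chains, matching the sampler
  keys <- vapply(parts, function(pt)
    partitionKey(pt[lengths(pt) >= 2]), character(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  r <- mcmcdaTrack(det, m, nIterations = 200000, burnIn = 5000, seed = 7,
                   init = "clutter", keepSamples = TRUE, thin = 25)
  # samples are successor strings; convert to partition keys
  sampKey <- vapply(strsplit(r$samples, ","), function(sv) {
    succ <- as.integer(sv)
    pred <- integer(length(succ))
    pred[succ[succ != 0]] <- which(succ != 0)
    partitionKey(ChirpULM:::.chainsFromSucc(succ, pred))
  }, character(1))
  obs <- table(factor(sampKey, levels = keys))
  expected <- p * sum(obs)
  chisq <- sum((as.numeric(obs) - expected)^2 / pmax(expected, 1e-9))
  pval <- pchisq(chisq, df = length(keys) - 1, lower.tail = FALSE)
  expect_gt(pval, 1e-3)
})

test_that("track recovery stays pure on a five-bubble stream with clutter", {
  set.seed(21)
  nf <- 40
  truth <- lapply(1:5, function(b)
    data.frame(frame = 1:nf, x = 0.3 * (1:nf) / 10 + 0.2,
               z = 2 * b, id = b))
  det <- do.call(rbind, truth)
  det$x <- det$x + rnorm(nrow(det), 0, 0.02)
  det$z <- det$z + rnorm(nrow(det), 0, 0.02)
  det <- det[runif(nrow(det)) < 0.9, ]          # p_detect = 0.9
  clutter <- data.frame(frame = sample(1:nf, nf, replace = TRUE),
                        x = runif(nf, 0, 2), z = runif(nf, 0, 12),
                        id = 0)
  det <- rbind(det, clutter)
  det <- det[order(det$frame), ]
  rownames(det) <- NULL
  m <- motionModel(frameRate = 100, maxSpeed = 50, minTrackLength = 5,
                   fieldArea = 24, measurementNoiseSigma = 0.03,
                   processNoiseSigma = 0.03, clutterRate = 1)
  r <- mcmcdaTrack(det, m, nIterations = 15000, seed = 9)
  chains <- r$partition[vapply(r$partition, length, integer(1)) >= 5]
  # detection-level purity under majority assignment
  purity <- vapply(chains, function(ch) {
    ids <- det$id[ch]
    max(table(ids)) / length(ids)
  }, numeric(1))
  nAssigned <- sum(vapply(chains, length, integer(1)))
  expect_gte(weighted.mean(purity, vapply(chains, length, integer(1))), 0.9)
  # most true detections recovered
  expect_gt(nAssigned, 0.8 * sum(det$id > 0))
})

test_that("velocities follow displacement over time", {
  tr <- data.frame(frame = 1:20, x = 0.02 * (1:20), z = 3,
                   intensity = 1)
  v <- estimateVelocities(tr, 1500)
  expect_equal(sqrt(v$vx^2 + v$vz^2), rep(30, 20), tolerance = 1e-9)
  # stationary detections
  v0 <- estimateVelocities(transform(tr, x = 1), 1500)
  expect_true(all(v0$vx == 0 & v0$vz == 0))
  expect_error(estimateVelocities(tr[1, ], 1500), "length >= 2")
})

test_that("central differences are exact for quadratic motion inside the track", {
  fr <- seq(1, 41, by = 2)                     # gaps of one frame throughout
  t <- fr / 100
  tr <- data.frame(frame = fr, x = 3 * t^2 - t, z = 2 * t^2, intensity = 1)
  v <- estimateVelocities(tr, 100, halfWindow = 3L, smoothWindow = 1L)
  interior <- 4:(nrow(tr) - 3)
  expect_equal(v$vx[interior], (6 * t - 1)[interior], tolerance = 1e-9)
  expect_equal(v$vz[interior], (4 * t)[interior], tolerance = 1e-9)
})

test_that("speeds never exceed the motion model's gate", {
  set.seed(30)
  tr <- data.frame(frame = 1:30, x = cumsum(rnorm(30, 0, 0.3)),
                   z = cumsum(rnorm(30, 0, 0.3)), intensity = 1)
  v <- estimateVelocities(tr, 1500, maxSpeed = 100)
  expect_true(all(sqrt(v$vx^2 + v$vz^2) <= 100 + 1e-9))
})
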