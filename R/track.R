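# Multi-target tracking by Markov chain Monte Carlo data association.
#
# A partition assigns every detection to exactly one track (a frame-ordered
# chain of detections) or to clutter. Internally a partition is a set of
# directed links between detections in nearby frames: each detection has at
# most one predecessor and one successor, chains of length >= 2 are tracks,
# isolated detections are clutter. The sampler proposes symmetric moves on
# the link set -- "toggle" (add/remove one feasible link, which depending on
# context is a track birth, death, extension, reduction, split or merge) and
# "switch" (exchange the partners of two links, the classic identity swap at
# crossings) -- so Metropolis-Hastings acceptance reduces to the posterior
# ratio.

#' Construct a microbubble motion/association model
#'
#' Nearly-constant-velocity Kalman motion model plus the association priors
#' (detection probability, Poisson clutter, track births) used to score
#' partitions of detections into tracks and clutter.
#'
#' @param processNoiseSigma per-frame position diffusion (mm); default 0.05.
#' @param measurementNoiseSigma localization noise (mm); default 0.05.
#' @param maxSpeed hard speed gate (mm/s); default 100 (phantom mode).
#' @param pDetect per-frame detection probability; default 0.9.
#' @param clutterRate expected false detections per frame; default 1.
#' @param birthRate expected track births per frame; default 0.01.
#' @param fieldArea imaging-field area (mm^2) for the spatial densities;
#'   default 600.
#' @param maxGap maximum missed frames within a track; default 2.
#' @param minTrackLength minimum detections per reported track; default 5.
#' @param frameRate compounded frame rate (Hz); default 1500.
#' @param velocityKappa velocity-diffusion fraction of the Kalman model;
#'   default 0.1.
#' @return a \linkS4class{MotionModel}.
#' @export
motionModel <- function(processNoiseSigma = 0.05, measurementNoiseSigma = 0.05,
                        maxSpeed = 100, pDetect = 0.9, clutterRate = 1,
                        birthRate = 0.01, fieldArea = 600, maxGap = 2L,
                        minTrackLength = 5L, frameRate = 1500,
                        velocityKappa = 0.1) {
  new("MotionModel", processNoiseSigma = processNoiseSigma,
      measurementNoiseSigma = measurementNoiseSigma, maxSpeed = maxSpeed,
      pDetect = pDetect, clutterRate = clutterRate, birthRate = birthRate,
      fieldArea = fieldArea, maxGap = as.integer(maxGap),
      minTrackLength = as.integer(minTrackLength), frameRate = frameRate,
      velocityKappa = velocityKappa)
}

# gate: maximum association distance for a frame difference df
.gateDistance <- function(model, df) {
  model@maxSpeed / model@frameRate * df + 3 * model@measurementNoiseSigma
}

# log spatial density of a clutter detection
.clutterLogDensity <- function(model) {
  log(max(model@clutterRate, .Machine$double.xmin)) - log(model@fieldArea)
}

# score of one chain of detection indices (length >= 2): birth prior,
# position prior of the first detection, detection/missed-detection terms,
# and the constant-velocity Kalman innovation likelihood
.chainScore <- function(idx, det, model) {
  if (length(idx) < 2) return(.clutterLogDensity(model))
  frames <- det$frame[idx]
  nGap <- sum(diff(frames) - 1L)
  ll <- cvTrackLogLikCpp(as.integer(frames), det$x[idx], det$z[idx],
                         model@measurementNoiseSigma,
                         model@processNoiseSigma, model@velocityKappa,
                         model@maxSpeed / 2, model@frameRate)
  log(model@birthRate) - log(model@fieldArea) +
    length(idx) * log(model@pDetect) + nGap * log(1 - model@pDetect) + ll
}

#' Log-posterior of a partition of detections into tracks and clutter
#'
#' Up to an additive constant: each track contributes a birth prior, its
#' constant-velocity Kalman innovation log-likelihood, log pDetect per
#' detected frame and log(1 - pDetect) per gap frame; every unassigned
#' detection contributes the log Poisson-clutter spatial density. Higher is
#' better; deterministic.
#'
#' @param partition list of integer vectors, each a track of detection row
#'   indices with strictly increasing frames and gaps of at most
#'   model@maxGap; detections in no track are clutter.
#' @param detections data.frame with columns frame, x, z.
#' @param model a \linkS4class{MotionModel}.
#' @return scalar log-posterior (unnormalized).
#' @export
partitionLogPosterior <- function(partition, detections, model) {
  n <- nrow(detections)
  if (n == 0) return(0)
  used <- integer(0)
  score <- 0
  for (tr in partition) {
    if (length(tr) < 2) stop("tracks must contain at least 2 detections")
    if (any(tr < 1 | tr > n)) stop("track references unknown detections")
    fr <- detections$frame[tr]
    if (any(diff(fr) <= 0)) stop("track frames must strictly increase")
    if (any(diff(fr) - 1 > model@maxGap)) stop("track gap exceeds maxGap")
    if (any(tr %in% used)) stop("tracks must be disjoint")
    used <- c(used, tr)
    score <- score + .chainScore(tr, detections, model)
  }
  score + (n - length(used)) * .clutterLogDensity(model)
}

# feasible frame-ordered links under the distance/gap gate;
# returns from/to integer vectors
.feasibleLinks <- function(det, model) {
  n <- nrow(det)
  from <- integer(0); to <- integer(0)
  if (n < 2) return(list(from = from, to = to))
  o <- order(det$frame)
  byFrame <- split(o, det$frame[o])
  frames <- as.integer(names(byFrame))
  for (i in seq_along(frames)) {
    for (j in seq_along(frames)) {
      df <- frames[j] - frames[i]
      if (df < 1 || df > model@maxGap + 1) next
      a <- byFrame[[i]]; b <- byFrame[[j]]
      g <- .gateDistance(model, df)
      d2 <- outer(det$x[a], det$x[b], `-`)^2 + outer(det$z[a], det$z[b], `-`)^2
      ok <- which(d2 <= g^2, arr.ind = TRUE)
      if (nrow(ok)) {
        from <- c(from, a[ok[, 1]])
        to <- c(to, b[ok[, 2]])
      }
    }
  }
  list(from = from, to = to)
}

# walk a chain containing detection i given successor/predecessor maps
.chainOf <- function(i, succ, pred) {
  h <- i
  while (pred[h] != 0L) h <- pred[h]
  out <- h
  while (succ[h] != 0L) {
    h <- succ[h]
    out <- c(out, h)
  }
  out
}

# partition (list of chains, length >= 2) from a successor map
.chainsFromSucc <- function(succ, pred) {
  n <- length(succ)
  heads <- which(pred == 0L & succ != 0L)
  lapply(heads, function(h) {
    out <- h
    while (succ[h] != 0L) {
      h <- succ[h]
      out <- c(out, h)
    }
    out
  })
}

#' Track microbubbles by MCMC data association
#'
#' Metropolis-Hastings over partitions of the detections into tracks and
#' clutter, targeting \code{\link{partitionLogPosterior}}. Candidate links
#' are gated by maxSpeed/frameRate x frame-difference + 3 x measurement
#' noise, with frame gaps up to maxGap. Returns the maximum-a-posteriori
#' partition visited, as tracks passing minTrackLength, with velocities from
#' \code{\link{estimateVelocities}}. Reproducible given the seed.
#'
#' @param detections data.frame with columns frame, x, z (and optionally
#'   intensity), sorted or not.
#' @param model a \linkS4class{MotionModel}.
#' @param nIterations MCMC iterations (default 20000).
#' @param burnIn burn-in iterations (default 5000), only relevant when
#'   posterior samples are kept.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param moveProbabilities named probabilities of the proposal kernels
#'   \code{toggle} (add/remove one link: birth, death, extension, reduction,
#'   split or merge depending on context) and \code{switch} (exchange the
#'   partners of two links).
#' @param init "nn" initializes from the nearest-neighbour solution,
#'   "clutter" from the all-clutter partition.
#' @param keepSamples record the visited partition every \code{thin}
#'   iterations after burn-in (as canonical successor strings) for
#'   convergence diagnostics.
#' @param thin sample thinning interval.
#' @return list with \code{tracks} (a \linkS4class{TrackSet}),
#'   \code{partition} (MAP list of detection-index chains),
#'   \code{logPosterior} (its score), \code{acceptRate}, and optionally
#'   \code{samples}.
#' @export
mcmcdaTrack <- function(detections, model, nIterations = 20000,
                        burnIn = 5000, seed = 1L,
                        moveProbabilities = c(toggle = 0.9, switch = 0.1),
                        init = c("nn", "clutter"), keepSamples = FALSE,
                        thin = 10L) {
  init <- match.arg(init)
  if (is.null(names(moveProbabilities)) ||
      !setequal(names(moveProbabilities), c("toggle", "switch")) ||
      any(moveProbabilities < 0) ||
      abs(sum(moveProbabilities) - 1) > 1e-8)
    stop("moveProbabilities must be a distribution over 'toggle' and 'switch'")
  emptyTS <- new("TrackSet", tracks = list(), frameRate = model@frameRate)
  if (nrow(detections) == 0)
    return(list(tracks = emptyTS, partition = list(), logPosterior = 0,
                acceptRate = NA_real_, samples = character(0)))
  det <- detections
  n <- nrow(det)
  links <- .feasibleLinks(det, model)
  nL <- length(links$from)
  clutterLd <- .clutterLogDensity(model)
  succ <- integer(n); pred <- integer(n)
  linkOf <- function(i, j) which(links$from == i & links$to == j)
  linkKey <- links$from * (n + 1) + links$to
  active <- logical(nL)
  if (init == "nn" && nL > 0) {
    nnts <- nnTrack(det, model, minLength = 2L)
    for (tr in attr(nnts, "chains")) {
      for (k in seq_len(length(tr) - 1)) {
        l <- match(tr[k] * (n + 1) + tr[k + 1], linkKey)
        if (!is.na(l)) {
          active[l] <- TRUE
          succ[tr[k]] <- tr[k + 1]
          pred[tr[k + 1]] <- tr[k]
        }
      }
    }
  }
  # chain score bookkeeping: total = sum of per-chain scores, singletons at
  # the clutter density
  scoreOfChain <- function(idx) .chainScore(idx, det, model)
  totalLog <- n * clutterLd
  if (any(active)) {
    chains <- .chainsFromSucc(succ, pred)
    totalLog <- totalLog +
      sum(vapply(chains, function(ch)
        scoreOfChain(ch) - length(ch) * clutterLd, numeric(1)))
  }
  set.seed(as.integer(seed))
  bestLog <- totalLog
  bestSucc <- succ
  accepted <- 0L
  samples <- character(0)
  pToggle <- moveProbabilities[["toggle"]]
  if (nL > 0) for (it in seq_len(nIterations)) {
    if (stats::runif(1) < pToggle) {
      l <- sample.int(nL, 1)
      i <- links$from[l]; j <- links$to[l]
      if (active[l]) {
        # remove: chain splits at (i, j)
        ch <- .chainOf(i, succ, pred)
        pos <- match(i, ch)
        left <- ch[seq_len(pos)]
        right <- ch[seq((pos + 1), length(ch))]
        delta <- scoreOfChain(left) + scoreOfChain(right) - scoreOfChain(ch)
        if (length(left) == 1) delta <- delta  # singleton scored as clutter
        if (log(stats::runif(1)) < delta) {
          succ[i] <- 0L; pred[j] <- 0L; active[l] <- FALSE
          totalLog <- totalLog + delta
          accepted <- accepted + 1L
        }
      } else if (succ[i] == 0L && pred[j] == 0L &&
                 !(j %in% .chainOf(i, succ, pred))) {
        chI <- .chainOf(i, succ, pred)
        chJ <- .chainOf(j, succ, pred)
        merged <- c(chI, chJ)
        if (all(diff(det$frame[merged]) >= 1) &&
            all(diff(det$frame[merged]) <= model@maxGap + 1)) {
          delta <- scoreOfChain(merged) - scoreOfChain(chI) - scoreOfChain(chJ)
          if (log(stats::runif(1)) < delta) {
            succ[i] <- j; pred[j] <- i; active[l] <- TRUE
            totalLog <- totalLog + delta
            accepted <- accepted + 1L
          }
        }
      }
    } else {
      act <- which(active)
      if (length(act) >= 2) {
        pick <- sample(act, 2)
        a <- links$from[pick[1]]; b <- links$to[pick[1]]
        cc <- links$from[pick[2]]; dd <- links$to[pick[2]]
        l1 <- match(a * (n + 1) + dd, linkKey)
        l2 <- match(cc * (n + 1) + b, linkKey)
        if (!is.na(l1) && !is.na(l2) && !active[l1] && !active[l2] &&
            a != cc && b != dd) {
          oldChains <- unique(lapply(c(a, cc), .chainOf, succ = succ,
                                     pred = pred))
          succ2 <- succ; pred2 <- pred
          succ2[a] <- dd; pred2[dd] <- a
          succ2[cc] <- b; pred2[b] <- cc
          newChains <- unique(lapply(c(a, cc), .chainOf, succ = succ2,
                                     pred = pred2))
          valid <- all(vapply(newChains, function(ch) {
            dfr <- diff(det$frame[ch])
            all(dfr >= 1) && all(dfr <= model@maxGap + 1)
          }, logical(1)))
          if (valid) {
            delta <- sum(vapply(newChains, scoreOfChain, numeric(1))) -
              sum(vapply(oldChains, scoreOfChain, numeric(1)))
            if (log(stats::runif(1)) < delta) {
              succ <- succ2; pred <- pred2
              active[pick] <- FALSE; active[c(l1, l2)] <- TRUE
              totalLog <- totalLog + delta
              accepted <- accepted + 1L
            }
          }
        }
      }
    }
    if (totalLog > bestLog + 1e-12) {
      bestLog <- totalLog
      bestSucc <- succ
    }
    if (keepSamples && it > burnIn && it %% thin == 0L)
      samples <- c(samples, paste(succ, collapse = ","))
  }
  bestPred <- integer(n)
  bestPred[bestSucc[bestSucc != 0L]] <- which(bestSucc != 0L)
  partition <- .chainsFromSucc(bestSucc, bestPred)
  ts <- .partitionToTrackSet(partition, det, model)
  list(tracks = ts, partition = partition,
       logPosterior = partitionLogPosterior(partition, det, model),
       acceptRate = if (nIterations > 0) accepted / nIterations else NA_real_,
       samples = samples)
}

.partitionToTrackSet <- function(partition, det, model) {
  keep <- partition[vapply(partition, length, integer(1)) >=
                      model@minTrackLength]
  tracks <- lapply(keep, function(idx) {
    tr <- data.frame(frame = det$frame[idx], x = det$x[idx], z = det$z[idx],
                     intensity = if (!is.null(det$intensity))
                       det$intensity[idx] else NA_real_)
    estimateVelocities(tr, model@frameRate, maxSpeed = model@maxSpeed)
  })
  new("TrackSet", tracks = tracks, frameRate = model@frameRate)
}

#' Greedy nearest-neighbour tracking baseline
#'
#' Frame-to-frame greedy linking under the same gate as
#' \code{\link{mcmcdaTrack}}; deterministic, ties broken by smaller distance
#' then lower detection index. Known to swap identities at crossings, which
#' is precisely what the MCMC association resolves.
#'
#' @param detections data.frame with columns frame, x, z.
#' @param model a \linkS4class{MotionModel}.
#' @param minLength minimum reported track length; defaults to the model's
#'   minTrackLength.
#' @return a \linkS4class{TrackSet}; attribute "chains" carries the raw
#'   detection-index chains.
#' @export
nnTrack <- function(detections, model, minLength = NULL) {
  if (is.null(minLength)) minLength <- model@minTrackLength
  det <- detections
  n <- nrow(det)
  if (n == 0) {
    ts <- new("TrackSet", tracks = list(), frameRate = model@frameRate)
    attr(ts, "chains") <- list()
    return(ts)
  }
  frames <- sort(unique(det$frame))
  chains <- list()        # growing chains, identified by last detection
  lastIdx <- integer(0)   # last detection of each open chain
  lastFrame <- integer(0)
  for (f in frames) {
    cand <- which(det$frame == f)
    open <- which(f - lastFrame >= 1 & f - lastFrame <= model@maxGap + 1)
    if (length(open) && length(cand)) {
      pairs <- expand.grid(o = open, c = seq_along(cand))
      d <- sqrt((det$x[lastIdx[pairs$o]] - det$x[cand[pairs$c]])^2 +
                (det$z[lastIdx[pairs$o]] - det$z[cand[pairs$c]])^2)
      gate <- .gateDistance(model, f - lastFrame[pairs$o])
      ok <- d <= gate
      ord <- order(d, cand[pairs$c])
      usedO <- logical(length(lastIdx)); usedC <- logical(length(cand))
      for (k in ord) {
        if (!ok[k]) next
        o <- pairs$o[k]; ci <- pairs$c[k]
        if (usedO[o] || usedC[ci]) next
        usedO[o] <- TRUE; usedC[ci] <- TRUE
        chains[[o]] <- c(chains[[o]], cand[ci])
        lastIdx[o] <- cand[ci]
        lastFrame[o] <- f
      }
      cand <- cand[!usedC]
    }
    for (ci in cand) {
      chains[[length(chains) + 1]] <- ci
      lastIdx <- c(lastIdx, ci)
      lastFrame <- c(lastFrame, f)
    }
  }
  keep <- chains[vapply(chains, length, integer(1)) >= minLength]
  model2 <- model
  model2@minTrackLength <- as.integer(max(2L, minLength))
  ts <- .partitionToTrackSet(keep, det, model2)
  attr(ts, "chains") <- keep
  ts
}

#' Estimate per-detection track velocities
#'
#' Finite differences of position over time on a fixed-baseline secant: at
#' interior points this is the symmetric central difference over
#' +/- halfWindow samples (exact for quadratic trajectories); near the track
#' ends the window slides to stay inside the track, becoming a forward or
#' backward difference over the same baseline, so the noise level stays
#' uniform along the track. Differences divide by the actual frame spacing,
#' which handles gaps. A short moving average smooths the velocity series
#' and speeds are capped at maxSpeed (preserving direction).
#'
#' @param track data.frame with columns frame, x, z (frames strictly
#'   increasing).
#' @param frameRate frame rate (Hz).
#' @param maxSpeed speed cap (mm/s); Inf disables.
#' @param halfWindow difference stencil half-width in samples.
#' @param smoothWindow moving-average window (odd; 1 disables).
#' @return the track with vx, vz columns (mm/s).
#' @export
estimateVelocities <- function(track, frameRate, maxSpeed = Inf,
                               halfWindow = 8L, smoothWindow = 5L) {
  n <- nrow(track)
  if (n < 2) stop("velocity estimation needs a track of length >= 2")
  t <- track$frame / frameRate
  vx <- numeric(n); vz <- numeric(n)
  span <- min(2L * halfWindow, n - 1L)
  for (i in seq_len(n)) {
    j1 <- max(1L, min(i - halfWindow, n - span))
    j2 <- j1 + span
    dt <- t[j2] - t[j1]
    vx[i] <- (track$x[j2] - track$x[j1]) / dt
    vz[i] <- (track$z[j2] - track$z[j1]) / dt
  }
  if (smoothWindow > 1 && n > 2) {
    vx <- .movingAverage(vx, smoothWindow)
    vz <- .movingAverage(vz, smoothWindow)
  }
  sp <- sqrt(vx^2 + vz^2)
  over <- sp > maxSpeed
  if (any(over)) {
    scale <- maxSpeed / sp[over]
    vx[over] <- vx[over] * scale
    vz[over] <- vz[over] * scale
  }
  track$vx <- vx
  track$vz <- vz
  track
}

# symmetric moving average that shrinks near the ends (window stays centred)
.movingAverage <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  out <- v
  for (i in seq_len(n)) {
    k <- min(h, i - 1, n - i)
    out[i] <- mean(v[(i - k):(i + k)])
  }
  out
}
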