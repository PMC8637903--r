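# Canonical phantom-study configurations. These are the package's reference
# conditions for characterizing the pipeline: the acquisition follows the
# full 128-channel compounded-chirp protocol (PRF 1500 Hz, five angles) with
# the frame count scaled to the study, and the medium parameters define the
# bubble regime for each phantom.

#' Reference phantom-study configurations
#'
#' Ready-made \code{\link{runPipeline}} configurations for the package's
#' reference studies:
#' \describe{
#'   \item{two_tube_dense}{two-tube phantom at high bubble density (tens of
#'     simultaneous bubbles), the full 600 frames; used for diameter and
#'     flow-speed recovery and the high-density reconstruction error.}
#'   \item{two_tube_sparse}{same phantom at very low density (about one
#'     bubble in the field at a time), 300 frames; the low-density
#'     reconstruction error condition.}
#'   \item{depth_ladder}{four tubes at 10--55 mm depth with bulk attenuation
#'     plus an extra 6 dB skull-mimicking attenuation, 100 frames; depth
#'     coverage.}
#' }
#'
#' @param name study name.
#' @param seed global pipeline seed.
#' @param nFrames optional frame-count override (smaller for quick runs).
#' @return a configuration list for \code{\link{runPipeline}}.
#' @export
studyConfig <- function(name = c("two_tube_dense", "two_tube_sparse",
                                 "depth_ladder"),
                        seed = 1L, nFrames = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    two_tube_dense = list(
      seed = seed,
      phantom = list(preset = "two_tube"),
      acquisition = list(preset = "paper_sim"),
      medium = list(concentration = 0.6, n_static = 100,
                    static_amplitude = 10, lifetime_frames = 20,
                    radial_diffusion = 0.015),
      localize = list(threshold_sigma = 8),
      track = list(n_iterations = 20000, burn_in = 4000)),
    two_tube_sparse = list(
      seed = seed,
      phantom = list(preset = "two_tube"),
      acquisition = list(preset = "paper_sim", n_frames = 300),
      medium = list(concentration = 0.03, n_static = 100,
                    static_amplitude = 10, lifetime_frames = 60,
                    radial_diffusion = 0.012),
      localize = list(threshold_sigma = 8),
      track = list(n_iterations = 10000, burn_in = 2000)),
    depth_ladder = list(
      seed = seed,
      phantom = list(preset = "depth_ladder"),
      acquisition = list(preset = "paper_sim", n_frames = 100,
                         skull_attenuation_db = 6),
      medium = list(concentration = 0.15, n_static = 100,
                    static_amplitude = 10, lifetime_frames = 60,
                    radial_diffusion = 0.005),
      localize = list(threshold_sigma = 5),
      track = list(n_iterations = 10000, burn_in = 2000))
  )
  if (!is.null(nFrames)) cfg$acquisition$n_frames <- as.integer(nFrames)
  cfg
}
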