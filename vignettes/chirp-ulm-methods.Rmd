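---
title: "Super-resolution ultrasound localization microscopy with compounded chirp plane waves: models and methods"
author: "ChirpULM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChirpULM methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ChirpULM)
```

# The problem

Conventional B-mode and contrast-enhanced ultrasound are diffraction
limited: at the low frequencies (around 2 MHz) needed to penetrate the
skull, the wavelength is ~0.8 mm and sub-millimetre cerebral microvessels
cannot be resolved. Ultrasound localization microscopy (ULM) circumvents
the limit by imaging intravascular microbubble contrast agents over many
frames, localizing each isolated bubble far below the wavelength, linking
the localizations into trajectories, and accumulating the trajectories into
density and velocity maps on a grid of 10 x 10 um cells. Transcranial ULM
additionally fights the skull's attenuation; the acquisition modelled here
answers that with low-frequency linear-FM chirp transmits (1.3--2.7 MHz
over 6 us), recompressed on receive by a matched-type filter, and coherent
compounding of five steered plane waves (-6, -3, 0, 3, 6 degrees) at a
compounded frame rate of 1500 Hz (300 Hz in the transcranial protocol,
where 4 s of data give 1200 frames).

ChirpULM implements the complete processing chain together with a synthetic
phantom/RF simulator, so every stage is testable without hardware:

1. **phantom + RF simulation** -- vessel phantoms with flowing bubbles and
   multi-angle chirp channel data;
2. **beamforming** -- pulse compression, delay-and-sum (DAS) with coherent
   compounding, an eigenspace-based variant;
3. **spatiotemporal filtering** -- SVD clutter rejection on the Casorati
   matrix;
4. **localization** -- thresholded regional maxima plus sub-pixel
   refinement;
5. **tracking** -- Markov chain Monte Carlo data association (MCMCDA) under
   a constant-velocity motion model, with a nearest-neighbour baseline;
6. **reconstruction and metrics** -- super-resolved density/velocity maps
   and the evaluation quantities (normalized MSE, SNR gain, resolution
   gain, vessel diameter, depth coverage, flow speed).

# The synthetic data generator

`simulateAcquisition()` / `simulateAndBeamform()` use a far-field
point-scatterer model: each bubble inserts the excitation waveform at the
delay (plane-wave transmit path + element receive path)/c, scaled by 1/r
spherical spreading and bulk attenuation (0.5 dB/(cm MHz) at the 2 MHz
centre frequency, over the round-trip path), plus white Gaussian channel
noise. A full acoustic field simulator is deliberately not reproduced: the
point model preserves the geometry, timing, spectra and SNR structure that
every downstream stage consumes, at desk-scale cost. Consequences of the
simplification: no diffraction from the transducer's elevation plane, no
nonlinear bubble oscillation or harmonics, no speckle from sub-resolution
tissue microstructure. Passing tests therefore demonstrate correctness of
the *processing*, not robustness to every property of in vivo data.

Choices a reader should know about:

* **Coordinates and units.** x lateral (array axis, origin at the array
  centre), z depth, millimetres and microseconds in all interfaces; speed
  of sound 1540 m/s by default.
* **Skull.** A global extra attenuation in dB
  (`skullAttenuationDb`), plus optional per-channel random phase jitter;
  full aberration physics is out of scope.
* **Static clutter.** Optional static background scatterers (`nStatic`,
  `staticAmplitude`, default 10 x bubble amplitude) stand in for
  tissue/skull echoes. They are what gives the SVD filter real work to do
  in end-to-end runs.
* **Flow.** Plug flow by default (the phantom pump circulates at a single
  rate, ~30 mm/s); a parabolic (Poiseuille) profile is available. Bubbles
  leaving a segment are recycled at its entrance with a fresh radial
  offset.
* **Bubble turnover.** `lifetimeFrames` gives bubbles a finite geometric
  lifetime with immediate replenishment at a random vessel position,
  emulating destruction/reperfusion. This matters quantitatively: a
  plug-flow bubble otherwise keeps a single radial offset forever, and no
  finite acquisition could sample the lumen cross-section densely enough to
  read a diameter.
* **Radial dispersion.** `radialDiffusion` adds a small per-frame radial
  random walk (reflected at the lumen walls), standing in for hydrodynamic
  dispersion across the lumen. Defaults are a few micrometres per frame.
* **Concentration.** Bubble density is specified per millimetre of vessel
  length. The two reference regimes map the volumetric extremes used for
  such simulations onto "about one bubble in the field at a time"
  (`two_tube_sparse`, 0.03 /mm) and "tens of simultaneous bubbles"
  (`two_tube_dense`, 0.6 /mm); the elevation slice linking MBs/ml to
  per-frame counts is never stated in the protocols this emulates, so the
  line densities are the package's own calibration, fixed once.

# Beamforming

`pulseCompress()` is the classical matched filter (cross-correlation with
the transmitted waveform, normalized by its energy, output aligned so a
point echo's compressed peak sits at its two-way delay). At this chirp's
small time--bandwidth product (1.4 MHz x 6 us = 8.4) the matched filter
leaves axial range sidelobes near -17 dB -- spectral Fresnel ripple, not
removable by plain window tapering -- which masquerade as spurious
scatterers in dense scenes. The `weighting = "hamming"` mode therefore uses
a regularized inverse filter that equalizes the occupied band to a Hamming
window (in-band response |W|^2 win/(|W|^2 + eps), eps = 1% of the spectral
peak), pushing range sidelobes below -45 dB at the cost of a little SNR and
mainlobe width. The imaging chain uses the equalized filter; the pure
matched filter remains the default of the public function and the reference
for the compression-gain analyses.

`dasBeamform()` sums analytic-signal channel samples at geometric delays
with receive f-number aperture control (default 1.5) and Hann apodization,
normalized by the apodization sum; sub-sample delays are linearly
interpolated. One detail with large practical impact: the Hann taper always
reaches zero at whichever limit binds -- the f-number aperture *or* the
physical array edge. A window truncated at the array edge leaves strong
lateral sidelobes for off-centre targets, which at 32 channels dominated
the artifact budget.

`coherentCompound()` is the complex mean over the steered transmits.
`esbBeamform()` provides an eigenspace-projected minimum-variance
beamformer (per-pixel subaperture spatial smoothing, diagonal loading,
weights projected on the eigenvectors with eigenvalues >= delta x the
largest, DAS fallback on degenerate covariance). It is an approximation of
fast eigenspace beamformers described elsewhere, is considerably slower
than DAS in this implementation, and is excluded from the package's
quantitative evaluation protocol.

The default grid spacing is lambda/4 laterally (~0.19 mm at 2 MHz) and
lambda/8 axially, fine enough that the compressed envelope is well sampled
for sub-pixel localization; the super-resolution 10 um grid enters only
after localization.

# Spatiotemporal filtering

`svdClutterFilter()` reshapes the complex stack to a (pixels x frames)
Casorati matrix and removes a band of singular components by projection
(computed from the frames x frames Gram matrix, never pixels x pixels).
Filtering before envelope detection preserves phase; the projection is
idempotent and splits energy exactly (Parseval over singular values), both
of which are tested. `selectRankThreshold()` places the cut at the elbow of
the log singular-value curve -- the largest second difference -- and falls
back to a cut of 1 with a warning when no pronounced elbow exists (the
protocols here give no rank rule, so an automatic, deterministic choice is
used). In the simulated scenes the static background is exactly
time-invariant, so one component carries almost all clutter; the residual
leakage (the top singular vector is slightly rotated by bubbles and noise)
is at bubble amplitude scale and is one reason detection uses a robust
threshold.

# Localization

`detectCandidates()` takes regional maxima of the envelope above
median + thresholdSigma x MAD (default 4; the reference studies use 6--8 in
dense scenes), separated by at least one PSF half-width (intensity-ordered
suppression). `refineSubpixel()` computes a background-subtracted weighted
centroid over an anisotropic window sized to the PSF: wide laterally
(~0.75 x lateral FWHM), narrow axially. Two numerical details proved
essential and are encoded in the defaults: (i) a window much narrower than
the PSF produces pixel locking -- positions quantized toward pixel centres
-- which comb-structures the accumulated maps; (ii) the background under a
bubble is *tilted* by the skirts of its neighbours, and subtracting only a
constant drags the centroid sideways (in a tube, systematically toward the
vessel axis, shrinking measured diameters by ~10%). The refinement
therefore fits a planar background on the window border. A 2-D Gaussian
least-squares fit is available as `method = "gaussian"` for precision
studies. Detection operates on the envelope; this is a choice (the
protocols do not specify envelope vs complex data).

# Tracking

A partition assigns every detection to one track or to clutter.
`partitionLogPosterior()` scores a partition, up to a constant, as

* per track: a birth prior log(birthRate/fieldArea), the innovation
  log-likelihood of a nearly-constant-velocity Kalman filter (independent
  x/z, per-frame position diffusion `processNoiseSigma`, velocity diffusion
  `velocityKappa` x `processNoiseSigma` x frameRate per frame, velocity
  prior sd maxSpeed/2, measurement noise `measurementNoiseSigma`),
  log(pDetect) per detected frame and log(1-pDetect) per missed frame;
* per clutter detection: log(clutterRate/fieldArea).

`mcmcdaTrack()` runs Metropolis--Hastings over partitions represented as a
set of frame-ordered links (each detection has at most one predecessor and
one successor). Two proposal kernels are used, both *symmetric*, so the
acceptance ratio is exactly the posterior ratio: **toggle** picks a link
uniformly from the gated feasible set and adds or removes it -- depending
on context this is a track birth, death, extension, reduction, split or
merge -- and **switch** exchanges the partners of two active links (the
identity swap at crossings). Gating admits links with displacement <=
maxSpeed/frameRate x frame-difference + 3 x measurementNoiseSigma and frame
gaps <= maxGap. The chain is initialized from the greedy nearest-neighbour
solution by default (all-clutter for the oracle tests), the best-scoring
visited partition is returned as the MAP estimate, and tracks shorter than
minTrackLength are discarded. Correctness is checked two ways: on all small
instances the MAP equals exhaustive enumeration over every valid partition,
and on a tiny ambiguous instance the empirical visit distribution matches
the exact normalized posterior (chi-square). The classical formulations
carry an "update" move for continuous track states; here the partition
carries no continuous state (velocities are derived afterwards), so no such
kernel exists.

Defaults (all configurable): pDetect 0.9, clutterRate 1/frame, birthRate
0.01/frame, maxGap 2, minTrackLength 5, processNoiseSigma = measurement
noise = 0.05 mm, maxSpeed 100 mm/s (the hard gate also caps reported
speeds: flows of tens of cm/s in large vessels are beyond the tracker by
construction), 20000 iterations with 5000 burn-in.

`estimateVelocities()` differentiates positions on a fixed-baseline secant:
symmetric +/- halfWindow samples (default 8) at interior points -- exact
for quadratic trajectories -- sliding to one-sided at the same baseline
near the ends, then a short moving average (default 5). The fixed baseline
matters: at PRF 1500 Hz a bubble moves 20 um per frame while localization
noise is 30--50 um, so short-baseline differences at track ends would be
pure noise; |v| of a noisy velocity is biased upward, and that bias
propagated all the way into the lumen-averaged speed maps until the ends
were given the same baseline as the interior.

# Reconstruction and metrics

`accumulateMaps()` densifies each track by linear interpolation at steps of
at most one cell (10 um), counts visits per cell and averages interpolated
speeds. `computeMSE()` normalizes the density map (by its maximum, or
binarized occupancy as a mode), takes the binary truth map, and averages
squared per-cell differences over either the full shared grid (default, the
convention under which whole-image reconstruction errors of this kind are
reported; the reference values 0.08/0.09 are treated as upper bounds) or
the truth bounding box dilated by 0.5 mm (`region = "bbox"`, a much harsher
region in which a thin-vessel phantom is mostly lumen and even a perfect
sparse reconstruction scores near the occupancy fraction -- the reason the
protocol-level evaluation uses the full grid).

`measureFWHMDiameter()` reads a vessel diameter as the full width at half
maximum of the cross-sectional profile of the map, averaged over a band
along the vessel and lightly smoothed; by default the profile uses cell
*occupancy* rather than raw counts, so a handful of heavily traversed cells
cannot masquerade as the vessel. `computeSNR()` is
20 log10(peak signal ROI / RMS background ROI). `resolutionGain()` divides
the conventional compounded image's lateral -6 dB FWHM by 2.355 x the
standard deviation of replicate localizations of the same point target.
`maxTrackedDepth()` is the deepest tracked detection.

# Reference studies and problem sizes

`studyConfig()` bundles the three reference conditions: `two_tube_dense`
(two parallel depth-oriented tubes, 1.0 mm at x = -3 and 0.7 mm at
x = +3 mm spanning 15--40 mm depth, 30 mm/s plug flow, 0.6 bubbles/mm,
bubble lifetime 20 frames, dispersion 15 um/frame, the full 600 frames --
at shorter runs the lumen cross-section is sampled too sparsely for a
stable diameter readout), `two_tube_sparse` (0.03 bubbles/mm, 300 frames)
and `depth_ladder` (four 1 mm tubes at 10, 25, 40, 55 mm, bulk attenuation
plus 6 dB of skull attenuation, 100 frames). All use the full 128-channel,
five-angle chirp sequence at PRF 1500 Hz; frame counts can be scaled with
the `nFrames` argument. Vessel diameters are reported as the mean FWHM of
perpendicular cuts at three stations along each vessel. The test suite runs the same studies at
reduced frame counts. The tube placement (within a few millimetres of the
axis) together with the 128-channel aperture keeps targets away from the
aperture edge, where any finite array's point-spread function degrades.

Two further experiments characterize the front end on a single simulated
bubble: `snrGainExperiment()` (matched-filtered 5-angle chirp image vs a
single-cycle, single-angle pulse image at equal transmit peak amplitude and
equal noise; the time-bandwidth product alone predicts ~9 dB, compounding
adds ~7 dB) and `resolutionGainExperiment()` (conventional FWHM over
effective localization FWHM across independent-noise replicates).

# Known limitations

* The point-scatterer simulator omits nonlinear bubble acoustics,
  elevation-plane effects and realistic tissue speckle; clutter is a static
  scatterer field.
* The eigenspace beamformer is a straightforward (slow) R implementation,
  intended for small regions of interest.
* Dense scenes are limited by the diffraction-scale PSF: bubbles closer
  than about one PSF half-width are suppressed or merged, which bounds the
  usable concentration well below what the tracker itself could associate.
* Velocity maps are qualitative at the margins: localization noise enters
  |v| non-linearly, and cells are weighted by path length rather than
  residence time.
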