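---
title: "Mapping microtubule dynamics by correlation spectroscopy and comet tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping microtubule dynamics by correlation spectroscopy and comet tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
models, the parameters that matter, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations. No empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` compute.

## The measurement problem

Microtubules grow and shrink stochastically; their growing plus ends are
decorated by EB proteins, so a two-channel movie (tubulin-GFP + EB3)
shows both the polymer network and moving comets at growing tips.
Two readouts are implemented:

1. **Comet tracking** — detect comets per frame, link them into
   trajectories, and summarise per-cell growth metrics.
2. **STICCS** — space–time correlation functions of intensity
   fluctuations on a grid of overlapping subregions. Velocity comes from
   the translation of the correlation peak across temporal lags; no
   individual particle needs to be resolvable, so dense or slow motion
   that defeats trackers is still measurable. Cross-correlating the GFP
   and EB3 channels reports *co-transport*: a microtubule assembling into
   unoccupied territory moves its polymer edge and its EB3 comet
   together (a cross-correlated, "explorative" event), whereas assembly
   along an existing bright fiber changes the GFP channel too little
   relative to the fiber's brightness to register (a "fiber-guided"
   event).

## Preprocessing

* **Photobleaching correction** fits a monoexponential `a·exp(-b·t)` to
  the per-frame mean (over the cell mask) and divides each frame by the
  fitted decay. Non-decaying series pass through unchanged. The
  monoexponential is a deliberate, minimal model; more complex
  photophysics is out of scope.
* **Background subtraction** is a grayscale morphological opening
  (rolling-ball equivalent) with a disc of radius 15 px (10× the PSF
  sigma), preserving diffraction-limited structure while removing
  large-scale background; a light Gaussian denoise (σ = 0.75 px)
  follows. Intensities are clipped at zero.
* **Immobile filter** — per pixel, the temporal Fourier transform is
  computed, the `n_low_freq` lowest-frequency bins (DC included) are
  zeroed symmetrically, and the trace is inverse-transformed. The
  default removes only DC (`n_low_freq = 1`): the minimal
  interpretation that removes truly immobile structure without
  attenuating slow flows. The filter is linear and idempotent, which the
  test suite asserts as properties.

## The correlation function and its normalisation

For each voxel (16×16 px ROI × 30-frame TOI; grid shifts 4 px / 15
frames, with end-anchored windows appended so the grid covers the whole
movie), fluctuations are taken about the **per-pixel temporal mean
within the voxel**, so any structure immobile during the TOI contributes
nothing. The correlation is evaluated by zero-padded FFT and equals the
direct-sum definition to ~1e-15 (asserted against an independent
direct-sum oracle at 1e-10). Spatial lags are stored up to ±ROI/2 and
temporal lags two-sided (±τ_max); the padding (to 24×24×40 for the
default geometry) makes every stored lag alias-free, which is the
purpose zero-padding serves here.

The classical normalisation divides by the product of mean channel
intensities. Because the immobile filter zeroes the per-pixel means, the
driver normalises with voxel means taken from the *preprocessed but
unfiltered* series (the "mean source"); without a mean source it falls
back to the product of channel SDs. The mean normalisation matters
beyond cosmetics: it makes the cross-peak amplitude a *contrast*
measure, small for a faint increment on a bright bundle and large for a
new fiber entering dark territory — the physical basis of the
explorative/guided classification.

## Velocity extraction

The peak of each lag slice is located by a 2-d Gaussian fit (quadratic
fit to log-values in a 5×5 window; paraboloid for windows with
non-positive values; intensity-weighted centroid as a last resort).
Peaks are *tracked* outward from the zero-lag position — each lag's
search is confined to a 3 px neighbourhood of the previous peak — which
makes the fit robust to secondary noise peaks. Velocity is the
amplitude-weighted least-squares slope of peak position against lag,
anchored at the τ = 0 peak; quality is the weighted R². Autocorrelation
modes use positive lags with a default requirement of 6 usable lags
(signals present only briefly in a TOI do not produce a vector; a peak
that exits the measurable lag range — fast genuine flow — is exempt down
to 3). The cross mode fits short two-sided lags (±4) anchored near zero
lag: the cross peak of a growing trail is offset ahead of the laid
polymer, and negative lags extend its measurable range.

Two caveats are documented deliberately. First, at small displacements
(≲0.2 px/frame with 30-frame TOIs) the within-TOI mean subtraction
biases recovered speeds upward by a few percent; this is inherent to
finite-window fluctuation correlation. Second, the cross peak of a
growing trail translates somewhat *slower* than the comet (the trail
stretches rather than translates), which is why the classification's
speed window (×3) is looser than the similarity filter's (×2).

## Noise-vector rejection and classification

A vector is retained when its fit quality passes (0.7 for
autocorrelations; 0.3 for the noisier cross mode, which is additionally
gated during classification) *and* enough 8-connected same-TOI
neighbours agree within 45° and a ×2 magnitude ratio (2 for
autocorrelation fields, 1 for the sparser cross field). Isotropic random
fields lose ≳65% of their vectors to this criterion; coherent flow
fields lose almost none.

Classification labels each retained EB3 vector `cross_correlated = TRUE`
when a retained cross vector with matching direction (≤45°) and speed
(≤×3) sits in its voxel or an adjacent voxel (the cross peak localises
slightly behind the comet). Two amplitude gates suppress false matches:
a contrast score (cross amplitude over the EB3 amplitude of the comet
that produced it, evaluated at the *donor* voxel so a weak far-away EB3
vector cannot promote a stray cross vector) and a reconstructed
co-moving polymer brightness
`ampG ∝ (r_cross/r_eb3)·⟨G⟩·sqrt(r_eb3)/⟨E⟩`, which cancels the local
structure brightness ⟨G⟩ and therefore discriminates with one threshold
across dense and sparse regions of the network.

**Known limitation.** On synthetic ground truth the per-vector
discrimination between explorative and guided growth is shot-noise
limited: with the default camera model the operating point is roughly
85% sensitivity at 20% false-positive rate (or trade-offs along that
curve), so measured per-cell explorative fractions are compressed toward
the middle of the range — the response to true fractions 0.2/0.5/0.8 is
approximately linear with slope ≈0.6–0.7. Rank order across conditions
is recovered robustly (Spearman ρ = 1 in every tested configuration),
and the mid-range is recovered within a few percentage points, but
recovered fractions at the extremes are 10–20 points toward the centre.
Real data with brighter bundles (larger guided/explorative contrast
ratios) would separate better; users comparing conditions should rely on
ordering and differences rather than absolute fractions.

## Comet tracking

Detection is a scale-normalised LoG filter (σ = 1.5 px) with 8-connected
local maxima above a quality threshold (0.3; on simulated movies real
comets score ≈0.7–0.9 and noise maxima ≈0.05–0.08, so the threshold
sits in a wide gap), sub-pixel refined, with duplicates within σ merged.
Linking solves a global linear assignment per frame pair
(Jonker–Volgenant; verified against an exhaustive matching oracle) under
a 3 px cap, with a second gap-closing pass (≤2 frames, 2.5 px). Track
speed is **net displacement over duration**: localisation noise inflates
frame-to-frame link speeds substantially for slow comets (+15–20% at 10
µm/min), while endpoints average it out; the per-link speed is still
reported as `mean_link_speed_um_min`. Growth length is reported as path
length. Filters: ≥3 detections, ≥0.1 µm net displacement, mean quality.

## The synthetic generator

One simulated cell is an elliptical mask holding a radial network of
fiber bundles (persistent random walks from a nucleation point; each
fiber ends at a random fraction 0.35–0.9 of the local cell radius, so
tips with free territory beyond them exist throughout the interior).
Growth events start at Poisson times (0.5 events/frame by default);
each is explorative with the requested probability. Guided events run
along an original bundle and end at its tip; explorative events extend
straight paths from fiber tips into unoccupied space, and the polymer
they lay *extends the network state*, so later explorative events from
the same tip continue into genuinely new territory (the direction search
widens over placement retries so a tip blocked by the cell boundary can
still grow sideways). Speeds are normal (20 ± 5 µm/min by default,
truncated at zero); durations are geometric (catastrophe probability
0.05/frame) with a 3-frame floor — briefer events are not resolvable by
any of the analyses.

Rendering: the GFP channel holds the static bundles (amplitude 1) plus
laid polymer — full contrast (0.6) for explorative growth into empty
space, a small increment (0.18) on top of the parent bundle for guided
growth, emulating single-microtubule versus multi-microtubule-bundle
brightness; the EB3 channel holds a Gaussian comet (amplitude 1.2) at
each tip. Both channels share a smooth immobile background structure
(0.3), monoexponential bleaching (0.005/frame), Poisson shot noise at
100 photons per intensity unit and 2-photon Gaussian read noise; the
default calibration is 0.1 µm/px and 0.2 s/frame over 100 frames (pixel
size chosen as typical 63× confocal sampling; only the frame count and
interval are acquisition-anchored).

What the generator does **not** emulate: 3-d structure and defocus,
microtubule shrinkage/rescue within a movie, asymmetric comet shapes,
fiber transport or treadmilling, fluorophore photophysics beyond
monoexponential bleaching, and detector fusion artefacts. Passing
recovery tests therefore demonstrate correctness of the computation and
robustness to the modelled noise, not performance on every real-data
pathology.

## Problem sizes and numerical choices

Validation runs use one cell = 64×64 px × 100 frames (≈1000 voxels,
three correlation modes, a few seconds per movie), three cells per
condition, and 96×96 px fields with 48 bundles over 150 frames for tracking
validation (50 events at realistic comet density — comets closer than the PSF merge
optically, so denser fields undercount by construction). FFT sizes are
2-3-5-smooth; the correlation uses overlap- and pair-count-corrected
normalisation per lag; degenerate (constant) voxels are flagged and emit
no vector; ties in peak location resolve to the first maximum; all
randomness flows from a single integer seed through per-component
derived seeds, making every pipeline run bit-reproducible (asserted
byte-for-byte on the demo configuration).
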