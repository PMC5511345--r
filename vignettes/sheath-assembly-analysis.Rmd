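---
title: "Measuring where a contractile sheath grows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring where a contractile sheath grows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheathtrack)
```

## The scientific question

The type VI secretion system (T6SS) fires a contractile sheath, a
VipA/VipB polymer wrapped around an Hcp tube, anchored to the cell envelope
through a baseplate. In live-cell fluorescence movies the sheath cycle has
three steps: polymerization to a fully extended state, contraction to about
half the extended length within less than one high-speed frame, and
disassembly of the contracted polymer by the ClpV ATPase. A basic open
question is *where* new subunits join the growing polymer. Three mechanisms
are conceivable:

* **distal** — subunits add at the end far from the baseplate;
* **proximal** — subunits insert at the baseplate, pushing the existing
  polymer outward;
* **intercalation** — subunits insert at random positions along the polymer.

A photobleach chase distinguishes them. Bleach a short stretch of a
polymerizing sheath (and, unavoidably, part of the soluble subunit pool) and
watch the bleached mark: if it stays where it is, with constant size and
near-background intensity, growth is distal; if it migrates away from the
assembly origin at the polymerization speed, growth is proximal; if it
stretches and its intensity rises toward the level of the partially bleached
pool, subunits intercalate. Because wall-less spheroplasts grow to several
micrometres and their sheath length scales with cell diameter, they offer
polymers long enough to bleach only partially.

This package implements the whole measurement as testable code: a forward
simulator of sheath life cycles under each candidate mechanism, a
fluorescence renderer, and the kymograph-based analysis that recovers
speeds, contraction levels and the assembly mechanism from image stacks. On
simulated data every inference can be checked against ground truth; the
same analysis functions apply to real stacks given the acquisition
metadata (pixel size, frame interval, bleach time and line).

## The forward model

**Polymer.** A sheath is a stack of rings at a 10 nm pitch along a straight
chord from a fixed membrane anchor. The pitch is far below the 65 nm pixel
size, so its exact value is immaterial for rendered images; it exists to
make ring bookkeeping (who was built when, from which pool) exact. Each
ring stores the relative brightness of the subunits it was built from.
Growth adds `v_a * dt` of polymer per step (fractional remainders carry
over), capped by the chord length available inside the cell — this cap is
the mechanism behind the sheath-length/cell-diameter correlation. The three
mechanisms differ only in where new ring identities are inserted: appended
distally, prepended at the anchor, or inserted at uniformly random indices.

**Cell geometry.** Cells are 2D outlines in the focal plane: circles
(spheroplasts) or stadium shapes (rods). Randomly nucleated sheaths anchor
uniformly on the membrane and aim at the antipodal membrane point with
Gaussian angular jitter (sd 0.8 rad). The jitter width encodes the
observation that sheaths typically polymerize across the whole cell;
uniformly random chords would instead give a median chord of ~0.7 cell
diameters and a much weaker length–diameter correlation than is observed.

**Photobleaching.** The bleach is a line segment with a Gaussian footprint
(FWHM 0.8 um by default, matching the estimated bleached-area diameter).
Ring brightness is multiplied by
`polymer_survival + (1 - polymer_survival) * (1 - exp(-d^2 / (2 sigma^2)))`
with `d` the perpendicular distance to the line; the soluble pool is
multiplied by `pool_survival` (default 0.4). The pool factor is only
qualitatively constrained by experiment ("partially bleached"); 0.4 places
the dim sections well between background and full brightness and is exposed
in the configuration. Bleaching is irreversible; total polymer plus notional
pool brightness never increases.

**Contraction and disassembly.** Contraction is instantaneous between
frames (experimentally it completes in under 2 ms, sub-frame at both 2 s
and 2 ms frame intervals): ring positions scale toward the anchor by a
factor drawn from N(0.5, 0.03), clamped to (0.05, 0.95), so the population
mean matches the measured ~49% remaining length while individual events
scatter a few percent. Summed ring brightness is conserved, so fluorescence
density doubles. Disassembly is modelled phenomenologically as exponential
brightness decay (default time constant 15 s) after a configurable delay;
ClpV itself is not modelled. By default explicitly placed sheaths do not
contract (`extension_dwell_s = Inf`) so that assembly-phase analyses see
the complete growth curve; contraction studies set a finite dwell.

## Rendering

Each ring contributes a pixel-integrated isotropic 2D Gaussian
(sigma 110 nm, approximately diffraction-limited for GFP at NA 1.4; the
true PSF of the original optics is unknown, so it is a configuration
parameter). Cytosolic background is confined to the cell mask and scales
with the soluble-pool brightness, which is what makes the post-bleach
background drop and the 0% normalization reference time-dependent. Noise is
Poisson shot noise on expected photon counts followed by Gaussian read
noise and a constant camera offset. Defaults (20 photons per ring, 20
photons/pixel background, read noise 2, offset 100) put a single extended
sheath at roughly 5 times the per-pixel background standard deviation,
a realistic regime in which the dim (40%) sections are detectable but not
trivially so. The true photon budget of the original acquisitions is
unknown; recovery results are therefore reported against this declared
noise model, not as properties of any particular instrument. Exposure-time
scaling of photon counts is not modelled: 500 fps stacks are rendered with
the same per-frame budget as 2 s stacks, which makes the high-speed
detection test a geometry test, not a photon-starvation test. Motion blur
is not modelled (contraction is sub-frame by assumption).

## Kymograms and front tracking

A kymogram is built by bilinear interpolation of each frame at evenly
spaced points along a line, averaged over `width_px = 3` parallel offsets.
Bilinear sampling matters because typical growth is ~1.2 pixels per frame.
Samples span the line exactly end to end, so extraction is exactly
equivariant to reversing the line. The assembly origin is the line end
whose signal edge has the smaller positional spread over time (the
baseplate end is static while the front advances).

The front position per frame is measured in two stages. A detection stage
finds the origin-anchored above-threshold extent at
`background mean + 3 sd` (the per-bin sd is the per-pixel sd divided by
`sqrt(width_px)`), bridging single-bin gaps and tolerating the wider gap a
photobleached span cuts into the profile. A refinement stage then locates
the front at the *half-maximum* of the local plateau, because a polymer
edge convolved with a symmetric PSF crosses half its plateau height exactly
at the true edge: a fixed low threshold would sit systematically 2–3 bins
beyond the tip. The plateau is read from bins just inside a coarse tip
estimate (25% of the run's peak excess) so that near-noise-free data, where
the detected run extends into the PSF tail, does not bias it. On noiseless
renders the front is accurate to well under half a 65 nm bin for lengths
beyond ~0.5 um; lengths below the diffraction scale are not localizable by
any method, and the first one or two frames of a nucleating sheath are
treated accordingly.

Speeds are ordinary least squares of front position on time. The end of
assembly is the frame at which the 3-frame-median-smoothed front first
comes within half a bin of its final plateau level; anchoring on the
plateau rather than on individual increments keeps the estimate stable
within ±2 frames under the default noise. Contraction events are length
drops of at least 25% between consecutive frames — far above frame-to-frame
noise, far below the ~50% true drop.

## The photobleach-chase analysis

Eligibility mirrors the experimental selection: the sheath must be
polymerizing before the bleach (regression slope of at least 10 nm/s), only
partially bleached (origin-side signal and a second signal run beyond a
gap of at least 2 bins in the first post-bleach frames), and still
polymerizing afterwards. Measurements are taken at four time points:
directly before (t1) and after (t2) the bleach, 20 s before the end of
assembly (t3, dropped with a warning for short chases), and the end of
assembly (t4).

Sections are classified per distance bin from the post-bleach time average:
bleached at or below background + 2 sd, bright at or above 70% of the
pre-bleach on-polymer level, dim in between. Thresholds are expressed
relative to the polymer signal amplitude (pre-bleach level minus pre-bleach
background) with a floor of 8% of that amplitude, which keeps them
meaningful when the background sd approaches zero (noise-free renders) and
makes all classifications exactly invariant under affine rescaling of
camera counts. With a Gaussian bleach footprint the shoulders of the
bleached span genuinely sit at intermediate brightness, so narrow dim
transition bands flank the bleached section; the canonical
bright–bleached–dim ordering refers to the leading spans of each class.

Tracking does not assume the marks stay put (that would presuppose the
distal answer): at each time point the bleached mark is re-located as the
contiguous minimum-intensity region inside the polymer, with sub-bin edge
interpolation, and the bright section as the origin-nearest run above the
bright floor. The mark's mean intensity is read from its core bins — the
outer span bins sit on the footprint shoulders and carry flanking
fluorescence. Intensities are normalized per time point to the cytosolic
background (0%) and the mean pre-bleach on-polymer level (100%); the
experimental definition fixes only the 0% end, and the pre-bleach polymer
level is this package's choice of 100% reference, documented rather than
asserted as the original one.

The mechanism call is a pure function of three numbers: the bleached-mark
drift (slope of centroid versus time), its relative width change between t2
and the last time point, and its normalized intensity change.
With `drift_tol = 0.2 * v_a` and `width_tol = 0.3` (both exposed):
stationary and constant width calls distal; drift at least `drift_tol`
with constant width calls proximal; widening by at least `width_tol` with
an intensity rise of at least 5 points calls intercalation; anything else
is ambiguous. On 50 simulated noisy events per mechanism the confusion
matrix is diagonal at 98–100% with no distal/proximal confusion; noiseless
events classify perfectly. The tolerances were set from the geometry of
the problem (a proximal mark moves at the full polymerization speed, an
intercalating span stretches with the length ratio L(t4)/L(t2) ≈ 2–3),
not tuned per dataset.

## Population summaries

Morphology-by-dynamics category fractions, the OLS regression of the
longest *fully extended* sheath per cell on cell diameter, and per-cell
nucleation counts in a 2 min window. Cells in which no sheath completed
assembly during the observation window are recorded as NA and excluded
from the regression, exactly as a manual measurement of "longest fully
extended structure" would exclude them. Count summaries should be given
the full cell census (`cells =`), since cells without any event leave no
rows in an event log. Simulated populations use ground-truth diameters and
lengths plus one-pixel Gaussian measurement noise rather than rendered
images: the regression operates on measured-style tables, and automatic
cell segmentation is out of scope.

## Problem sizes and reproducibility

All randomness flows from a single integer seed per simulation; rendering
continues the same stream, so a simulation-plus-render is reproducible
end to end, and the orchestration commands write byte-identical truth
tables for identical configurations. The standard in-silico experiment
sizes used by the test suite and the analysis script are 50 photobleach
chases per mechanism, 50 speed-recovery acquisitions per speed (38 and
55 nm/s), 50 contraction events at 2 s/frame, five 5 s captures at 500
fps, and populations of 150 cells (regression, 5 min observation) and 200
cells (count recovery, 2 min). The chase, speed and contraction sizes match
the event counts of the study designs they emulate; the population censuses
are larger than the 50-cell samples typical of manual measurement because
simulated cells are cheap and the larger sample concentrates the
coefficient of determination at its population value.

## What passing tests do and do not show

The generator emulates the features the analysis depends on: chord-limited
straight growth at constant speed, partial bleaching of polymer and pool,
near-half instantaneous contraction, diffraction-limited blur and
camera noise. It does not emulate sheath curvature or buckling, crossing
or bundled sheaths, out-of-focal-plane tilt (all lengths are 2D
projections, as in the original measurements), pool diffusion gradients,
exposure-dependent photon budgets, or photobleaching during ordinary
imaging. Recovery results on synthetic data therefore validate the
*inference logic* under a declared optical model; they do not certify
performance on crowded wild-type cells, where sheaths are hard to resolve
individually — the experimental workaround (a strain assembling three
times fewer sheaths) has its analogue here in simulating one sheath per
cell for chase experiments. Analysis lines for simulated stacks come from
ground-truth geometry and are labelled as synthetic in the metadata; real
data requires manually drawn lines, as in the original workflow.

## Worked example

```{r example, eval = FALSE}
# simulate one distal photobleach-chase acquisition and analyse it
ev <- simulate_chase_event("distal", seed = 11)
report <- run_bleach_chase(ev$stack)
report$call$label                  # "distal"
report$speed_pre$v_a_nm_per_s      # ~55 nm/s before the bleach
report$speed_post$v_a_nm_per_s     # ~55 nm/s after it
subset(report$track, section == "bleached")  # stationary, ~0% intensity
```
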