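---
title: "Measuring membrane-potential gradients across the inner mitochondrial membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring membrane-potential gradients across the inner mitochondrial membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitograd)
```

## Scope and assumptions

`mitograd` quantifies how a cationic, membrane-potential-sensitive dye
(TMRM or similar) distributes between the two compartments of the inner
mitochondrial membrane — the cristae membrane (CM), which carries the more
negative potential, and the inner boundary membrane (IBM) — from
two-channel super-resolution images in which a potential-insensitive dye
(MTG or a matrix-targeted sensor) provides the geometry. Both readouts
assume a roughly barrel-shaped mitochondrion with clear geometric borders,
imaged at SIM-class lateral resolution (~100–140 nm) and at a pixel size
near 32 nm (50 px = 1.6 µm). Single cristae are *not* resolved at this
scale — several cristae superimpose within one resolution element — so all
quantities describe the average CM/IBM distribution, never per-crista
potentials, and no Nernst-equation conversion of intensities to millivolts
is attempted.

## The two readouts

**IBM association index.** The background-subtracted reference channel is
Otsu-thresholded (256-bin histogram over the intensity range, the ImageJ
convention). One binary erosion of the foreground with a 3×3 square
structuring element produces the *core* mask (bulk/cristae proxy); two
dilations minus the core produce a hollow *rim* mask tracking each
object's periphery (IBM proxy). The index is the ratio of the object
channel's mean intensity over the rim to its mean over the core. The
erosion/dilation counts (1 and 2) are the method's standard setting at
32 nm pixels; both are parameters. Pixels beyond the image border count as
background in both operations, so the masks agree pixel-for-pixel with a
set-translation definition of erosion and dilation (the suite verifies
this against an independent brute-force implementation). By default one
pooled index is computed per frame, matching whole-field analysis of
time-lapse data; a per-object mode exists, as does a `lock_masks` option
that freezes first-frame masks across a time lapse (per-frame masks are
the default because each frame's reference image is the best estimate of
its geometry).

**ΔFWHM.** A cross-section profile is sampled with bilinear interpolation
along a segment, averaging across a configurable width (default 50 px =
1.6 µm) perpendicular to it; both channels are sampled at identical
coordinates. The full width at half maximum of each channel is located by
linear interpolation between the samples bracketing the half-max level on
each side of the peak, giving subpixel crossings. The baseline is 0 for
background-subtracted input (the default; a profile-minimum baseline is
available for raw input). `delta = FWHM_obj − FWHM_ref`: negative when the
potential probe runs narrower than the reference (cristae-concentrated),
rising toward and past zero as dye shifts to the boundary membrane. The
opposite sign convention is one config switch away
(`delta_sign = "mtg_minus_tmrm"`), because both conventions appear in
practice; the default is chosen so that cristae hyperpolarization
*decreases* the reported value, in step with the index.

Degenerate profiles are rejected rather than guessed: a maximum at a
profile end or two separated maxima is an error ("profile not resolved"),
and a plateau lying exactly at the half-max level resolves to the plateau
midpoint with a warning.

Endpoints may be chosen manually (the classical workflow). The automated
placement used by `compute_traces` puts one section per object through its
intensity-weighted centroid, perpendicular to the moment-ellipse major
axis, extending half the minor axis plus a margin on each side. A
skeleton-based placement at regular arc-length intervals was considered
and rejected: for the capsule-like objects this tool targets, the centroid
section measures the same cross-section without skeleton-pruning
heuristics, and it is deterministic.

## Morphometrics

Particle analysis follows the ImageJ conventions: Otsu binarization,
connected components (8-connectivity by default, 4 available) with a
minimum area of 4 px to reject single-pixel noise, area as pixel count,
and fitted-ellipse axes from the second central moments scaled so the
ellipse area matches the pixel area ("Fit Ellipse"). A per-pixel variance
term of 1/12 keeps one-pixel-wide objects non-degenerate and makes the
axis ratio of an ideal rectangle exact. Aspect ratio is `major/minor`;
form factor is `p²/(4π·a)` (1 for a circle, larger for elongated shapes).

The perimeter uses a corner-corrected chain-code estimator
(Vossepoel–Smeulders weights 0.980 / 1.406 / −0.091 on straight steps,
diagonal steps and direction changes) on the oriented outer contour. This
estimator is near-unbiased on digitized smooth shapes (a radius-30 disk
measures FF = 0.993) but *underestimates right-angle polygons by up to
~8%* (a 60×60 square measures FF ≈ 1.18 against the ideal 1.273); that
bias band is pinned in the tests. A raw pixel-edge count was rejected
because FF is quadratic in p and the staircase length biases circle FF
high by ~27%. Perimeters of objects below ~30 px are unreliable with any
chain-code method; the default minimum area filters the worst cases.

## The synthetic test bed

No reference microscopy data ships with the package, so validation rests
on a generative model whose ground truth is exact.

*Geometry.* Mitochondria are capsules (line segments with radius, default
125 nm — diameter 250 nm) at arbitrary orientations. Cristae are
transverse slabs at 70 nm spacing and 30 nm thickness — deliberately below
the simulated PSF, since the method never claims to resolve them — ending
50 nm short of the envelope. The IBM is the capsule envelope.

*Optical projection.* The rendered in-plane density is the 2D projection
of the 3D structure through the optical section: a thin cylindrical shell
projects to `1/sqrt(R² − d²)` of the centerline distance d, a transverse
crista disc to a `sqrt(Rc² − d²)` dome. This matters: rendering the IBM as
a thin in-plane outline instead produces deeply bimodal cross-sections
that no real image of a sub-resolution barrel shows, and breaks the
monotone relation between rim fraction and measured width. The projected
maps are rasterized on a 2× supersampled grid, convolved with a Gaussian
PSF (default FWHM 120 nm), and box-downsampled to the 32 nm pixel grid.

*Dye partition.* Nernstian weights `w = exp(−ψ/(RT/F))` (z = +1, thermal
voltage 26.7 mV at 310 K), multiplied by relative membrane areas
(CM:IBM = 2:1 — cristae fold more membrane), allocate the load between
compartments; the CM allocation then passes a Langmuir cap of capacity
`k_sat`, and the overflow returns to the IBM. This is the minimal model
with the two properties the readouts rely on: CM preference at low load,
IBM spillover at saturation. Defaults (ψ_C = −150 mV, ψ_IBM = −120 mV,
k_sat = 40 in load units) place the six-step 1.35–81 load series (a
60-fold range) on both sides of saturation, giving true rim fractions from
~0.15 to ~0.7. These constants are explicit scene parameters recorded with
every simulation, not claims about biology. The reference channel is
uniform per unit membrane area across both compartments — the behavior of
a dye that loads potential-dependently but stops responding once bound.

*Noise.* Per-channel totals are normalized region maps scaled by the
partitioned amounts times a gain (default 2×10⁴ photons per load unit,
giving hundreds to thousands of photons per foreground pixel, an
EMCCD-plausible budget), so the pre-noise object integral equals the load
exactly — dye conservation is a tested invariant. Poisson shot noise and
Gaussian read noise (σ = 2 photons) follow, seeded deterministically per
frame from the scene seed, so identical seeds give identical stacks.

*What the generator does not emulate:* 3D sectioning and defocus, SIM
reconstruction artifacts, flat-field/vignetting, dye photobleaching and
blinking, cytosolic background fluorescence, and mitochondrial motion.
Passing tests therefore demonstrate correctness of the estimators under
the stated optics/noise model, not robustness to every property of live
recordings.

*Protocols.* The histamine-style protocol steps the CM potential more
negative after a stimulus (default −30 mV with a 15 s exponential
approach, stimulus at 20 s), so the true rim fraction drops; an ATP proxy
rises either as a lagged logistic or as a linear coupling
`atp = α(1 − f) + ε` used for slope-recovery tests. Programmed fission
events dim the object channel locally (40% over a 400 nm zone) for the two
frames preceding a topological split with a 200 nm visible gap. The
oligomycin-style protocol ramps the CM potential from the stimulus
(default 120 s), then a crista-junction opening event pulls the IBM
potential toward it (rim fraction rises — the drop-then-rise index shape)
while mitochondria shorten and thicken, lowering the aspect ratio.

## Dynamics and statistics

`compute_traces` runs background subtraction, masks, index, automated
ΔFWHM, morphometrics and channel totals per frame; a failing metric on one
frame becomes `NA` with a recorded reason, never a silent drop, and only
an all-frame failure is an error. ATP traces recorded on a different clock
are aligned by linear interpolation onto the imaging timebase.
`linear_fit` is ordinary least squares with `r² = 1 − SS_res/SS_tot`, a
two-sided slope p-value from the t distribution on n−2 degrees of freedom,
and an optional percentile bootstrap CI (resampling pairs). Correlations
are computed on per-frame whole-field values; no multiple-testing
correction is applied because the tool reports single planned pairs.

`detect_fission` flags a parent whose footprint overlaps ≥ 2 next-frame
labels, each overlap covering ≥ 25% of the child, and records the
fractional object-channel change in a 5×5 px window at the split site over
the preceding 2 frames. The split site is taken between the facing ends of
the closest child pair (child-centroid midpoints misplace the site for
asymmetric splits). The 25% overlap and 2-frame lookback are defaults of
this detector — the phenomenon itself fixes neither — and both are
configurable and logged.

## Numerical choices and degenerate inputs

- Background subtraction: local median (optionally minimum) in a sliding
  window (default diameter 50 px) on a stride-quarter-window grid,
  bilinearly interpolated, subtracted, clamped at 0. A window larger than
  the image falls back to a global scalar with a warning. The operation is
  idempotent to within 1% of the dynamic range on generator scenes.
- Ratio images clip the denominator at 1% of its foreground median by
  default and set pixels where both channels sit below the floor to 0.
- A core mask that empties under erosion is an error naming the offending
  objects, as is an empty Otsu foreground or a constant image.
- Intensities are carried unscaled from 8/16-bit TIFF; float pages use an
  explicit 65535-scaling convention because the TIFF writer cannot store
  values above 1. Values above 65535 must be rescaled before writing.
- All randomness flows from explicit seeds; the CSV/TIFF writers are
  byte-deterministic under a fixed seed.

## Problem sizes used in the validation suite

The test suite and acceptance script use 96×96 px scenes with three
capsules, 10–24 frame protocols, 20 histamine replicates, 200 random
64×64 mask-oracle images and 5-seed noisy fission runs. These sizes give
stable statistics for every check while keeping a full run in well under
a minute of compute on one core; all of them scale up by changing scene
parameters only.

## Known limitations

2D only (single-plane analysis of what is really a 3D network); no
registration between channels (simultaneous dual-camera acquisition is
assumed pre-registered); the partition model is phenomenological — its
constants set the *operating point* of the simulations, and none of the
package's claims depend on their biological accuracy; morphometric
perimeters carry the documented polygon bias; and the automated profile
placement assumes elongated, non-branching objects (use manual endpoints
for branched mitochondria).
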