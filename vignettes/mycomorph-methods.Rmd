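---
title: "Quantifying asymmetric polar growth: methods and design choices"
author: "mycomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying asymmetric polar growth: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomorph)
```

## The measurement problem

Mycobacteria build new cell wall at their tips, and unevenly so: the old
pole (inherited from the mother cell) incorporates peptidoglycan faster and
over a broader zone than the new pole (created at the last division). When
nascent peptidoglycan is labelled with a fluorescent D-amino acid (HADA),
this asymmetry is visible in the axial fluorescence profile of each cell:
both poles and — in dividing cells — the septum appear as intensity peaks,
and the two polar flanks decay at different rates. The quantities this
package computes from such images are:

* per-cell **length** (from the membrane-stain mask),
* the **length-normalized axial profile** of each fluorescence channel,
* **foci** (peaks) of HADA incorporation, their counts and spacings,
* **pole and septum landmarks**, the **relative septum position**
  `min(p, 1 - p)`, and the **pole/septum intensity ratio**,
* the per-pole **decay slope** and the derived **old/new classification**,
* second-channel intensity at each pole **keyed by pole age**,
* per-pixel **spectral phasor** coordinates of hyperspectral (LAURDAN)
  stacks and **two-reference mixing fractions**,
* group comparisons with the normality-gated test policy.

Because the package is validated entirely on synthetic scenes with known
ground truth, this vignette also describes exactly what the generator
emulates and where it stops.

## Axial profiles

**Medial axis.** The cell mask is thinned to a skeleton (Zhang–Suen), the
longest geodesic path through the skeleton is taken (double breadth-first
search, exact on trees), smoothed with a modest-df smoothing spline, and
both ends are extended along the local tangent until the 0.5-crossing of
the bilinearly interpolated mask, located by bisection to ~0.03 px. This is
a reproducible surrogate for a hand-drawn segmented line along the cell's
long axis. The axis orientation is fixed deterministically (the endpoint
with the smaller (row, col) coordinate comes first) and carries no meaning;
pole identities are assigned later from landmarks. Masks that are not
elongated at least 1.8:1 are rejected as degenerate (a disk has no usable
axis), and cells whose extended axis covers less than 80% of the mask's
major extent are flagged as branched/bent and excluded, with the reason
logged and counted in the pipeline manifest.

**Profile extraction.** At every 1-px arc step along the axis the channel
is sampled at `width_px` points spaced 1 px along the perpendicular
(bilinear interpolation, 0-based pixel-centre coordinates) and averaged —
the wide-line average used in practice (10 px ≈ 1.06 µm at 0.105 µm/px, a
band that spans the cell width, so transversely off-axis foci still
contribute). The trace is background-subtracted (median intensity of all
label-0 pixels, per channel — the most robust plain choice where no
convention is established), clamped at zero,
and resampled to 101 uniform positions on [0, 1] (step 0.01 of cell length,
finer than the ~0.09 µm native acquisition step over typical cells). No
per-cell intensity normalization is applied before population averaging;
an optional max-normalization exists but is off by default. Population mean
profiles carry the elementwise mean and sample SD (n − 1).

**Length** is the arc length of the tip-to-tip axis times the pixel size.
On noiseless synthetic populations the mean absolute error is well under
1%; the residual comes from mask pixelation at the caps.

## Foci, landmarks, and calibration

**Prominence.** Peaks are local maxima of the 101-point profile;
prominence is the peak height minus the higher of the two base minima,
where each base is the minimum between the peak and the nearest strictly
higher point on that side. One deliberate deviation from the textbook
definition: a side whose walk reaches the profile end without meeting a
higher point is *open* and does not set the base. The axial profile is
truncated at the cell boundary, so the outward flank of a pole-tip peak is
unobservable; without this rule a bright pole peak sitting a few points in
from the profile end would inherit a spuriously high base from the
truncated shoulder and be scored as barely prominent. Endpoints themselves
are eligible peaks. Retained foci must also be at least 0.08 of the cell
length apart (shoulder double-counting guard; kept greedily in decreasing
height order).

**Calibration.** In the control phenotype a cell has 2 foci when
non-septate (both poles) and 3 when septate (poles + septum). The
prominence floor is chosen over a 30-point logarithmic grid spanning 1% to
100% of the control population's median peak intensity as the value
maximizing the fraction of control cells with the expected count; among
ties the candidate nearest the log-midpoint of the optimal plateau is
taken (the maximum-margin choice, least sensitive to noise in either
direction). The value is then frozen and applied unchanged to all
comparison groups. Calibration refuses to proceed below 50% best agreement
or with fewer than 20 control cells.

**Landmarks.** Pole peaks are the highest local maxima within the terminal
15% windows (falling back to the endpoint values); the septum is the
highest interior local maximum within the central 70% that clears the
calibrated prominence; near-ties within 0.05 are resolved to the more
prominent candidate with a logged note. The relative septum position is
reported as the min-distance fraction in (0, 0.5] — whether such
distributions should instead be oriented toward the new pole is a
convention choice; the min-distance form is used and stated here openly.
The pole nearer the septum is labelled *new*; poles equidistant within one
grid step are ambiguous and excluded from pole-aligned statistics.

Foci detection operates on the 1D axial profile rather than on 2D image
maxima. All downstream metrics (spacings, septum position, alignment)
consume axial positions, and the 10-px transverse band already projects
off-axis foci onto the axis; this is a divergence from workflows that pick
maxima in 2D and is documented as such.

## Asymmetry metrics

The polar decay slope is an ordinary least-squares line through 10
consecutive grid points (step 0.01 of length) starting at the pole peak and
moving inward — toward the septum when present, toward midcell otherwise —
reported as the magnitude of the fitted slope together with its R². Slopes
are fitted on raw background-subtracted intensities; per-strain comparisons
of such slopes are scale-consistent because all cells of a group share the
acquisition scale. The pole/septum ratio is `(pole1 + pole2)/2 / septum`
and is undefined (cell excluded, logged) when the septum is absent or has
non-positive intensity; it is scale-invariant by construction.

Pole-aligned population profiles reverse each septate, unambiguous cell so
the new pole sits at 0. Slope-based pole-age classification labels the pole
with the *smaller* decay magnitude as old (broader incorporation zone =
faster-growing); slopes within 10% of each other (relative to the larger)
are ambiguous. The 10% threshold is a package choice; nothing in the data
dictates it, and it is exposed as a parameter. Second-channel pole
intensities are windowed means (±0.05 of length; window 0 degenerates to
the nearest grid point) keyed by the age labels, so a polar fusion-protein
signal can be attributed to old vs new poles without using that channel for
the classification itself.

## Spectral phasors

For a pixel spectrum $I_k$, $k = 0 \dots K-1$ with $k = 0$ at the
*shortest* wavelength,
$$G = \frac{\sum_k I_k \cos(2\pi h k/K)}{\sum_k I_k}, \qquad
  S = \frac{\sum_k I_k \sin(2\pi h k/K)}{\sum_k I_k},$$
with harmonic $h = 1$ by default, $\Phi = \mathrm{atan2}(S, G)$ and
$M = \sqrt{G^2+S^2}$. Under this convention a red shift increases $\Phi$
(counter-clockwise) and a blue shift moves clusters clockwise; spectral
widening lowers $M$. The convention (channel origin, rotation direction) is
fixed and documented because different acquisition software disagrees; all
comparisons within the package are relative, so only internal consistency
matters. For any nonnegative spectrum $M \le 1$, the transform is invariant
to intensity scaling, and the phasor of a sum of spectra is the
intensity-weighted mean of the component phasors — all three properties are
verified to machine precision in the tests, alongside agreement with a
generic FFT's first harmonic.

Pixels are included when their total intensity exceeds a threshold; by
default Otsu's threshold on the total-intensity image (restricted to
labelled pixels when a mask is available). Group summaries are
intensity-weighted means of (G, S), with $\Phi$ and $M$ derived from the
mean vector (safe against angle wrap-around) and dispersion as the weighted
RMS distance from the mean.

The two-reference **linear fraction** projects each pixel's (G, S)
orthogonally onto the segment between two reference phasors and reports the
position as the fraction of reference A (1 at A, 0 at B), clipped to
[0, 1]. Reference phasors are supplied by configuration — typically phasors
of pure-component spectra; the pipeline default uses Gaussian references at
440/15 nm (ordered, blue) and 520/30 nm (disordered, red). The
"solid fraction" axis of intensity-vs-fraction curves is interpreted as the
fraction of the ordered (blue-shifted) component; the curve is normalized
to unit maximum for display while its centre of mass is computed on the raw
per-bin intensity mass.

## The synthetic generator

The generator exists so that every stage above can be tested against known
truth. Cells are capsules (straight or gently bowed centrelines; bow
capped at 4% of length so the medial axis stays unambiguous) placed without
overlap on a common canvas, at 0.105 µm/px for channel scenes and
0.05 µm/px for spectral scenes. The recorded centreline runs tip to tip, so
its arc length *is* the cell length and pole foci at relative positions
0 and 1 sit on the mask boundary.

Channels:

* **membrane** — uniform intensity over the cell mask (envelope stain);
* **hada** — a sum of axial Gaussian components rendered along the
  centreline (a flat-core transverse kernel of 1 px half-width with
  Gaussian falloff, σ = 1 px): one component per pole with amplitude and
  decay extent set per pole age, a septal component, and optional discrete
  body foci;
* **mscarlet** (optional) — polar components weighted by pole age.

Scenes are blurred with an isotropic Gaussian PSF (default σ = 1.5 px; no
measured PSF is available at desk scale, and one blur parameter suffices)
and corrupted with Poisson shot noise plus Gaussian read noise
(σ = 2 photons) at 100 photons per unit amplitude, giving SNR ≈ 10 at
unit-amplitude focus peaks. All of PSF, noise and photon scale are
overridable; "noiseless" test populations switch both noise and PSF off.

Preset phenotypes (lengths are log-normal; means/SDs are package choices on
the scale of reported strain means, as only means ± SEM are published):

| parameter | control | delta_fhaA | overexpressor |
|---|---|---|---|
| length mean ± SD (µm) | 7.0 ± 1.5 | 5.5 ± 0.8 | 4.5 ± 1.0 |
| septate fraction | 0.4 | 0.4 | 0.4 |
| septum position (min-fraction) | 0.30–0.45 | 0.42–0.50 | 0.30–0.45 |
| pole amplitudes (new/old) | 1.0 / 1.0 | 0.5 / 0.5 | 1.0 / 1.0 |
| pole decay extents (new/old) | 0.10 / 0.22 | 0.25 / 0.25 | 0.10 / 0.14 |
| septum amplitude | 0.6 | 1.0 | 0.6 |
| extra body foci | – | – | 2 |

The control preset encodes pole-dominated incorporation with asymmetric
polar decay and an off-centre septum; `delta_fhaA` encodes
septum-dominated incorporation, equal polar decays, shorter and more
homogeneous cells, and a near-midcell septum; `overexpressor` encodes
short cells with two extra discrete mid-cell foci (drawn in [0.2, 0.8] of
length, at least 0.8 µm apart from each other and from the septum so that
"discrete foci" remain optically resolvable at the default PSF — cells too
short to honour the spacing receive fewer, which mirrors reality). The
overexpressor's polar zones are kept narrow (0.10/0.14): its phenotype is
delocalized discrete incorporation rather than the control's broad old-pole
gradient. Septa are placed nearer the new pole; the generator records which
pole is old, the per-pixel centreline, all focus positions, and the
closed-form OLS slope of the noiseless analytic profile at each pole, so
classification and slope estimates can be scored against truth.

Spectral scenes give every cell pixel a discretized Gaussian emission
spectrum on the 30-channel grid (centres 423–713 nm, 10 nm bins);
`control_like` uses centre 490 nm, width 25 nm, and `shifted` moves the
centre by −30 nm (blue) and narrows to 20 nm, emulating a strain with a
more ordered envelope; per-cell centre jitter (SD 2 nm) and Poisson noise
are applied. Ground truth stores the per-pixel (centre, width, amplitude).

Reproducibility: one root seed; per-cell parameter streams are derived by
counter, so populations are reproducible under reordering, and the same
(preset, n, seed) yields bit-identical scenes, ground truth, manifests and
output checksums.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: realistic optics beyond a Gaussian blur
(no diffraction rings, no depth dependence), structured background and
autofluorescence, segmentation errors (masks are exact by construction;
only an Otsu helper for synthetic scenes is provided), V-snapping or
branched cells, focus drift, photobleaching, or time-lapse growth. Results
on real images will additionally depend on segmentation quality and
background structure.

## Numerical choices and degenerate inputs

* Coordinates are 0-based with pixel centres at integers; all sub-pixel
  sampling is bilinear; samples outside the raster are dropped from the
  band average with a warning.
* Profile grids: 101 points; detection separations and windows are
  expressed in normalized length.
* Sample SD (n − 1) everywhere a spread is reported.
* Ties: septum candidates within 0.05 → the more prominent; equidistant
  poles → ambiguous; equal-agreement calibration candidates → log-midpoint
  of the plateau.
* Degenerate inputs: flat profiles yield zero foci (valid); all-zero
  channels yield flat zero profiles (valid); empty groups are skipped with
  a log; fewer than `k_points` grid points from a pole peak inward is an
  error for that pole; a fraction distribution collapsed onto one endpoint
  flags the curve as degenerate.
* Normality for the test-selection policy is assessed per group with
  Shapiro–Wilk at α = 0.05 (the branching rule itself names only
  "normally distributed"; Shapiro–Wilk is this package's convention,
  recorded in the output). No multiple-testing correction is applied
  across metrics; comparisons are reported per metric.

## Problem sizes used in the shipped checks

The test suite validates geometry on populations of 100 noiseless cells
(length error < 2%, septum position error < 0.02, focus position error
< 0.03 of length), foci detection on 100 cells at SNR 10
(precision/recall ≥ 0.95, calibration agreement ≥ 90%), and the asymmetry
statistics on 50 seeded runs of 100 cells each (two-sample KS on new- vs
old-pole slopes: power ≥ 90% on the asymmetric preset, type-I rate 5% ± 3
points on the equal-decay preset). The acceptance script recomputes the
same quantities (30 runs per arm for the KS rates) and writes them as JSON.
These sizes were chosen as the smallest populations at which the binomial
noise of the rates is comfortably below the margins being asserted.

## Known limitations

* Very short cells (< ~3 µm) concentrate all landmarks within a few PSF
  widths; focus merging is then physical, not algorithmic, and detected
  counts undercount the truth.
* The 2% profile-fidelity guarantee degrades toward ~4% for short cells
  with narrow foci, driven by sub-pixel axis-end registration (the profile
  is normalized by a length that is itself estimated).
* The pole peak of a PSF-blurred cell sits 1–3 px inside the mask tip
  (edge loss), so pole foci positions are biased slightly inward at
  default blur; the terminal search windows absorb this.
* `pole_channel_intensity` assumes the two channels share the cell's
  geometry (same axis and grid); chromatic offsets are not modelled.
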