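---
title: "Quantifying centriole distal-end organisation and ciliogenesis phenotypes with centriolr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centriole distal-end organisation and ciliogenesis phenotypes with centriolr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centriolr)
```

# Scope

`centriolr` implements the quantitative image-analysis layer of a 3D-SIM
study of centriole distal-end proteins: (i) axial line-profile
measurement of inter-protein distances along the centriole axis, (ii)
toroidal ring diameter measurement in maximum z-projections, (iii)
centriole/centrosome focus segmentation and dark-subtracted intensity
quantification, and (iv) population-level scoring of ciliation, CP110
focus-count and marker-positivity phenotypes with classical two-sample
statistics. Because the original microscope data are proprietary, every
stage is validated on synthetic images with known ground truth; the
generators are first-class, tested package code, not test fixtures.

# Imaging geometry and calibration

A `voxel_calibration()` carries the physical constants every
measurement needs: lateral pixel size, axial step and the axial/lateral
resolution (FWHM). Defaults describe a linear 3D-SIM acquisition:
z-sections 125 nm apart (25 sections per stack), axial resolution
340–380 nm depending on wavelength (default 360 nm, the midpoint), and
a 120 nm lateral FWHM with 40 nm pixels — the reconstructed lateral
pixel size is instrument-specific and therefore a configurable default,
not a constant. Coordinates are 0-based pixel indices; a pixel's
physical position is its centre; all distances are reported in nm.

# Axial distances from line profiles

For each channel the z-sections are chained into a montage strip and an
intensity profile is sampled along the montage axis through the
structure (one sample per section, so positions advance by the z-step).
Profiles are normalised to their maximum, maximal runs of samples at or
above 30% of the maximum are taken as peak regions, and a
one-dimensional Gaussian `A·exp(−(x−µ)²/2σ²) + C` is fitted to the
region containing the global maximum. The inter-channel distance is the
unsigned difference of fitted peak centres; across repeated lines the
median and 25%/75% quantiles are reported. Distances are relative
measurements: they inherit the axial resolution, the epitope geometry
of the antibodies, and the orientation of the structure, which is why a
same-epitope two-channel control (true separation 0) anchors every
experiment.

Numerical choices:

* The fit includes a constant offset `C` even though the conceptual
  model is a bare Gaussian: images have non-zero background, and
  offset-free fits bias σ.
* At a 125 nm axial step, a 30%-of-maximum region of a ~365 nm-wide
  band holds only 3–5 samples — too few for a well-posed 4-parameter
  fit. `profile_pipeline()` therefore widens the fitted window by
  `fit_pad` samples (default 2) on each side of the region;
  `fit_gaussian()` itself fits exactly the range it is given.
* Initialisation is deterministic: µ at the region argmax, σ from the
  intensity-weighted second moment of the region (a width-of-region
  start makes the amplitude and offset directions collinear and the
  Jacobian singular on coarsely sampled peaks), amplitude from the
  region's dynamic range, offset at the region minimum. The
  Levenberg–Marquardt fit (analytic Jacobian) is bounded — µ inside the
  region span, σ > 0 — and iterates to a relative RSS tolerance of
  1e-8, at most 500 iterations; non-convergence is an error that
  reports the initialisation.
* When several regions clear the threshold, the pipeline fits the one
  containing the global maximum: each protein contributes one axial
  band per centriole in this assay.

# Ring diameters

Transverse (end-on) centrioles show toroidal protein distributions.
The diameter pipeline is: maximum z-projection → radial boundary-point
extraction → least-squares circle fit. The circle fit is algebraic
(Kåsa) followed by damped Gauss–Newton refinement of the geometric loss
Σ(‖p−c‖−r)², tolerance 1e-10, at most 200 iterations; the geometric
stage never does worse than the algebraic one, and exact circles are
recovered to numerical precision.

The published measurements selected ring boundary pixels interactively.
`extract_boundary_points()` is a reproducible surrogate: 36 rays are
cast from an interior point, each ray's baseline-corrected radial
profile (0.25 px sampling, baseline = median of the 2 px image border)
is averaged with its four angular neighbours — legitimate because a
circular ridge is rotationally invariant about its centre, so the
average suppresses noise without distorting the radial shape — and the
boundary point is placed where the profile falls to half of its radial
maximum outward of the peak, with sub-pixel linear interpolation.
"Outer ring diameter" is thus operationalised as the outer
half-maximum edge circle; whether interactive boundary clicking
corresponds to this edge, the intensity ridge, or a visual contour is
not knowable from the published description, so the peak-radius
convention is available via `ring_convention = "peak"`, and manually
clicked points can be supplied from CSV to bypass extraction entirely.
`measure_ring()` additionally trims boundary points lying more than 2.5
r.m.s. residuals off the fitted circle (at most two passes): a ray that
latches onto a noise crossing otherwise skews the geometric fit.

The ring generator takes the same convention: `ring_truth$outer_diameter`
is the outer half-maximum edge diameter of the *blurred* ring, so
generator truth and measurement share one definition. Internally the
generator solves, by root-finding on the exact Hankel-integral radial
profile of a Gaussian annulus convolved with the lateral PSF, for the
annulus peak radius that places the blurred outer half-max edge at the
requested diameter; the solved peak radius is returned with the truth.

Limitation: when the diameter approaches twice the blurred ring width
(≈ 2·√(ring FWHM² + lateral FWHM²) ≈ 260 nm at the defaults) the
annulus is no longer resolved — the projection is a filled disc — and
the outer-edge estimate acquires a noise-dependent inward bias of a few
percent (≈ −3% at 250 nm, SNR 8). For resolved diameters (350–600 nm)
the recovery bias is below 1% at SNR ≥ 8.

# Focus segmentation and intensity quantification

Centriole/centrosome foci are segmented on a reference marker channel
by adaptive thresholding: local mean over a square window (default
51 px; exact integral-image means, so flat inputs threshold exactly)
plus `offset_fraction` of the image dynamic range (default 0; a
positive value suppresses background speckle on noisy raw images — an
offset proportional to the *local* range fails in signal-free windows,
where the local range is pure noise). Foreground is labelled with
8-connected components, filtered to an area range (defaults 4–400 px at
2×-binned widefield scale), and ordered by integrated intensity. Masks
are then dilated radially (default 3 px, Euclidean disc; contested
pixels go to the nearest original label, ties to the lower id) and
applied to the dark-noise-subtracted projected images to obtain the
mean and integrated intensity per focus and channel
(`integrated = mean × area` exactly). The dark offset comes from the
stack; when unknown it can be estimated externally (e.g. a low
percentile of the image) and passed in. Population summaries report the
mean, the mean ± 2 s.d. band, and the Student-t 95% confidence interval
of the mean.

# Phenotype scoring

Cilium calls, CP110 focus counts and marker positivity were manual
operations in the original study; the package provides automated
surrogates whose thresholds are exposed, plus the option to supply
per-cell calls from CSV and use only the statistics layer.
`detect_cilium()` thresholds the cilia-marker channel (fraction of
dynamic range with an absolute floor so empty channels stay empty) and
requires a connected object longer than 1 µm in maximum Feret extent.
`count_cp110_foci()` counts prominent local maxima, with a minimum
separation, inside the dilated centrosome region segmented from the
centriole marker. `score_marker_positive()` tests whether the brightest
marker structure clears a prominence floor; eligibility (ciliated cells
for RAB8A-style scoring, non-ciliated centrioles for SMO-style scoring)
is applied by the caller. `summarize_condition()` reports percentages
with explicit denominators; a marker percentage with zero eligible
cells is undefined (`NA`), never 0. Group comparisons use the classical
pooled-variance two-tailed unpaired Student t-test (`welch = TRUE` for
the unequal-variance form); star annotations default to *p* < 0.05 /
*p* < 0.01 and accept figure-specific keys. Degenerate inputs are
resolved before testing: zero variance with equal means gives
t = 0, p = 1; zero variance with unequal means is an error.

# The synthetic-data generators

Three generators define the study conditions:

* `generate_transverse_ring()` — a Gaussian annulus (default radial
  FWHM 50 nm, a thin protein torus) convolved with the lateral PSF,
  rendered from the exact radial profile, as a single plane: the
  diameter measurement operates on the maximum projection, so the
  projection is simulated directly rather than an axial envelope.
* `generate_axial_bands()` — per channel, a lateral Gaussian spot whose
  per-section amplitude follows a sum of Gaussians at the true band
  centres with effective FWHM √(band² + axial²); 25 sections, 125 nm
  apart by default. Band amplitudes default to 3000 counts over a
  200-count background (peak SNR ≈ 47), bright but unremarkable for
  reconstructed SIM data of abundant centriolar antigens on a 16-bit
  scale.
* `generate_cell_population()` — Bernoulli per-cell states (ciliation,
  two CP110 foci, marker given cilium) rendered as widefield-like
  scenes (110 nm px, 280 nm lateral FWHM): a mother/daughter focus pair
  660 nm apart, a 2–5 µm line-segment cilium anchored at the mother
  centriole (only presence and marker co-occupancy are scored, so
  cilium morphology is not modelled), CP110 foci at both centrioles or
  at one, and a marker decorating the proximal micrometre of positive
  cilia. Cells without the two-foci state get one focus.

Camera noise is Poisson shot noise on signal + background, plus
Gaussian read noise, plus a constant dark offset, clamped at zero — the
simplest model that makes dark-noise subtraction exact in expectation.
`noise_for_snr()` fixes the read-noise s.d. to reach a requested peak
SNR. All randomness flows from one seed through a counter-based
per-scene derivation, so any scene is reproducible in isolation, and
noiseless renders are seed-independent.

What the generators do **not** emulate: structured SIM reconstruction
artefacts (honeycombing, out-of-focus haze), chromatic mis-registration
between channels, epitope-linker offsets, variable centriole
orientation, cell-to-cell expression variability beyond Bernoulli
states, and crowded fields with touching cells. Passing recovery tests
therefore demonstrates the correctness and calibration of the
*estimators*, not robustness to every artefact of real microscopy;
real-data workflows should retain the same-epitope control and the
manual-call CSV entry points.

# Problem sizes in the validation suite

The test suite and acceptance script use the sizes the study design
calls for where stated — 300 cells per condition for phenotype
percentages, 36 boundary rays, 25 z-sections — and otherwise modest
replicate counts chosen for tight-enough Monte-Carlo error: 50 rings
per diameter recovery, 30 stacks per axial separation, 10 000 null
replicates for t-test calibration, 500 replicates for the
noisy-render-mean convergence check.

# Known limitations

* Ring diameters below ~260 nm are resolution-limited (above).
* Axial distances are unsigned; proximal/distal sign requires a
  declared line orientation.
* Per-cell grouping of foci assumes one centrosome neighbourhood per
  scene; nucleus-based assignment is out of scope.
* The automated cilium/marker detectors are calibrated on the
  generator's rendering; on real images their thresholds are starting
  points, not validated claims.
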