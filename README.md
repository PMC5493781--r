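# centriolr

Quantitative image analysis of centriole distal-end proteins and
ciliogenesis phenotypes from 3D structured-illumination microscopy
(3D-SIM) data, for cell biologists measuring where proteins sit on the
centriole and how their loss changes a cell population's ability to
grow cilia.

The package implements four measurement pipelines, each validated
end-to-end against a synthetic-image generator with known ground truth:

* **Axial distances** — z-sections are chained into a montage, an
  intensity profile is sampled along the centriole axis, peaks brighter
  than 30% of the profile maximum are fitted with a one-dimensional
  Gaussian `A·exp(−(x−µ)²/2σ²) + C`, and the distance between two
  proteins is `|µ_a − µ_b|` in nm. A same-epitope two-channel control
  (true separation 0) anchors each experiment; repeated lines are
  summarised by the median and 25%/75% quantiles.
* **Ring diameters** — toroidal protein distributions seen end-on are
  measured in maximum z-projections: 36 radial profiles are cast from
  the ring interior, each boundary point is placed at the outer
  half-maximum edge of its baseline-corrected profile, and a circle is
  fitted by algebraic (Kåsa) least squares refined by geometric
  Gauss–Newton, minimising Σ(‖p−c‖−r)². The diameter is `2r` in nm.
  Manually selected boundary pixels can be supplied from CSV instead.
* **Recruitment quantification** — centriole/centrosome foci are
  segmented by adaptive (local-mean) thresholding, the mask is dilated
  by 3 px radially, and per-focus mean and integrated intensities are
  computed on dark-noise-subtracted images; populations are summarised
  by mean, ±2 s.d. band and 95% confidence interval of the mean.
* **Phenotype scoring** — per-cell ciliation, CP110 focus counts and
  marker positivity (RAB8A/SMO-style) are scored automatically or taken
  from manual-call tables, summarised as percentages with explicit
  denominators, and compared across conditions with the two-tailed
  unpaired (pooled-variance) Student t-test with `*p<0.05, **p<0.01`
  star conventions.

The synthetic generators (`generate_transverse_ring`,
`generate_axial_bands`, `generate_cell_population`) emulate the assay
geometry — 25 z-sections 0.125 µm apart, 340–380 nm axial resolution,
Gaussian lateral PSF, Poisson + Gaussian camera noise over a constant
dark offset, Bernoulli per-cell phenotype states — so every estimator
can be tested for parameter recovery without proprietary microscope
data. See `vignettes/centriolr-methods.Rmd` for the model details and
limitations.

## Worked example

```r
library(centriolr)

# a synthetic transverse ring, truth diameter 465 nm, peak SNR 10
truth <- ring_truth(outer_diameter = 465, ring_fwhm = 50, peak_intensity = 1000)
sim   <- generate_transverse_ring(truth, noise = noise_for_snr(1000, snr = 10), seed = 1)
measure_ring(sim$stack, "ring")
#> ring_measurement: diameter 470.9 nm (radius 235.5 nm), center (678.1, 679.1) nm,
#>   rms 2.26 nm over 35 points [automated]

# two axial bands 45 nm apart, measured through the montage/Gaussian-fit pipeline
bands <- generate_axial_bands(band_truth(list(cep19 = 0, fop = -45)), seed = 1)
profile_pipeline(bands$stack)$distances[, c("pair", "distance_nm")]
#>        pair distance_nm
#> 1 cep19-fop    49.79331

# 100 synthetic cells at 80% true ciliation, scored automatically
pop <- generate_cell_population(population_truth(n_cells = 100, p_ciliated = 0.8, seed = 7))
summarize_condition(score_population(pop))
#>   condition n_cells percent_ciliated percent_two_foci n_marker_eligible percent_marker_positive
#> 1 condition     100               85               18                85                72.94118

# replicate ciliation percentages, rescue-style contrast
tt <- two_tailed_ttest(c(75, 80, 85), c(10, 12, 14))
sprintf("t = %.2f, p = %.2g %s", tt$t, tt$p, significance_stars(tt$p))
#> "t = 21.87, p = 2.6e-05 **"
```

The single-ring measurement scatters around the truth (s.d. ≈ 3.5 nm at
SNR 10); averaged over 50 rings the recovered mean is within a few nm
of 465. The 85% scored ciliation of a population drawn at p = 0.8 is
within the binomial sampling margin for n = 100.

## Analysis workflow

The `analysis/` scripts chain the package into the study's analyses and
write their tables under `results/`:

1. `01_simulate_images.R` — render reference synthetic TIFFs (ring,
   45 nm band pair, same-epitope control).
2. `02_ring_diameters.R` — ring-diameter recovery at 350/465/600 nm
   (50 rings each, SNR 10).
3. `03_axial_distances.R` — axial-distance recovery at 0/45/70 nm
   (30 stacks each).
4. `04_recruitment.R` — knockout-vs-wild-type intensity ratios
   (f = 1, 0.5, 0.05) with 2 s.d. bands, CIs and t-tests.
5. `05_phenotypes.R` — wild-type-like vs knockout-like populations
   (3 × 100 cells each): ciliation, CP110 two-foci and marker-positive
   percentages, with replicate-level t-tests.

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

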