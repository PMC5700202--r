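# mpsdetect

Automated detection and quantification of periodic protein nanostructures in
super-resolved fluorescence images.

The prototypical target is the membrane-associated periodic skeleton (MPS)
of neurons: alternating actin/spectrin rings repeating along axons and
dendrites with a ~190 nm period, visible only by super-resolution microscopy
(STED, STORM). Manual quantification — hand-picking regions and running
autocorrelations — is slow and subjective. `mpsdetect` answers, tile by
tile across whole images and image batches: *is the periodic structure
present, and how regular is it?*

## Method

The local structure is modeled by a sharpened-sine reference pattern

    f(x) = A + B sin^P(pi x / T + phi),        P = 6, T = 190 nm

oriented along the neurite direction θ. Each image is processed as:

1. **Neuron discrimination** — Gaussian filter (σ_GF = 125 nm) plus a
   relative intensity threshold (0.65 sd above the filtered mean) mask the
   labeled biological material.
2. **Segmentation** — square 1 µm subregions; tiles with ≥ 20% masked
   pixels count as neuronal.
3. **Orientation** — a progressive probabilistic Hough transform on the
   mask boundary finds line segments; if one angular cluster holds > 50% of
   them, its circular mean is the neurite direction θ_N, otherwise the tile
   is discarded (curved or crossing neurites).
4. **Correlation scan** — the masked two-dimensional Pearson coefficient

       R_P = Σ(I−⟨I⟩)(P−⟨P⟩) / sqrt(Σ(I−⟨I⟩)² Σ(P−⟨P⟩)²)

   (sums over neuronal pixels only) is maximized over θ ∈ θ_N ± 20° and the
   full phase range.
5. **Detection and summaries** — a tile is positive when its best R_P
   exceeds a threshold calibrated as *null mean + 2.5 sd* on structure-free
   subregions (≲ 1% false positives for a near-Gaussian null). Batch
   output: **abundance** (fraction of analyzed tiles detected),
   **regularity** (mean R_P of detected tiles), detection maps, and
   logistic/exponential trend fits against a covariate such as days in
   vitro.

A four-step simulator (pattern → stochastic immunolabeling → 40 nm FWHM
Gaussian PSF → Gaussian background + Poisson shot noise) generates ground
truth images at controlled signal-to-background ratios for validation and
calibration experiments.

## Worked example

Simulate a 3 × 3 µm image crossed by a periodic neurite at SBR 8, then run
the full pipeline:

```r
library(mpsdetect)

cfg <- sim_config(pattern = mps_pattern(phi_rad = 1.2), theta_true = 25,
                  fov_nm = 3000, neurite_width_nm = 900,
                  neurite_length_nm = 6000, seed = 7)
cfg$bg_mean <- solve_bg_mean(cfg, 8)   # background for target SBR 8
sim <- simulate_mps(cfg)
sim
#> Simulated neurite image: 150 x 150 px at 20 nm/px, 1239 fluorophores
#>   theta = 25.0 deg, phi = 1.200 rad, realized SBR = 8.05

an <- analyze_image(sim$image, sim$pixel_size, threshold = 0.2,
                    config = mps_config(seed = 7))
summary(an)
#> Batch summary
#>   tiles: 9   neuronal: 5   analyzed: 3   detected: 3
#>   abundance: 1.000   mean R_P above threshold (0.2): 0.613
```

Nine 1 µm tiles are produced; five contain neuronal material; three of those
have an unambiguous neurite direction and are analyzed; all three exceed the
threshold (abundance 1.0), with a mean best R_P of 0.61 — the structure is
present and regular wherever it could be interrogated. Thresholds come from
calibration on structure-free tiles:

```r
fit_threshold(c(0.06, 0.10, 0.14), n_sigma = 2.5, modality = "STORM")
#> Detection threshold calibration [STORM]
#>   null: mean 0.1000, sd 0.0400 (n = 3)
#>   threshold = mean + 2.5 sd = 0.2000
#>   false positives: 0.00%   false negatives: -
```

A thin command-line front end over the same functions lives in
`inst/cli/mpsdetect.R` (subcommands `simulate`, `calibrate`, `analyze`,
`sbr-sweep`). The methods vignette (`vignettes/mps-detection.Rmd`) explains
the model, parameter choices and numerical details.

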