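---
title: "Detecting periodic protein nanostructures with mpsdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodic protein nanostructures with mpsdetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsdetect)
```

## The problem

Axons and dendrites of neurons carry a membrane-associated periodic skeleton
(MPS): alternating rings of actin and spectrin repeating along the neurite
with a period of roughly 190 nm. The structure is invisible to
diffraction-limited microscopy and appears only in super-resolved (STED,
STORM) images. Quantifying it by hand — picking regions of interest and
running autocorrelations — is slow and subjective. `mpsdetect` automates the
question *"is the periodic structure present here, and how regular is it?"*
over entire images and image sets.

## The reference pattern

The local appearance of the MPS along a neurite is modeled by a sharpened
sine,

$$f(x) = A + B\,\sin^{P}\!\left(\frac{\pi x}{T} + \phi\right),$$

with baseline $A$, amplitude $B$, period $T$, phase $\phi$ and an even
sharpness power $P$. Because $P$ is even, $\sin^P$ is non-negative and has
period $T$ rather than $2T$: the crests of the profile sit exactly $T$ apart.
Averaged experimental MPS profiles are well described by $P = 6$ and
$T = 190$ nm, which are the package defaults; $A = 0$, $B = 1$ are used for
the template because the Pearson correlation is invariant to affine intensity
scaling. In two dimensions the pattern varies along an axis at angle
$\theta$ (the neurite direction) and is constant along the stripes
perpendicular to it.

```{r pattern}
p <- mps_pattern()
p
evaluate_profile(c(0, 47.5, 95), p)
```

Two identifiability facts matter downstream. First, a stripe pattern is
unchanged by a half-turn, so $\theta$ is meaningful modulo 180°. Second, for
even $P$ the profile is invariant under $\phi \to \phi + \pi$, so the phase
is recoverable only modulo $\pi$; phase comparisons in the package and its
tests are made on that circle.

A numerically tabulated 1-D profile can replace the analytic model through
`tabulated_profile()`, for structures whose shape is known only empirically.

## Pipeline

`analyze_image()` chains five steps, each available separately:

1. **Neuron discrimination** (`discriminate()`). The image is smoothed with
   a Gaussian of width $\sigma_{GF}$ (default 125 nm; 100–150 nm works well)
   and thresholded at $k$ standard deviations above the mean of the filtered
   image (default 0.65; useful range 0.5–0.8). The filter suppresses both
   the 190 nm modulation itself (at $\sigma_{GF} = 125$ nm a 190 nm
   sinusoid is attenuated by about four orders of magnitude) and small
   bright specks of nonspecific label, so the mask follows the neurite
   envelope. Because the threshold is expressed in mean/std units, the mask
   is invariant to affine rescaling of the intensities — but for the same
   reason it is not a detector of "is there anything in this image at all":
   a featureless pure-noise image still has ~25% of pixels above
   mean + 0.65 sd. Rejection of truly empty fields comes from the later
   stages (no coherent direction, low correlation), not from the mask.
2. **Segmentation** (`segment_grid()`). Square subregions of side
   $L_{sr}$ = 1 µm by default: small enough to resolve spatial variation,
   large enough to hold ~5 periods of the 190 nm pattern. Incomplete edge
   tiles are discarded. A tile is *neuronal* if at least 20% of its pixels
   are masked (`flag_neuronal()`); 20% keeps thin neurites that clip a tile
   corner-to-corner.
3. **Orientation** (`estimate_direction()`). The mask boundary (mask minus
   its 3×3 erosion) provides linear intensity edges; a progressive
   probabilistic Hough transform extracts line segments (minimum length 25%
   of the tile side, maximum gap 10%, 10 accumulator votes — all
   configurable). Segment angles are clustered on the 180° circle with a
   15° single-linkage tolerance, each segment counting once
   (length-weighting is available). If one cluster holds **strictly more
   than half** of the segments, $\theta_N$ is its circular mean; otherwise
   the tile is discarded — typically a strongly curved neurite or crossing
   neurites, where no single direction exists. The Hough transform visits
   pixels in seeded random order, so a fixed seed gives identical results.
4. **Correlation scan** (`scan_correlation()`). The masked two-dimensional
   Pearson coefficient between tile $I$ and rendered pattern $P$,

   $$R_P = \frac{\sum_{mn}(I_{mn}-\langle I\rangle)(P_{mn}-\langle P\rangle)}
   {\sqrt{\sum_{mn}(I_{mn}-\langle I\rangle)^2\sum_{mn}(P_{mn}-\langle P\rangle)^2}},$$

   with all sums over masked (neuronal) pixels only, is maximized over
   $\theta \in \theta_N \pm 20°$ (step 1°) and $\phi$ over $[0, 2\pi)$ in
   20 steps. The pattern is re-rendered analytically at pixel centres for
   every combination — never rotated by resampling — so the scan has no
   interpolation bias.
5. **Detection**. A tile is positive when its best $R_P$ strictly exceeds
   the calibrated threshold.

```{r pipeline, eval = FALSE}
cfg <- sim_config(pattern = mps_pattern(phi_rad = 1.2), theta_true = 25,
                  fov_nm = 3000, neurite_width_nm = 900,
                  neurite_length_nm = 6000, seed = 7)
cfg$bg_mean <- solve_bg_mean(cfg, 8)
sim <- simulate_mps(cfg)
an <- analyze_image(sim$image, sim$pixel_size, threshold = 0.2,
                    config = mps_config(seed = 7))
summary(an)
```

## Numerical choices in the scan

Two details of step 4 deserve explanation because they interact.

*Centroid-referenced phase.* The scanned phases are applied to the pattern
coordinate measured from the centroid of the masked pixels, not from the
tile corner. The scanned pattern family at each single $\theta$ is the same
either way, but across $\theta$ it is not: with a corner-referenced phase, a
small tilt of $\theta$ shifts the effective phase at the mask centroid, so
when the true phase falls between grid points the scan can "buy" a better
phase match by tilting the orientation — a systematic bias of about half a
degree for the default grids. Referencing the phase at the centroid removes
the trade-off; the reported `best_phi` is converted back to the tile-origin
convention.

*Phase polish.* With 20 phase steps, an unlucky true phase costs several
percent of $R_P$ for the sharp $\sin^6$ pattern (its phase autocorrelation
falls quickly). After the grid scan, the phase is therefore refined by a
deterministic one-dimensional optimization within one grid step of the best
grid point, at the best orientation (`phi_refine = TRUE`, the default).
The grid provides the global search; the polish removes the discretization
loss. Ties in the grid maximum break to the first point in scan order
($\theta$ ascending, then $\phi$ ascending), keeping results deterministic.

Degenerate tiles — fewer masked pixels than 10% of the tile, or zero
variance of image or pattern over the mask — yield a flagged result and are
excluded from statistics rather than contributing a spurious coefficient.
Negative coefficients are kept (they never detect, since detection is
one-sided above a positive threshold) because anti-correlation is a useful
diagnostic.

## Threshold calibration

`fit_threshold()` sets the detection threshold from subregions known to lack
the structure: threshold = null mean + 2.5 × null sd (sample sd, ddof = 1).
For an approximately Gaussian null this bounds false positives near 0.6%,
under the 1% design criterion; `false_rates()` reports the realized
false-positive rate (nulls strictly above threshold) and false-negative rate
(positives at or below it — the complement convention, so the two rules
partition all cases). Different imaging modalities (STED vs STORM) get
separate calibrations that differ only in data, not in formula. The null
$R_P$ values are maxima over the scan grid, so their distribution is
slightly right-skewed; with the 2.5-sigma rule this stays comfortably below
the 1% design bound in our synthetic checks.

## Abundance, regularity, trends

`summarize_records()` aggregates per-tile records: **abundance** is the
fraction of *analyzed* tiles (neuronal **and** direction-valid) whose best
$R_P$ exceeds the threshold; **regularity** is the mean best $R_P$ over
detected tiles. Tiles discarded for ambiguous direction are excluded from
the denominator by default, because no statement about the structure was
possible there; `count_discarded = TRUE` switches to the conservative
accounting in which they count as not-detected. The choice materially
changes abundance fractions and should be reported with results.

`fit_trend()` fits either a 4-parameter logistic
$y = y_0 + (y_1 - y_0)/(1 + e^{-(x - x_{50})/\tau})$ — whose midpoint
$x_{50}$ is the half-height time of a developmental rise, e.g. against days
in vitro — or a saturating exponential that only conveys an increasing
trend. Fits use Levenberg–Marquardt least squares; non-convergence and
unidentifiable midpoints (flat data, midpoint far outside the covariate
range) are flagged, never thrown.

## The simulator

`simulate_mps()` implements a four-step generative model of an immunolabeled
neurite segment:

1. the rotated periodic pattern is rasterized at 1 nm resolution inside a
   rectangular neurite footprint (default 600 nm wide, crossing a 1 µm
   field);
2. fluorophore positions are drawn with probability proportional to the
   local pattern intensity (specific labeling), plus a uniform density of
   nonspecific labels over the footprint;
3. positions are binned to the output raster (20 nm) and convolved with a
   Gaussian PSF of 40 nm FWHM;
4. a Gaussian background with 10% relative standard deviation is added and
   Poisson shot noise is applied pixelwise.

Defaults place ~190 specific fluorophores in a 1 µm² tile
(`label_density = 1e-3` per nm² at peak intensity) with ~10% as many
nonspecific labels, and `photons_per_fluor = 100` detected photons per
fluorophore — a realistic budget for organic dyes under STED, giving peak
pixel values of tens of counts so that shot noise is present but not
dominant. The signal-to-background ratio (SBR) is defined operationally as
the mean of the top decile of in-footprint pixels divided by the mean
outside the footprint; `solve_bg_mean()` inverts this for a target SBR,
estimating the peak signal from a few noise-free labeling realizations
(discrete fluorophores concentrate photons into hotspots, so the smooth
expectation would understate the top decile). A single seed drives three
independent substreams (labeling, background, shot noise), so one component
can be varied without perturbing the others, and a fixed seed reproduces the
image bit for bit.

`sbr_experiment()` sweeps target SBRs (default 3, 5, 8, 10 — the range
typical of STED/STORM acquisitions) with 10 replicates each, runs the
correlation scan on every tile, and reports the mean and standard deviation
of the best $R_P$ per SBR plus the relative range of the means across the
band. Under the default labeling density the mean coefficient is nearly
flat across the band: with ~200 fluorophores per tile the coefficient is
limited by labeling stochasticity, which does not depend on the background
level, rather than by shot noise.

**What the simulator does not emulate:** blinking and localization artifacts
of single-molecule reconstruction (it models the rendered image, not the
photophysics), 3-D PSFs, sample drift, curved neurites, and spatially
varying background. Passing tests on this generator therefore demonstrate
the correctness and calibration of the analysis under the stated image
model; they do not certify performance on pathological real-world inputs
such as strongly curved or densely crossing neurites, which the pipeline
deliberately discards at the orientation step.

## Problem sizes used by the test suite

The packaged tests exercise the method at desk scale: 8×8 images against a
double-loop oracle for the coefficient; 50×50-pixel (1 µm) tiles for
recovery, with 50 seeded replicates for orientation/phase recovery at
SBR 8; a 100-tile calibration null set plus a 50/50 labeled composite for
the false-rate check; 10 replicates per SBR for the robustness sweep; and
$10^6$ Gaussian draws for the threshold rule. These sizes keep the full
suite within a few minutes on one CPU while leaving Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

- Only linear (stripe) periodic patterns are implemented; the reference
  pattern interface accepts tabulated profiles, but cyclic geometries such
  as nuclear pores would need a different renderer.
- The period and sharpness are held fixed during scanning by design — the
  method asks *whether a known structure is present*, not *what its period
  is*. A least-squares fit of profile parameters to averaged data is out of
  scope.
- The TIFF writer stores integer counts exactly (16-bit) and fractional
  data only within [0, 1] (32-bit float); arbitrary-range floats are
  rejected rather than silently distorted, a limitation of the underlying
  TIFF library.
- Abundance estimates depend on the denominator convention for
  direction-discarded tiles (see above); comparisons across studies must
  use the same convention.
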