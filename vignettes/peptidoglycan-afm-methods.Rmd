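---
title: "Quantifying glycan chain order, pores and chain geometry in AFM images of peptidoglycan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glycan chain order, pores and chain geometry in AFM images of peptidoglycan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgafm)
```

## The measurement problem

The bacterial cell wall is a single cross-linked macromolecule — the sacculus —
built from glycan chains (~1.4 nm wide ridges in a high-resolution AFM height
map) tied together by short peptides. Whether those chains are arranged with a
preferred direction, how porous the network is, and how long the chains are
all bear directly on how the wall is built and how it determines cell shape.
None of these quantities can be read off an image by eye in a reproducible
way. `pgafm` implements a pipeline of simple, deterministic statistics for
AFM height maps, and — because real AFM data carry instrument artifacts that
make ground truth unknowable — a synthetic image generator with known
orientation statistics against which every stage is validated.

All images are carried as a `heightmap`: a matrix of heights in nm, row 1 at
the top, with a single isotropic pixel size in nm. This fixed convention
matters because scan-line operations act on rows ("horizontal lines" of the
raster scan).

## The orientational order parameter

The core statistic answers: *how aligned are the ridge-like features in this
image?* The pipeline is

1. **Line flattening** (`flatten_lines`): each row has its least-squares
   polynomial of degree `d` removed; the default `d = 0` subtracts the row
   mean, the minimal correction for the per-row offsets characteristic of
   raster scanning. The operation is a projection (idempotent), and the
   degree is exposed because row-alignment conventions differ between AFM
   processing packages.
2. **Plane subtraction** (`subtract_plane`): a least-squares plane
   `z = a + bx + cy` removes sample tilt.
3. **0.5× downsampling** (`downsample_half`): non-overlapping 2×2 blocks are
   averaged, further suppressing residual scan-line noise. A trailing odd
   row/column is cropped so every output pixel is an exact four-pixel mean.
4. **Gradient** (`gradient_field`): central differences (one-sided at
   borders) give `(gx, gy)` per pixel.
5. **Polar histogram** (`orientation_histogram`): each pixel contributes its
   gradient magnitude to the angular bin containing `atan2(gy, gx)`.
   Defaults: 72 bins (5°), magnitude weighting, no magnitude floor.
   Magnitude weighting suppresses the isotropically oriented gradients of
   flat background without a hard mask; `weighting = "count"` and
   `min_magnitude` are available where a mask-like behaviour is wanted.
6. **Ellipse fit** (`fit_ellipse`): each bin becomes a point at radius =
   weight; the set is symmetrised with its antipodes (orientation is an
   axis); an origin-centred ellipse is fitted and the **order parameter** is
   the ratio of its long to short axis: 1 for isotropic images, larger for
   aligned ones. Because gradients lie perpendicular to ridges, the chain
   direction is the ellipse major axis + 90°, reported separately as
   `chain_angle` to avoid sign confusion.

### How the ellipse is fitted, exactly

For points uniform in polar angle on an origin-centred ellipse with semi-axes
`a >= b`, the eigenvalues of the second-moment tensor of the points are

$$\lambda_1 = \frac{a^2 b}{a+b}, \qquad \lambda_2 = \frac{a b^2}{a+b},$$

so the generating ellipse is recovered in closed form:
`a = sqrt((λ1+λ2)·λ1/λ2)`, `b = sqrt((λ1+λ2)·λ2/λ1)`, and the axis ratio is
simply `λ1/λ2`. This moment inversion is deterministic, invariant to bin
phase, and exact whenever the bin radii lie on an ellipse — the test suite
verifies recovery within 5% for ratios 1–4 and exact behaviour (ratio 1) for
isotropic histograms. Note that the ratio of the *fitted ellipse's* axes is
`λ1/λ2`, not `sqrt(λ1/λ2)`: the square root would be the axis ratio of the
inertia ellipse of the point cloud, which is a different (and flatter)
object than an ellipse passing through the histogram.

Degenerate inputs are rejected rather than guessed at: a histogram whose
weight collapses onto one antipodal bin pair has a zero minor axis
(degenerate error), and fewer than three nonzero bins cannot constrain an
ellipse (fit error). A constant image fails at the histogram stage because
no pixel carries gradient weight.

### The sampling floor, and why the simulator default is dense

An image containing `N` independently oriented features cannot score exactly
1 even when the orientations are drawn uniformly: the resultant of `N`
random axes has expected length `~sqrt(π N)/2`, giving an order parameter
floor of roughly `(1+A)/(1-A)` with `A ≈ sqrt(π/(4N))` — about 1.19 at
`N = 100` and 1.06 at `N = 1600`. Real sacculus images are dense: with a
~2.7 nm chain spacing, a 1 μm² field holds hundreds of chain segments. The
generator default of 800 features of 200 nm per 512×512 image at 2 nm/px is
therefore both realistic (roughly four-fold *sparser* than a real sacculus
surface) and dense enough that the isotropic baseline lands near 1 (measured
mean 1.098 over seeds 1–10), reproducing the expectation that a
randomly oriented control scores ~1. The same arithmetic explains why local
order maps on sparse images show inflated, noisy tile values: each tile sees
only a fraction of the features.

```{r baseline}
ops <- vapply(1:5, function(seed) {
  sim <- simulate_image(synthetic_image_spec(angle_dist = "uniform",
                                             seed = seed))
  order_parameter(sim$heightmap)$order_parameter
}, numeric(1))
round(ops, 3)
```

### Local order maps and group comparison

`order_map` tiles the image (default 4×4) and runs the full pipeline per
tile, reporting the mean and s.d. of local order. Tiles must be at least
32×32 px after downsampling; smaller tiles are refused rather than silently
analysed. `compare_order` contrasts two groups of order parameters (e.g.
wild-type versus MreB-inhibited cells) with a two-sided Welch test, with the
Mann–Whitney test reported alongside because group sizes in imaging
experiments are typically small.

### Spectral cross-check

`power_spectrum_anisotropy` provides the Fourier-side sanity check: a Hann-
windowed magnitude spectrum, lightly smoothed (5×5 box) to suppress
single-pixel speckle, searched for strict local maxima exceeding the
radially matched background by 5 s.d. Background mean and s.d. are estimated
robustly (annulus median and scaled MAD) so a genuine diffraction-like spot
cannot inflate its own background and mask itself. Simulated images with
random feature placement show no peaks — matching the absence of long-range
periodic chain spacing in real data — while a pure sinusoid yields exactly
its antipodal Fourier pair. The elongation of the central lobe (its
second-moment axis ratio) tracks partial alignment. Limitations: the 5 s.d.
rule is calibrated for the fixture sizes used in the tests; in very large
spectra occasional speckle excursions a few percent above threshold can
survive, so peak lists from megapixel images deserve inspection.

## Pore segmentation

Pores are depressions in the height map. `bradley_threshold` implements
adaptive thresholding via an integral image: after min–max normalisation a
pixel is a pore candidate when it falls below `local mean × (1 − sensitivity)`
over a `window × window` neighbourhood (edge-replicated). The dark-object
convention is deliberate — pores are low regions. `detect_pores` then fills
enclosed holes, removes 8-connected components of four or fewer pixels (the
minimum pore definition, implemented literally as component-size removal
rather than a structuring-element opening, which would also erode pore
shape), and labels the survivors with areas in nm². Defaults
(`window = width/8` rounded to odd, `sensitivity = 0.15`) follow common
Bradley implementations; both matter on real data and are exposed
everywhere. The implementation is validated against a brute-force local-mean
oracle on random images, and end-to-end against constructed depression
images where the areas are known by construction.

```{r pores}
sim <- simulate_pore_image(c(64, 64), pixel_size = 1, depressions = list(
  list(origin = c(5, 5), side = 3, depth = 2),
  list(origin = c(20, 20), side = 5, depth = 2),
  list(origin = c(40, 40), side = 10, depth = 2)))
detect_pores(sim$heightmap, window = 31, sensitivity = 0.5)$pores
```

## Chain cross-sections

`extract_profile` samples the map along an arbitrary segment by bilinear
interpolation with an nm distance axis. `fwhm` measures peak width at half
maximum; the baseline defaults to the mean of the local minima flanking the
peak (with `global_min` as the alternative) because chain profiles sit on
the undulating background of neighbouring chains, not on zero.
`peak_spacing` finds local maxima above a topographic prominence threshold
and refines each position with a parabolic fit through three samples —
sub-sample refinement is essential because a 2.7 nm inter-chain spacing
spans only a few pixels at realistic scan sizes. Analytic anchors: a
Gaussian of s.d. σ has FWHM 2.3548 σ; the width of a simulated chain
cross-section matches the dense numeric convolution of a 1 px ridge with the
tip kernel within 5%.

## The synthetic image generator

`simulate_image` draws `n_features` linear segments with uniform random
start points and angles from `N(mean, sd)` (or uniform on [0°, 180°) for the
isotropic control), paints them at `feature_height` — overlaps take the
maximum, not the sum, since a chain crossing is one chain atop another, and
summation of densely rasterised pixels would create spurious spikes —
convolves with a unit-sum Gaussian tip kernel (reflective borders, so total
mass is conserved exactly), then adds per-row offsets and per-pixel Gaussian
noise. One PRNG stream is consumed in a fixed order (start rows, start
columns, angles, row offsets, pixel noise), so a fixed seed reproduces an
image bit for bit.

What it emulates: feature geometry with controlled orientation statistics,
tip broadening, scan-line offsets, sensor noise. What it does **not**
emulate: tip–sample contact mechanics, the cross-linked network topology,
height variation along chains, or substrate regions. Passing the validation
suite therefore demonstrates that the *analysis* recovers known orientation
statistics under AFM-like artifacts — not that any particular biological
image will behave identically; on real data, masking of bare substrate and
the Bradley parameters remain the analyst's responsibility.

Companion generators provide ground-truthed fixtures for the other modules:
`simulate_pore_image` (flat surface minus non-overlapping square
depressions) and `simulate_chromatogram` (Gaussian elution peaks with areas
proportional to known mass fractions, centred where a calibration curve
puts them).

## Cell geometry and chromatography

`spherocylinder_fractions` evaluates the printed partition
`100% = l/((4/3)r + l) + (4/3)r/((4/3)r + l)` for a rod cell of radius `r`
and length `l`; at `r = 0.5` μm, `l = 2` μm this gives 75% (cylinder, built
by the MreB-directed elongasome) versus 25% (poles, built by the divisome).
The formula is implemented exactly as printed; algebraically it coincides
with the spherocylinder *volume* partition rather than the strict area
partition `l/(l + 2r)` (which would give 67%/33% here), and the returned
record carries that note so downstream users see it.

`calibrate_sec` fits the standard SEC calibration `log10(MW) ~ volume`
(dextran standards), exposing `predict_mw`/`predict_volume`;
`fraction_before` integrates a chromatogram trapezoidally up to a threshold
volume to report the percentage of material eluting before a given size
standard. `mw_to_length` converts glycan molecular weight to contour length
with explicit constants (480 Da and 1.0 nm per GlcNAc–MurNAc disaccharide by
default — literature values vary with the retained peptide stem, so both are
parameters); 100 kDa converts to ~208 nm, i.e. about 200 nm at one
significant figure.

```{r geometry}
spherocylinder_fractions(r = 0.5, l = 2)
mw_to_length(1e5)
```

## Numerical and design choices

* **Bin count 72 (5°)**: small enough that binning error is far below the
  seed-to-seed spread of the order parameter, large enough to resolve the
  two antipodal lobes cleanly.
* **Angles**: gradient orientations are kept on the full circle [0, 2π) and
  symmetrised only at fit time, matching full-circle polar histogram
  displays; chain orientation itself is parameterised on [0°, 180°) because
  it is an axis.
* **Tie-breaks and edges**: odd image dimensions are cropped (not padded) in
  downsampling; gradient borders use one-sided differences; Bradley windows
  use edge replication; tip convolution uses reflective borders.
* **Error taxonomy**: every failure is a classed condition
  (`pgafm_metadata_error`, `pgafm_format_error`, `pgafm_fit_error`,
  `pgafm_degenerate_error`, `pgafm_size_error`, …) inheriting from
  `pgafm_error`, so pipelines can catch and log per-image failures and
  continue — which is exactly what `run_pipeline` does.
* **TIFF convention**: float TIFF samples outside [0, 1] are not portable
  across readers, so heights are stored min–max normalised with the affine
  transform and pixel size in a JSON sidecar; the self-describing ASCII grid
  (`pixel_size_nm=…` header plus rows) is the fully transparent alternative.
  Neither reader ever invents a pixel size.
* **Problem sizes in the validation suite**: simulated validation uses
  512×512 px images (10 seeds for baseline and monotonicity ladders) and
  256×256 px fixtures for rotation/comparison properties — sizes chosen to
  keep each property estimate's sampling error well inside its assertion
  margin while the whole suite runs in well under a minute.

## Known limitations

* The order parameter is a global second-moment statistic: a bimodal
  orientation distribution with two perpendicular modes can score near 1.
  The polar histogram itself should be inspected when that is plausible.
* Bradley window/sensitivity for real images are data-dependent; the
  defaults are starting points, and pore statistics on real data should be
  reported together with both parameters.
* "Well-resolved chain" selection for width/spacing measurements is manual
  by nature; `extract_profile` reproduces the measurement, not the
  selection.
* The simulator's feature height is constant along a chain; real chains
  undulate, so absolute FWHM comparisons on real data include that extra
  variance.
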