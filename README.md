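# pgafm — quantitative analysis of peptidoglycan AFM height maps

The bacterial cell wall (the sacculus) is a bag-shaped macromolecule of
glycan chains cross-linked by peptides. High-resolution atomic force
microscopy resolves individual chains as ~1.4 nm ridges in a height map, but
turning such images into numbers — *how aligned are the chains, how porous
is the network, how wide and how far apart are the chains, how much wall do
the elongation and division machines each build* — needs reproducible
statistics. `pgafm` is for microscopists and cell-wall biologists who have
AFM height maps (or size exclusion chromatograms) of peptidoglycan and want
those numbers with full provenance.

## The core statistic

For a height map \(z(x, y)\), the image is line-flattened (per-row
polynomial removal), plane-subtracted, downsampled 0.5× (2×2 block means),
and differentiated. Each pixel contributes its gradient magnitude
\(|\nabla z|\) to the angular bin containing \(\mathrm{atan2}(z_y, z_x)\),
giving a polar histogram of gradient orientations. Treating each bin as a
point at radius = weight (plus its antipode), an origin-centred ellipse is
fitted through the second-moment tensor: for points on an ellipse with
semi-axes \(a \ge b\), the eigenvalues are \(\lambda_1 = a^2b/(a+b)\),
\(\lambda_2 = ab^2/(a+b)\), so the generating axes are recovered in closed
form and the **orientational order parameter** is

\[ S = \frac{a}{b} = \frac{\lambda_1}{\lambda_2} \ \ge 1, \]

with \(S = 1\) for isotropically oriented features. Gradients are
perpendicular to ridges, so the estimated chain direction is the ellipse
major axis + 90°.

Around this sit: Bradley adaptive-threshold pore segmentation (integral
image, hole filling, removal of components ≤ 4 px, areas in nm²), line
profile metrics (bilinear extraction, FWHM, peak spacing with parabolic
sub-sample refinement), spherocylinder surface fractions, SEC calibration
and fraction-before-threshold analysis, and a ground-truthed synthetic image
simulator (linear features with controlled orientation statistics, Gaussian
tip convolution, scan-line offsets, pixel noise) used to validate the whole
pipeline. See the methods vignette
(`vignettes/peptidoglycan-afm-methods.Rmd`) for the full account.

## Worked example

```r
library(pgafm)

# an image of well-aligned chains (mean angle 30 deg, s.d. 5 deg) ...
sim <- simulate_image(synthetic_image_spec(mean_angle = 30, angle_sd = 5,
                                           seed = 1))
order_parameter(sim$heightmap)
#> <orientation_result> order parameter 23.664 (axes 1e+03/42.3),
#>   gradient major axis 122.7 deg, chain direction 32.7 deg, n = 65536 px

# ... versus the isotropic control
ctrl <- simulate_image(synthetic_image_spec(angle_dist = "uniform", seed = 1))
order_parameter(ctrl$heightmap)
#> <orientation_result> order parameter 1.116 (axes 133/119),
#>   gradient major axis 109.7 deg, chain direction 19.7 deg, n = 65536 px

# pores with areas known by construction
pores <- simulate_pore_image(c(64, 64), 1, list(
  list(origin = c(5, 5),  side = 3,  depth = 2),
  list(origin = c(20, 20), side = 5,  depth = 2),
  list(origin = c(40, 40), side = 10, depth = 2)))
pore_stats(detect_pores(pores$heightmap, window = 31, sensitivity = 0.5))
#> <pore_summary> 3 pores, max 100 nm2, 0% below 5 nm2

# a rod cell, radius 0.5 um and length 2 um
spherocylinder_fractions(r = 0.5, l = 2)
#> <surface_fractions> cylinder 75% / poles 25% (r = 0.5 um, l = 2 um)
```

Reading the aligned case: the chains were simulated at 30° and the pipeline
reports a chain direction of 32.7° with a large order parameter; the
uniform control sits near the theoretical minimum of 1 (the residual 0.1 is
the finite-sampling floor of ~800 independent orientations — see the
vignette). The recovered pore areas 9/25/100 nm² are exactly the constructed
depression areas.

Real images come in through `read_heightmap()` (self-describing ASCII grid,
or float TIFF with a JSON sidecar carrying the pixel size), and multi-image
batch runs with full parameter provenance go through `run_pipeline()` on a
YAML configuration, or the thin `exec/pgafm` command-line wrapper
(`simulate`, `analyze-order`, `detect-pores`, `profile`, `sec`, `geometry`,
`run`).

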