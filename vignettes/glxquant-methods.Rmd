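---
title: "Measuring the glomerular endothelial glycocalyx: models, QC and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the glomerular endothelial glycocalyx: models, QC and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glxquant)
```

## The measurement problem

The endothelial glycocalyx is a thin (tens to hundreds of nanometres)
carbohydrate gel on the luminal face of the endothelium. In the glomerulus
it contributes to the filtration barrier, and its loss is an early event in
diabetic kidney disease. Because the layer is below the diffraction limit
in width but its *position* is not, a practical index of its thickness is
the distance between two fluorescence peaks along a line crossing the
capillary wall: a lectin channel labels the glycocalyx sugars and a
lipophilic membrane dye labels the endothelial cell membrane. Walking a
profile line from the lumen outward, the lectin peak comes first and the
membrane peak second; the signed distance between the fitted peak centres
("peak-to-peak") tracks glycocalyx thickness. This package implements that
measurement (automated and manual modes), the companion TEM grid-intersection
morphometry used to validate it, and the trapped-glomerulus albumin
permeability readout — each against synthetic inputs with known truth.

## Peak-to-peak pipeline

### Contour extraction

The automated mode needs the membrane ridge of a preselected capillary
loop. Given a lumen-side seed point, the membrane channel is smoothed
(Gaussian, default SD 0.1 um), thresholded (Otsu over a 256-bin histogram,
ties broken by the lowest maximizing bin; the threshold is overridable),
and rays are cast from the seed: along each ray the ridge position is the
sub-pixel maximum (quadratic refinement over three samples) of the smoothed
intensity inside the first above-threshold run. The per-angle radii are
low-pass filtered by truncating their Fourier series (8 harmonics by
default), yielding a smooth closed contour. A design note: a common recipe
is thresholding followed by morphological skeletonization plus a periodic
spline. For a single closed loop, ray casting from the lumen is simpler,
needs no morphology machinery, is exactly deterministic, and measures the
ridge with sub-pixel accuracy (on noiseless synthetic loops the mean radius
is recovered well within one pixel and the perimeter within 2%); it does,
however, assume the contour is star-shaped around the seed, which holds for
capillary loop cross sections.

Degenerate inputs fail loudly: a flat or empty membrane channel, a ridge
that never closes around the seed, or a ridge running off the image border
are all descriptive errors.

### Line placement and sampling

200 lines per loop (the automated protocol's count) are anchored at equal
arc length along the contour, each perpendicular to the local tangent and
oriented lumen to abluminal, so a positive peak-to-peak means the
glycocalyx peak is luminal — the expected geometry. Lines are 2 um long,
sampled every 0.05 um (both configurable; the underlying acquisition
protocol does not state them, so these are declared defaults, not inferred
values). Sampling is bilinear at continuous coordinates with pixel centres
at (i − 0.5)·pixel_size. The manual mode converts ROI segments exactly as
drawn — no reorientation — matching a protocol of 3 hand-drawn lines per
loop.

### Gaussian fitting

Each channel profile is fitted with a + b·exp(−(d − c)²/2σ²) by nonlinear
least squares. The amplitude and baseline enter linearly, so they are
profiled out (solved in closed form at each candidate (c, σ)), and the
remaining two-parameter problem is optimized by bounded quasi-Newton
(L-BFGS-B; centre bounded to the sampled range, σ to [step, range]),
initialized from the argmax and a quarter of the range. Because L-BFGS-B
stalls at ~1e−5 relative precision when residuals approach machine zero, a
damped Gauss–Newton polish follows; reaching a Gauss–Newton fixed point is
also the convergence certificate when the line search aborts on a
numerically flat objective. On exact Gaussian samples all four parameters
are recovered to better than 1e−6 relative error, and on noisy profiles the
fitted centre agrees with a brute-force (centre, σ) grid search at 0.001 um
resolution (the acceptance oracle). Constant profiles are flagged
`flat_profile`, never fitted.

### Quality control and aggregation

Per loop, the mean and SD of the signed peak-to-peak over converged lines
are computed, plus a signal-to-noise ratio. The published exclusion rule —
drop a loop when SD > 7.5 and/or SNR < 15 — leaves two things unstated,
which the configuration therefore makes explicit rather than guessing
silently:

* **SD unit.** `qc_config(sd_unit = ...)` applies the 7.5 threshold in the
  reporting unit (um) by default, with `"nm"` and `"px"` conversions
  selectable. No hidden conversion is ever applied.
* **SNR definition.** Implemented as the fitted membrane-channel amplitude
  divided by the SD of that fit's residuals, averaged over lines — the
  peak-over-noise reading using quantities the fit already produces. The
  lectin channel is selectable (`snr_channel = "glx"`). A perfect fit
  (zero residual SD) yields `Inf` and can never be excluded on SNR.

Threshold boundaries are retained (the rule uses strict inequalities).
Loops with more than 10% of lines showing negative peak-to-peak are flagged
`orientation_anomaly` but not auto-excluded, since the protocol is silent
on them; the sign is preserved throughout. A minimum number of converged
lines (default 50 automated, 3 manual) guards the SD estimate.

Aggregation is an unweighted mean of means at each level (loops within
glomerulus, glomeruli within subject, subjects within group), omitting
excluded loops; a glomerulus or subject left empty is omitted with a
warning. The same aggregator serves the TEM summaries.

## TEM morphometry

The module consumes annotation tables, not micrographs — the underlying
measurements are manual, and automating EM segmentation is out of scope.
Thickness at a grid intersection is the Euclidean distance (nm) between
the luminal phospholipid point and the farthest glycocalyx point; a
thickness of at most 10 nm counts as *uncovered* (the boundary value is
uncovered), and coverage is the complementary percentage. Widths (GBM,
foot process, slit) are mean pair distances per kind; fenestration and
foot-process densities divide counts by the GBM length analysed. Whether
the original protocol pooled intersections across grid sections or
averaged per section is ambiguous; this package computes per capillary and
then averages capillary → glomerulus → subject, mirroring its sampling
design (3–4 loops per glomerulus, 2–3 glomeruli per animal).

## Permeability

After the perfusate switch (t = 0) the luminal intensity of a trapped
glomerulus is modelled as one well-mixed compartment,
I(t) = I∞ + (I0 − I∞)·e^(−kt) with k = 2·Ps/r for a cylinder of radius r.
The protocol estimates "the rate of decline over the first minute": an
ordinary least-squares line on I(t)/I(t0) over [t0, t0 + 60 s], with I(t0)
the mean of samples strictly within 1 s of the switch. Two numerical
choices matter:

* **Window anchoring.** The fit includes the t = 0 sample. The chord of an
  exponential over a window w underestimates the initial rate by the
  analytic factor (1 − e^(−kw))/(kw); anchoring at the switch keeps the
  OLS slope within 1% of that factor for kw ≤ 0.6, which is the regime of
  the assay (k of order 0.01 1/s).
* **Bias correction.** The reported k inverts the exact map
  k → OLS-slope-of-e^(−kt) on the observed time grid (root finding on the
  small-k branch; the map is not monotone, returning to zero at large k).
  Noiseless exponential traces are therefore recovered without bias, and
  the raw slope `k_raw` is always reported alongside for transparency. The
  inversion assumes I∞ = 0; a substantial asymptotic floor (unwashed
  tracer, autofluorescence) biases k low by roughly the factor
  (1 − I∞/I0), a known limitation.

Conversion uses Ps′_alb = k·r/2; the geometry factor is an explicit
argument so other conventions (published variants differ in background
subtraction and geometry) can be substituted without code change — the
implemented convention is declared, not asserted to be identical to any
particular prior instrument. Negative rates are passed through flagged,
never clipped. An exponential-fit mode exists for comparison.

## Synthetic data: what it emulates, what it does not

The generators state a world and hold it fixed:

* **Loop images.** Ideal zero-width circles (membrane at R, glycocalyx at
  R − Δ; Δ is the ground-truth peak-to-peak) blurred by an isotropic
  Gaussian PSF and sampled at 0.05 um/px with PSF σ = 0.1 um — fixture
  choices, since the acquisition optics are not specified in the protocol;
  an intrinsic ring width (default 0) can be added in quadrature. The
  blurred profile is evaluated via its Bessel closed form
  f(r) ∝ e^(−(r−R)²/2s²)·I0(rR/s²) on a dense radial grid (validated in
  the tests against brute-force numerical convolution of the circle).
  Noise is additive Gaussian with SD a fraction of the peak (default 2%),
  or Poisson; negative pixels are clipped at zero and logged. Images are
  written as two-page 16-bit TIFF with the pixel size in the resolution
  tags.
* **Cohorts.** Between-subject variability only (normal around the group
  mean, default SD 0.02 um — a realistic biological spread an order of
  magnitude below the group effect); all loops of a subject share its true
  offset. Group structure emulates control / disease / treatment designs.
* **TEM tables.** Thicknesses are either drawn from a floored normal
  (mean 200 nm, SD 50 nm defaults) or constructed to hit an exact
  uncovered fraction; coordinates realize each thickness exactly as a pair
  separation, so the analysis side can be checked against truth with zero
  tolerance.
* **Decay traces.** The exact one-compartment model plus additive Gaussian
  noise, sampled at 1 Hz for 90 s.

All generators are pure functions of their parameters including the seed
(bit-for-bit reproducible). What a green test does **not** establish:
robustness to real-image nuisances — neighbouring loops and background
structures, non-circular and non-star-shaped loop sections, chromatic
misregistration between channels, depth-dependent PSF, detector
nonlinearity — none of which the ring model simulates. The pipeline also
deliberately reports the peak-to-peak index as defined, with no PSF
deconvolution: it is an index, not an absolute thickness.

## Determinism and provenance

Every pipeline output CSV starts with a provenance comment (package
version, md5 of the materialized YAML config, units), configs are echoed
with all defaults filled in, files are written atomically
(temp-then-rename), and reruns with identical config and seed are
byte-identical — asserted in the acceptance tests. Per-loop seeds are
derived from the master seed with a fixed integer recurrence kept inside
the 32-bit range R requires.

## Known limitations

* The TIFF codec covers the baseline subset the package writes
  (uncompressed grayscale 8/16-bit, either byte order); compressed or
  tiled TIFFs from microscope vendors must be converted first.
* Contour extraction assumes one star-shaped closed loop around the seed.
* The SD-threshold unit and the SNR definition in the published exclusion
  rule are declared choices (see above); results are reported so either
  can be recomputed under an alternative reading.
* Ps′_alb inversion assumes a zero asymptotic intensity; traces with a
  large unwashed floor need the exponential mode or background
  subtraction upstream.
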