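---
title: "Methods: quantifying gene expression in synthetic-cell populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gene expression in synthetic-cell populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvquant)
```

# Scope

`guvquant` analyses two kinds of data produced in light-activated
synthetic-cell experiments:

1. **Multi-channel epifluorescence images** of giant unilamellar vesicle
   (GUV) populations, with a reference dye channel (TXR; every vesicle
   encapsulates Texas-Red dextran) and a reporter channel (GFP; only
   vesicles that express the encoded fluorescent protein are bright).
   The package detects vesicles, measures per-vesicle diameters and
   background-corrected mean intensities, classifies expressing vesicles
   against a no-DNA control population, and scores how faithfully an
   expression pattern follows a photomask.
2. **96-well receiver-cell assays**, where bacterial reporter cells
   transduce an acyl-homoserine-lactone (AHSL) concentration into GFP
   fluorescence. The package fits the four-parameter logistic (Hill)
   dose-response model, inverts it to quantify unknown AHSL titers from
   dilution series, and converts titers into biosynthetic yields.

No instrument data ships with the package. Instead, every analysis step
is paired with a synthetic-data generator that emits exact ground truth,
and the test suite exercises the full workflow against that truth.

# The synthetic microscopy generator

`simulate_field()` renders vesicles as anti-aliased filled disks: the
encapsulated dextran fills the lumen, so the reference channel shows
filled disks rather than rings. Pixel values are
`intensity x clip(r + 0.5 - d, 0, 1)` where `d` is the distance from the
pixel center to the vesicle center — a linear-ramp approximation of the
covered area fraction, accurate enough that sub-pixel diameter recovery
is testable.

Key defaults, all overridable through `sim_image_config()`:

* **Diameter model.** A log-normal distribution truncated to
  [3, 20] µm whose *truncated* mean and standard deviation are 6.5 µm
  and 2.3 µm, the population statistics typical of GUVs formed by
  emulsion phase transfer. The log-scale parameters
  (`meanlog = 1.79244`, `sdlog = 0.35886`) were solved once from the
  closed-form truncated moments (`fit_truncated_lognormal()`) and
  verified by Monte Carlo before being frozen.
* **Intensity models.** Per-vesicle reference intensity is log-normal
  (median 50 gray units, `sdlog` 0.35). Expressing vesicles draw
  reporter intensity from a log-normal with median 20 gray units and
  `sdlog` 0.75, which spans more than an order of magnitude between the
  5th and 95th percentiles — the heterogeneity characteristic of
  stochastic solute partitioning during vesicle formation.
  Non-expressing vesicles sit at a basal lumen level of 1.5 gray units.
* **Background and noise.** A flat per-channel background of 5 gray
  units (camera offset plus out-of-focus light) and additive Gaussian
  noise with sd equal to 2% of the median reference intensity. This
  keeps the default signal-to-noise ratio in the regime where detection
  should be near-perfect; noise can be raised, and optional Poisson
  resampling adds shot noise.
* **Pixel size.** 0.65 µm/px by default (a 10x-objective regime used
  for patterning fields); 0.13 µm/px is the 100x regime appropriate for
  per-vesicle intensity work. Camera pixel pitch and bit depth are
  conventions of this package, not measured properties.
* **Placement.** Centers are drawn by rejection sampling; a candidate
  is rejected when its distance to an accepted center is less than
  0.9 x the sum of radii. Detection is thus evaluated on resolvable
  objects, but note that the rule still permits rim contact — two disks
  may genuinely intersect over a thin lens, which matters for
  classification exactness (below).
* **Expressing fraction** defaults to 0.9, and a binary photomask
  (`simulate_patterned_field()`) forces vesicles whose centers fall in
  dark regions to the OFF state, mimicking spatially patterned
  UV activation.

What the generator does **not** emulate: optics (no point-spread
function, no z-structure), vesicle deformation, membrane/lumen intensity
structure, uneven illumination, or debris. Passing tests therefore
demonstrate correctness of the algorithms under idealized disk-like
signal, not robustness to every artifact of real microscopy.

# Detection

`detect_vesicles()` implements a gradient-voting circular Hough
transform on the (normalized) reference channel:

1. Gaussian pre-smoothing (`sigma_px = 1`) and central-difference
   gradients.
2. Edge pixels are those whose gradient magnitude exceeds
   `median + 6 x MAD` of the magnitude image, floored at 2% of the
   robust intensity range. The MAD term adapts to noise; the floor is
   needed because on noise-free rasters the median and MAD collapse to
   zero and faint anti-aliasing gradients would otherwise generate
   satellite detections.
3. Each edge pixel casts one vote per candidate radius (integer grid,
   step 1 px) at the point one radius along its gradient direction —
   for bright disks on a dark surround the gradient points into the
   lumen. Accumulator peaks above `sensitivity` (votes pooled over a
   3x3 neighbourhood, divided by the circumference `2*pi*r`) become
   candidates; sub-pixel centers come from the 3x3 centroid of the
   peak.
4. **Radius refinement.** The accumulator only resolves radii to the
   1-px grid, and for small disks gradient voting is biased inward. The
   refined radius is instead the half-height crossing of the
   azimuthally averaged radial intensity profile (lumen mean vs. the
   median of a surrounding annulus — median, so that intruding
   neighbours do not corrupt the floor). For a symmetric edge blur this
   crossing sits exactly at the true radius; it is applied twice so a
   coarse initial radius cannot anchor the profile window wrongly.
5. **Screening and suppression.** A filled-disk candidate must be
   brighter inside its circle than in its surrounding annulus
   (`min_contrast`). Of any candidate pair with center distance
   < 0.8 x (r1 + r2), only the higher-scoring survives; additionally,
   any candidate whose center lies inside a kept detection's circle is
   dropped — rim segments of large disks otherwise masquerade as small
   circles, while genuine neighbouring vesicles never place a center
   inside another vesicle under the placement rule above.

The default radius search range is 0.75–12.5 µm (1.5–25 µm diameters),
bracketing the 3–20 µm population with margin. An image smaller than
twice the maximum search radius is an error rather than a silent
truncation.

Evaluation against ground truth uses an explicit matching convention
(`match_detections()`): centers within 2 px and radii within 15%,
greedy in score order. Recall, precision and diameter errors in the
tests and the acceptance script are always relative to this rule.

# Normalization and background

`normalize_experiment()` maps the pooled 1st percentile of all pixels
sharing an experiment and channel to 0 and the pooled 99.9th percentile
to 1 (robust against hot pixels). One affine map per (experiment,
channel) preserves relative intensities across images, makes the
operation exactly idempotent, and values are never clipped so intensity
linearity survives. `estimate_background()` is the arithmetic mean over
a vesicle-free region; `auto_background_region()` automates the choice
by scanning blocks for the lowest mean. Background subtraction happens
after normalization, so one scalar per channel remains valid across an
experiment; corrected intensities may be slightly negative through
noise and are deliberately not clipped.

# Per-vesicle measurement and classification

`measure_vesicle()` takes the ROI as all pixels whose centers lie
within the detected circle — no partial weighting, mirroring a manual
circular-ROI measurement — and reports per-channel raw and
background-corrected means plus the diameter
`2 x radius_px x pixel_size_um`. ROIs under 5 px are flagged and
excluded from population statistics but never silently dropped, keeping
counts auditable.

The expressing classifier (`control_threshold()`,
`expressing_fraction()`) thresholds the background-corrected reporter
mean at the no-DNA control mean plus 3 sample standard deviations.
The comparison is strictly greater-than, so a degenerate all-control
population yields fraction 0. Population summaries use the
linear-interpolation (type 7) quantile convention.

Two quantitative caveats follow directly from the model and are borne
out by the test suite:

* The ROI mean under-estimates the lumen intensity by roughly
  `0.25/r` (rim pixels are dimmer by anti-aliasing), about 1% at the
  0.13 µm/px regime and ~5% for median-sized vesicles at 0.65 µm/px.
  Intensity-critical work should use the high-magnification regime.
* With a mean + 3 sd threshold, a non-expressing vesicle crosses the
  threshold by noise with probability ≈ 0.13%. Exact ON/OFF label
  recovery is therefore only a meaningful expectation when the expected
  number of such crossings is well below one (population of order 100),
  and only for vesicles whose lumen is not contaminated by a touching
  neighbour's rim; at 500 vesicles the *fraction* is still recovered
  to well within ±0.04, which is the population-level claim the
  package makes.

# The dose-response model

Receiver-cell fluorescence as a function of ligand concentration `X`
follows the four-parameter logistic (Hill) model

GFP(X) = b + (a − b) / (1 + 10^(h (log10 EC50 − log10 X)))

with maximal output `a`, basal output `b`, half-maximal concentration
`EC50` and Hill coefficient `h`; GFP(0) = b, GFP(EC50) = (a+b)/2, and
GFP → a at saturation. This is the standard form of the model written
with base-10 exponents; a literal reading of the commonly printed
exponent `10^{log(EC50 − X)·h}` would subtract a molarity from a
logarithm and is dimensionally inconsistent, so the package implements
the standard form, which reproduces every stated property of the curve.

`fit_dose_response()` fits each replicate independently by bounded
Levenberg-Marquardt least squares on `(a, b, log10 EC50, h)` and
summarizes EC50 and h as mean ± sample sd across replicates — the
convention for reporting n independent experiments. Start values are
`b0 = min(y)`, `a0 = max(y)`, `EC50` at the geometric mean of the
positive concentrations and `h0 = 1`, with bounds
`EC50 ∈ [min conc/100, max conc x 100]` and `h ∈ (0, 10]`;
zero-concentration wells enter the objective through the `X → 0` limit.
Because the least-squares surface develops shallow (`h → 0`) and
step-like (`h` at bound) local minima when few concentrations land in
the transition, the optimizer restarts from a small grid of 12
`(EC50, h)` combinations and keeps the lowest-deviance converged fit.

**Dilution series.** The default simulated assay uses a six-point
ten-fold serial dilution from 63.2 µM down to 632 pM. Note that
63.2 = 10^1.8 and that half-log (÷√10) steps reproduce exactly the
2.00/6.32 mantissa pattern of such series; `dilution_series(step =
sqrt(10))` yields the 11-point half-log variant over the same
endpoints. The ten-fold series leaves about one concentration inside
the transition of a 1 nM curve, which limits per-replicate EC50
precision; the half-log series is the sampling density consistent with
recovering EC50 to ~10% across three replicates, and it is the design
used for the package's Monte-Carlo acceptance check of EC50 recovery.

**Inverse quantification.** `hill_inverse()` is the exact algebraic
inverse on the open interval `(b, a)`. `estimate_titer()` inverts each
well of a dilution series, multiplies by the dilution factor to get a
per-well stock estimate, and pools usable wells by geometric mean
(concentrations are log-scale quantities). Wells within a margin
`m = 0.05` of either curve limit are flagged `saturated_high` or
`below_range` instead of inverted; a series with no usable well is an
error that reports the flags, which is exactly the "fully activated"
situation where a titer can only be bounded, not estimated.
`yield_per_inner_solution()` converts a sample concentration (nM) and
volume (µl) to pmol per µl of encapsulated inner solution; with equal
volumes 1 µM corresponds to 1 pmol/µl.

# Patterning analysis

`feature_decompose()` splits a binary mask into 4-connected components
and assigns each a width equal to twice its maximum Euclidean
distance-transform value (the largest inscribed disk) in µm; an
even-sided square of side s has width exactly s, and a 1-px line has
width 2 pixel-equivalents. `score_pattern()` reports:

* **contrast** — mean background-corrected reporter intensity of
  vesicles inside the mask over those outside (flagged when either
  population is empty);
* **fidelity** — the fraction of expressing vesicles whose centers lie
  inside the mask;
* **feature resolution** — a feature is resolved iff it contains at
  least `k = 3` expressing vesicles *and* its local contrast is at
  least `c_min = 2`. "Resolved" has no standard quantitative
  definition for such patterns, so the rule is declared, configurable,
  and tested against its own definition; the smallest resolvable
  feature width at a given vesicle density follows the Poisson
  expectation `density x area >= k`, which produces the monotone
  resolved/unresolved transition across stripe widths that the
  acceptance suite checks.

Mask-to-image registration is assumed given (both share one grid);
registering a physical photomask to stage coordinates is out of scope.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → detect → quantify → population
[→ pattern] and simulate-assay → fit → titer with flat-file handoffs
(16-bit TIFF rasters quantized against a fixed 65535 gray-unit full
scale, PNG masks, tidy CSV tables, JSON reports), so every stage is
independently inspectable. A JSON manifest records the package version,
a hash of the configuration and an MD5 checksum per output file; one
global seed is fanned out as per-stage derived seeds (seed + stage
index). Identical configuration and seed reproduce identical checksums
for every stage, which the test suite asserts. A thin command-line
wrapper lives at `inst/scripts/guvquant-pipeline.R`.

# Problem sizes and test design

The default test suite and the acceptance script use synthetic problem
sizes chosen to exercise every claim at comfortable margins: 1024x1024
fields with 100 vesicles for detection metrics, 768x768 fields with 500
(plus 200 control) vesicles for classification, a 512x1800 field with
stripes of 400/200/100/50 µm for patterning, 1400x1400 at 0.13 µm/px
with 200 truth-fed vesicles for measurement recovery, and 100 seeded
simulations for the EC50 Monte Carlo. The whole suite runs in under
two minutes on one CPU.

# Known limitations

* The detector assumes bright filled disks; rings (membrane dyes),
  ellipses and overlapping aggregates are out of scope.
* Absolute gray-unit intensities are instrument-specific; only
  relative and population-level structure is meaningful.
* OD600 is carried through assay tables but not used to normalize
  fluorescence, matching common practice for these reporter assays.
* Cross-ligand selectivity is represented only as separate fitted
  curves per ligand; no structure-activity modelling.
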