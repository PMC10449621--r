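# guvquant

Quantifying gene expression in synthetic-cell (GUV) populations and in
quorum-sensing reporter assays.

Synthetic cells built from giant unilamellar vesicles (GUVs) express
encoded genes heterogeneously: vesicles are polydisperse (3–20 µm in
diameter), reporter intensities span more than an order of magnitude, and
only a fraction of the population switches ON after activation. Making
quantitative claims about such populations — *what fraction expresses,
how bright, how faithfully does expression follow a patterned light
stimulus, how much signalling molecule did the vesicles synthesize* —
requires per-vesicle image quantification and calibrated dose–response
inversion rather than bulk averages. `guvquant` provides that workflow
for researchers building and characterizing synthetic cells:

* **Synthetic microscopy generator** — multi-channel GUV fields
  (reference dye channel TXR, reporter channel GFP) rendered as
  anti-aliased filled disks with exact per-vesicle ground truth
  (geometry, intensity, expression state, photomask membership), so
  every downstream step is testable without instrument data.
* **Vesicle detection** — per-experiment brightness normalization,
  vesicle-free background estimation, and a gradient-voting circular
  Hough detector with sub-pixel centers and sub-grid radii.
* **Per-vesicle quantification** — diameters in µm and
  background-corrected mean intensities per channel over circular ROIs.
* **Population analysis** — expressing-vesicle classification against a
  no-DNA control threshold (control mean + 3 s.d.), population
  summaries, and fold-activation (dynamic range) arithmetic.
* **Dose–response** — the four-parameter logistic (Hill) model

  GFP(X) = b + (a − b) / (1 + 10^(h·(log₁₀EC₅₀ − log₁₀X)))

  fitted per replicate by bounded least squares with a multi-start grid;
  exact algebraic inversion; titer estimation of unknown AHSL stocks
  from dilution series (per-well inversion × dilution factor, pooled by
  geometric mean, saturated/below-range wells flagged); and conversion
  of sample concentrations to biosynthetic yields in pmol per µl of
  inner solution.
* **Patterning analysis** — photomask feature decomposition (4-connected
  components, widths from the largest inscribed disk) and pattern
  scoring: inside/outside contrast, fidelity of expressing vesicles to
  the mask, and a declared feature-resolution rule.
* **Pipeline** — `run_pipeline()` orchestrates everything through
  plain-text file handoffs (TIFF/PNG/CSV/JSON) with a checksummed
  manifest; bit-reproducible under a fixed seed.

## Worked example

Simulate a field of synthetic cells plus a matched no-DNA control,
detect and measure every vesicle, classify expression, then
characterize receiver cells and invert an unknown titer:

```r
library(guvquant)

cfg  <- sim_image_config(field_size_px = c(512L, 512L), n_vesicles = 50L,
                         expressing_fraction = 0.9, rng_seed = 1L)
ctrl <- sim_image_config(field_size_px = c(512L, 512L), n_vesicles = 30L,
                         expressing_fraction = 0, rng_seed = 1001L)
sim_m <- simulate_field(cfg); sim_c <- simulate_field(ctrl)

norm <- normalize_experiment(image_set(c(unclass(sim_m$images),
                                         unclass(sim_c$images))))
imgs <- unclass(norm$images)
quantify <- function(set) {
  set <- image_set(set)
  det <- detect_vesicles(get_channel(set, "TXR"))
  bg <- vapply(c("TXR", "GFP"), function(ch) {
    im <- get_channel(set, ch); reg <- auto_background_region(im)
    estimate_background(im, reg$rows, reg$cols)$value
  }, numeric(1))
  quantify_image_set(set, det, bg)
}
rec  <- quantify(imgs[1:2])   # main field
recc <- quantify(imgs[3:4])   # control field

thr <- control_threshold(recc)
ef <- expressing_fraction(rec, thr)
rec$expressing <- ef$expressing
summarize_population(rec)

plate <- simulate_dose_response(assay_config(rng_seed = 1L))$plate
fit <- fit_dose_response(plate)
unknown <- simulate_unknown_titer(4e-7, c(200, 2000), fit$params,
                                  noise_cv = 0.05, rng_seed = 2L)
est <- estimate_titer(unknown$plate, fit)
yield_per_inner_solution(est$stock_molar * 1e9, 25, 5)
```

Output:

```
<control_threshold> mean=0.02837 sd=0.002088 threshold=0.03464 (n=30)
<population_summary> n=50  diameter 6.61 +/- 2.08 um (median 6.46)  GFP median 0.335
  expressing fraction = 0.940
<dose_response_fit> n=3 replicates
  EC50 = 1.03e-09 +/- 1e-10 M   h = 1.69 +/- 0.28
  a = 3.735e+04   b = 9787
<titer_estimate> stock = 3.774e-07 M (geometric sd 1.14) from 2 usable well(s)
yield: 1.887 pmol/ul inner solution
```

Reading it: all 50 vesicles were detected; the population's diameter
statistics (6.61 ± 2.08 µm) recover the generator's truncated log-normal
(6.5 ± 2.3 µm); 94% of vesicles exceed the control threshold (47/50 were
simulated ON at this seed). The dose–response fit recovers the
generating curve (true EC₅₀ = 1 nM) from three noisy replicates, and the
titer inversion recovers the simulated 400 nM stock within the 5%
well-to-well noise, converting to 1.9 pmol per µl of inner solution for
a 25 µl sample encapsulating 5 µl.

The end-to-end pipeline with file contracts and a manifest:

```r
cfg <- pipeline_config(outdir = "run1", seed = 1L,
                       sim = list(field_size_px = c(512L, 512L),
                                  n_vesicles = 50L))
manifest <- run_pipeline(cfg)
```

or from a shell: `Rscript inst/scripts/guvquant-pipeline.R --config
run.yaml --outdir run1 --seed 1`.

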