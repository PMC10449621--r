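# Shared fixtures, built in code at load time so test files can reuse them
# without re-rendering. Small fields keep the default run fast.

# a 384x384 default-SNR field with 20 vesicles, plus its normalized TXR
fix_field <- local({
  cfg <- sim_image_config(field_size_px = c(384L, 384L), n_vesicles = 20L,
                          rng_seed = 101L)
  sim <- simulate_field(cfg)
  norm <- normalize_experiment(sim$images)
  list(cfg = cfg, sim = sim, norm = norm,
       txr = get_channel(norm$images, "TXR"))
})

# single noise-free disk of known radius/intensity on a quiet background
render_single_disk <- function(radius_px, intensity = 50, nr = 128L,
                               nc = 128L, center = c(nr / 2, nc / 2),
                               background = 5, noise_sd = 0,
                               pixel_size_um = 0.65, seed = 1L) {
  dm <- list(meanlog = log(2 * radius_px * pixel_size_um), sdlog = 1e-6,
             min_um = 2 * radius_px * pixel_size_um * 0.99,
             max_um = 2 * radius_px * pixel_size_um * 1.01)
  cfg <- sim_image_config(field_size_px = c(nr, nc),
                          pixel_size_um = pixel_size_um, n_vesicles = 1L,
                          diameter_model = dm,
                          txr_intensity_model = list(meanlog = log(intensity),
                                                     sdlog = 1e-9),
                          background_level = c(TXR = background,
                                               GFP = background),
                          noise_sd = noise_sd, rng_seed = seed)
  simulate_field(cfg)
}

# quantify a simulated field end to end (normalize, detect or truth-feed,
# background from the emptiest block, measure)
quantify_field <- function(sim, detections = NULL, norm = NULL) {
  if (is.null(norm)) norm <- normalize_experiment(sim$images)
  if (is.null(detections))
    detections <- detect_vesicles(get_channel(norm$images, "TXR"))
  bg <- vapply(c("TXR", "GFP"), function(ch) {
    im <- get_channel(norm$images, ch)
    reg <- auto_background_region(im)
    estimate_background(im, reg$rows, reg$cols)$value
  }, numeric(1))
  list(records = quantify_image_set(norm$images, detections, bg),
       detections = detections, bg = bg, norm = norm)
}
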