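test_that("empty field renders background plus noise and an empty truth table", {
  cfg <- sim_image_config(field_size_px = c(64L, 64L), n_vesicles = 0L,
                          rng_seed = 2L)
  sim <- simulate_field(cfg)
  expect_equal(nrow(sim$truth), 0)
  txr <- get_channel(sim$images, "TXR")$pixels
  expect_equal(mean(txr), 5, tolerance = 0.02)   # background 5, noise mean 0
  cfg0 <- sim_image_config(field_size_px = c(64L, 64L), n_vesicles = 0L,
                           noise_sd = 0, rng_seed = 2L)
  expect_true(all(get_channel(simulate_field(cfg0)$images, "TXR")$pixels == 5))
})

test_that("identical seeds give bit-identical rasters and truth", {
  cfg <- sim_image_config(field_size_px = c(128L, 128L), n_vesicles = 8L,
                          rng_seed = 7L)
  a <- simulate_field(cfg); b <- simulate_field(cfg)
  expect_identical(get_channel(a$images, "TXR")$pixels,
                   get_channel(b$images, "TXR")$pixels)
  expect_identical(get_channel(a$images, "GFP")$pixels,
                   get_channel(b$images, "GFP")$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("default diameter model reproduces the GUV population statistics", {
  set.seed(11)
  dm <- formals(sim_image_config)$diameter_model
  d <- rtrunclnorm(1e4, 1.7924440389, 0.3588646867, 3, 20)
  expect_true(all(d >= 3 & d <= 20))
  expect_equal(mean(d), 6.5, tolerance = 0.2 / 6.5)
  expect_equal(sd(d), 2.3, tolerance = 0.2 / 2.3)
})

test_that("fit_truncated_lognormal recovers the frozen default parameters", {
  f <- fit_truncated_lognormal(6.5, 2.3, 3, 20)
  expect_equal(f$meanlog, 1.7924440389, tolerance = 1e-4)
  expect_equal(f$sdlog, 0.3588646867, tolerance = 1e-4)
  m <- truncated_lognormal_moments(f$meanlog, f$sdlog, 3, 20)
  expect_equal(unname(m["mean"]), 6.5, tolerance = 1e-6)
  expect_equal(unname(m["sd"]), 2.3, tolerance = 1e-6)
})

test_that("expressing-state reporter intensities span an order of magnitude", {
  gm <- formals(sim_image_config)$gfp_on_model
  gm <- eval(gm)
  q <- qlnorm(c(0.05, 0.95), gm$meanlog, gm$sdlog)
  expect_gte(q[2] / q[1], 10)
})

test_that("rendered disk intensity matches truth within anti-aliasing tolerance", {
  # high-magnification regime: ROI-mean rim bias is within the 2% budget
  sim <- render_single_disk(radius_px = 25, intensity = 80,
                            nr = 128L, nc = 128L, pixel_size_um = 0.13)
  rec <- measure_vesicle(sim$images,
                         truth_as_detections(sim$truth, 0.13)[1, ],
                         bg = c(TXR = 5, GFP = 5))
  expect_equal(rec$mean_txr_corr, sim$truth$txr, tolerance = 0.02)
})

test_that("all-ones mask reproduces the unmasked simulation bit-exactly", {
  cfg <- sim_image_config(field_size_px = c(128L, 128L), n_vesicles = 8L,
                          rng_seed = 5L)
  plain <- simulate_field(cfg)
  ones <- simulate_patterned_field(cfg, matrix(1, 128, 128))
  expect_identical(get_channel(plain$images, "GFP")$pixels,
                   get_channel(ones$images, "GFP")$pixels)
  expect_equal(plain$truth$expressing, ones$truth$expressing)
})

test_that("all-zeros mask forces every vesicle OFF", {
  cfg <- sim_image_config(field_size_px = c(128L, 128L), n_vesicles = 8L,
                          expressing_fraction = 1, rng_seed = 5L)
  sim <- simulate_patterned_field(cfg, matrix(0, 128, 128))
  expect_true(all(!sim$truth$expressing))
  expect_true(all(!sim$truth$inside_mask))
})

test_that("stripe mask confines expressing vesicle centers to the stripes", {
  fs <- c(256L, 512L)
  mask <- stripe_mask(fs, c(60, 60), gap_um = 60, pixel_size_um = 0.65)
  cfg <- sim_image_config(field_size_px = fs, n_vesicles = 30L,
                          expressing_fraction = 1, rng_seed = 13L)
  sim <- simulate_patterned_field(cfg, mask)
  tr <- sim$truth
  idx <- cbind(pmin(pmax(round(tr$row), 1L), fs[1]),
               pmin(pmax(round(tr$col), 1L), fs[2]))
  expect_true(all(mask[idx[tr$expressing, , drop = FALSE]] == 1))
  expect_equal(tr$inside_mask, mask[idx] == 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_image_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(sim_image_config(expressing_fraction = 1.2),
               "expressing_fraction")
  expect_error(sim_image_config(diameter_model = list(
    meanlog = 1, sdlog = 0.3, min_um = 3, max_um = 2)), "bounds")
  expect_error(sim_image_config(field_size_px = c(64L, 64L),
                                mask = matrix(1, 32, 32)), "mask")
  expect_error(simulate_patterned_field(
    sim_image_config(field_size_px = c(64L, 64L)),
    matrix(0.5, 64, 64)), "binary")
})

test_that("overcrowded fields fail with an informative placement error", {
  cfg <- sim_image_config(field_size_px = c(64L, 64L), n_vesicles = 400L,
                          pixel_size_um = 0.65, rng_seed = 1L)
  expect_error(simulate_field(cfg), "achievable density")
})
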