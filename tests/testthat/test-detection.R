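test_that("normalization applies one shared affine map per experiment and channel", {
  grad <- matrix(seq(0, 100, length.out = 64 * 64), 64, 64)
  im1 <- channel_image(grad, "TXR", 0.65, experiment_id = "e1")
  im2 <- channel_image(2 * grad + 10, "TXR", 0.65, experiment_id = "e1")
  norm <- normalize_experiment(image_set(im1, im2))
  n1 <- norm$images[[1]]$pixels; n2 <- norm$images[[2]]$pixels
  # shared map preserves relative intensities: pixelwise affine consistency
  lo <- norm$model$low_anchor; hi <- norm$model$high_anchor
  expect_equal(n2, 2 * n1 + (lo + 10) / (hi - lo), tolerance = 1e-12)
  # single image: anchors map to [0, 1]
  solo <- normalize_experiment(image_set(im1))
  q <- quantile(solo$images[[1]]$pixels, c(0.01, 0.999), names = FALSE)
  expect_equal(q[1], 0, tolerance = 1e-12)
  expect_equal(q[2], 1, tolerance = 1e-12)
})

test_that("normalization is idempotent", {
  n1 <- normalize_experiment(fix_field$sim$images)
  n2 <- normalize_experiment(n1$images)
  expect_equal(n1$images[[1]]$pixels, n2$images[[1]]$pixels,
               tolerance = 1e-12)
})

test_that("normalization rejects empty or constant-valued input", {
  expect_error(normalize_experiment(list()), "non-empty")
  flat <- channel_image(matrix(3, 32, 32), "TXR", 0.65)
  expect_error(normalize_experiment(image_set(flat)), "degenerate")
})

test_that("background estimation is the arithmetic mean of the region", {
  im <- channel_image(matrix(4.5, 64, 64), "GFP", 0.65)
  expect_equal(estimate_background(im, 1:10, 1:10)$value, 4.5)
  expect_error(estimate_background(im, integer(0), 1:10), "empty")
  expect_error(estimate_background(im, 60:70, 1:10), "bounds")
  det <- data.frame(row = 5, col = 5, radius_px = 2)
  expect_warning(estimate_background(im, 1:10, 1:10, detections = det),
                 "overlaps")
})

test_that("background recovered from a simulated field matches the generator level", {
  # on the raw (unnormalized) field the emptiest block averages to the
  # configured background within noise sd / sqrt(n)
  im <- get_channel(fix_field$sim$images, "TXR")
  reg <- auto_background_region(im)
  bg <- estimate_background(im, reg$rows, reg$cols)
  tol <- 5 * fix_field$cfg$noise_sd / sqrt(length(reg$rows) *
                                             length(reg$cols))
  expect_lt(abs(bg$value - 5), max(tol, 0.05))
})

test_that("a blank image yields no detections", {
  set.seed(1)
  im <- channel_image(matrix(abs(rnorm(128^2, 5, 0.1)), 128, 128),
                      "TXR", 0.65)
  expect_equal(nrow(detect_vesicles(im)), 0)
})

test_that("a single rendered disk is detected with sub-pixel accuracy", {
  sim <- render_single_disk(radius_px = 10, intensity = 50, nr = 100L,
                            nc = 100L, noise_sd = 1)  # SNR 50
  txr <- get_channel(normalize_experiment(sim$images)$images, "TXR")
  det <- detect_vesicles(txr)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$row - sim$truth$row), 1)
  expect_lt(abs(det$col - sim$truth$col), 1)
  expect_lt(abs(det$radius_px - 10), 1)
})

test_that("detection on a crowded default-SNR field is near-perfect", {
  cfg <- sim_image_config(field_size_px = c(512L, 512L), n_vesicles = 50L,
                          rng_seed = 31L)
  sim <- simulate_field(cfg)
  txr <- get_channel(normalize_experiment(sim$images)$images, "TXR")
  det <- detect_vesicles(txr)
  m <- match_detections(det, sim$truth, cfg$pixel_size_um)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  cfg <- sim_image_config(field_size_px = c(256L, 256L), n_vesicles = 8L,
                          noise_sd = 0, rng_seed = 17L)
  sim <- simulate_field(cfg)
  px <- get_channel(sim$images, "TXR")$pixels
  dr <- 7L; dc <- 11L
  shifted <- matrix(5, 256, 256)  # background level
  shifted[(1 + dr):256, (1 + dc):256] <- px[1:(256 - dr), 1:(256 - dc)]
  d0 <- detect_vesicles(channel_image(px, "TXR", 0.65))
  d1 <- detect_vesicles(channel_image(shifted, "TXR", 0.65))
  # every interior detection must have a counterpart at exactly the offset
  interior <- d0$row + dr < 250 & d0$col + dc < 250 &
    d0$row > 5 & d0$col > 5
  for (i in which(interior)) {
    dd <- sqrt((d1$row - d0$row[i] - dr)^2 + (d1$col - d0$col[i] - dc)^2)
    expect_lt(min(dd), 0.05)
    j <- which.min(dd)
    expect_equal(d1$radius_px[j], d0$radius_px[i], tolerance = 0.01)
  }
})

test_that("recall degrades monotonically as noise increases", {
  recalls <- vapply(c(1, 3, 6, 10, 16), function(mult) {
    matched <- 0; total <- 0
    for (s in 1:3) {
      cfg <- sim_image_config(field_size_px = c(384L, 384L),
                              n_vesicles = 15L, noise_sd = mult,
                              rng_seed = s)
      sim <- simulate_field(cfg)
      txr <- get_channel(normalize_experiment(sim$images)$images, "TXR")
      m <- match_detections(detect_vesicles(txr), sim$truth, 0.65)
      matched <- matched + m$n_matched; total <- total + nrow(sim$truth)
    }
    matched / total
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})

test_that("no detection pair violates the overlap rule after suppression", {
  det <- detect_vesicles(fix_field$txr)
  if (nrow(det) > 1) {
    d <- as.matrix(dist(det[, c("row", "col")]))
    rsum <- outer(det$radius_px, det$radius_px, "+")
    off <- upper.tri(d)
    expect_true(all(d[off] >= 0.8 * rsum[off]))
  }
  expect_gte(nrow(det), 1)
})

test_that("out-of-range radius search is rejected", {
  im <- channel_image(matrix(5, 64, 64), "TXR", 0.65)
  expect_error(detect_vesicles(im, radius_range_um = c(5, 50)),
               "radius range out of bounds")
  expect_error(detect_vesicles(im, radius_range_um = c(2, 1)),
               "increasing")
})
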