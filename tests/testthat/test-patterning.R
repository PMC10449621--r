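test_that("feature decomposition: widths from the largest inscribed disk", {
  # even-sided filled square: width equals the side exactly
  m <- matrix(0, 20, 20); m[5:12, 5:12] <- 1
  f <- feature_decompose(m, pixel_size_um = 2)
  expect_equal(nrow(f), 1)
  expect_equal(f$width_um, 8 * 2)
  expect_equal(f$area_px, 64)
  # 1-px line: distance transform max 1 -> width 2 pixel-equivalents
  ln <- matrix(0, 9, 9); ln[5, 2:8] <- 1
  expect_equal(feature_decompose(ln, 1)$width_um, 2)
  # two disjoint squares -> two features
  m2 <- matrix(0, 20, 20); m2[2:5, 2:5] <- 1; m2[10:13, 10:13] <- 1
  expect_equal(nrow(feature_decompose(m2, 1)), 2)
  # diagonal touch is not connected (4-connectivity)
  m3 <- matrix(0, 5, 5); m3[1, 1] <- 1; m3[2, 2] <- 1
  expect_equal(nrow(feature_decompose(m3, 1)), 2)
  expect_equal(nrow(feature_decompose(matrix(0, 4, 4), 1)), 0)
})

pat_records <- function(row, col, gfp, expressing) {
  data.frame(row = row, col = col, mean_gfp_corr = gfp,
             expressing = expressing)
}

test_that("all-covering mask gives fidelity 1 and flags the missing outside population", {
  rec <- pat_records(c(10, 20), c(10, 20), c(5, 6), c(TRUE, TRUE))
  ps <- score_pattern(rec, matrix(1, 32, 32), 1)
  expect_equal(ps$fidelity, 1)
  expect_true(is.na(ps$contrast))
  expect_equal(ps$contrast_flag, "no_outside_population")
})

test_that("pattern scoring errors on empty inputs", {
  rec <- pat_records(1, 1, 1, TRUE)
  expect_error(score_pattern(rec, matrix(0, 8, 8), 1), "empty mask")
  expect_error(score_pattern(rec[0, ], matrix(1, 8, 8), 1), "no records")
})

test_that("fidelity is invariant under record relabeling and rigid translation", {
  mask <- matrix(0, 64, 64); mask[, 17:32] <- 1
  set.seed(3)
  n <- 30
  rec <- pat_records(runif(n, 5, 60), runif(n, 5, 60),
                     rlnorm(n, log(5), 0.5), runif(n) < 0.5)
  ps1 <- score_pattern(rec, mask, 1)
  ps2 <- score_pattern(rec[sample(n), ], mask, 1)
  expect_equal(ps2$fidelity, ps1$fidelity)
  # translate both mask and records by the same offset
  mask_t <- matrix(0, 64, 64); mask_t[, 25:40] <- 1
  rec_t <- rec; rec_t$col <- rec$col + 8
  rec_t <- rec_t[rec_t$col <= 64, ]
  rec_keep <- rec[rec$col + 8 <= 64, ]
  ps3 <- score_pattern(rec_keep, mask, 1)
  ps4 <- score_pattern(rec_t, mask_t, 1)
  expect_equal(ps4$fidelity, ps3$fidelity)
})

test_that("patterned simulation scores high fidelity and contrast above one", {
  fs <- c(256L, 512L)
  mask <- stripe_mask(fs, c(80, 80), gap_um = 60, pixel_size_um = 0.65)
  cfg <- sim_image_config(field_size_px = fs, n_vesicles = 40L,
                          expressing_fraction = 1, noise_sd = 0,
                          rng_seed = 23L)
  sim <- simulate_patterned_field(cfg, mask)
  rec <- quantify_image_set(sim$images,
                            truth_as_detections(sim$truth, 0.65),
                            bg = c(TXR = 5, GFP = 5))
  rec$expressing <- sim$truth$expressing
  ps <- score_pattern(rec, mask, 0.65)
  expect_equal(ps$fidelity, 1)
  expect_gt(ps$contrast, 1)
  expect_equal(ps$features$width_um, c(80, 80), tolerance = 0.02)
})

test_that("resolved features require both vesicle count and local contrast", {
  mask <- matrix(0, 64, 64)
  mask[10:25, 10:25] <- 1   # 16-px square, populated
  mask[40:55, 40:55] <- 1   # 16-px square, empty
  rec <- pat_records(row = c(12, 15, 20, 5, 60),
                     col = c(12, 15, 20, 60, 5),
                     gfp = c(10, 12, 11, 1, 1),
                     expressing = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  ps <- score_pattern(rec, mask, pixel_size_um = 2, k = 3, c_min = 2)
  expect_equal(ps$features$resolved, c(TRUE, FALSE))
  expect_equal(ps$min_resolved_width_um, 16 * 2)
  # raising k beyond the population leaves nothing resolved
  ps2 <- score_pattern(rec, mask, pixel_size_um = 2, k = 4, c_min = 2)
  expect_true(all(!ps2$features$resolved))
  expect_true(is.na(ps2$min_resolved_width_um))
})
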