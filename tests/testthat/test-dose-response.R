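test_that("Hill forward evaluation honors its limit properties", {
  p <- c(a = 100, b = 10, ec50 = 3e-9, h = 1.7)
  expect_equal(hill_forward(p, 3e-9), 55)        # midpoint
  expect_equal(hill_forward(p, 0), 10)           # zero-ligand limit
  expect_equal(hill_forward(p, 1), 100, tolerance = 1e-6)  # saturation
  p2 <- c(a = 1, b = 0, ec50 = 1e-9, h = 1)
  expect_equal(hill_forward(p2, 1e-8), 10 / 11)
  # monotone increasing for h > 0
  x <- 10^seq(-12, -6, length.out = 50)
  expect_true(all(diff(hill_forward(p, x)) > 0))
  expect_error(hill_forward(c(a = 1, b = 2, ec50 = 1e-9, h = 1), 1e-9),
               "a > b")
  expect_error(hill_forward(p, -1), ">= 0")
})

test_that("Hill inverse is the exact algebraic inverse on the dynamic range", {
  p <- c(a = 1, b = 0, ec50 = 1e-9, h = 1)
  expect_equal(hill_inverse(p, 10 / 11), 1e-8, tolerance = 1e-12)
  expect_equal(hill_inverse(p, 0.5), 1e-9, tolerance = 1e-12)
  set.seed(6)
  p2 <- c(a = 120, b = 8, ec50 = 2.4e-9, h = 1.38)
  y <- runif(100, 8 + 1e-6, 120 - 1e-6)
  expect_equal(hill_forward(p2, hill_inverse(p2, y)), y, tolerance = 1e-9)
  # out-of-range values return NA
  expect_true(is.na(hill_inverse(p2, 8)))
  expect_true(is.na(hill_inverse(p2, 121)))
})

test_that("noise-free fitting recovers the generating parameters", {
  cfg <- assay_config(noise_cv = 0, rng_seed = 1L)
  fit <- fit_dose_response(simulate_dose_response(cfg)$plate)
  tp <- cfg$true_params
  for (nm in c("a", "b", "ec50", "h"))
    expect_equal(unname(fit$params[nm]), unname(tp[nm]),
                 tolerance = 1e-4)
  expect_true(all(fit$per_replicate$converged))
  expect_equal(fit$summary$ec50_sd, 0, tolerance = 1e-12)
})

test_that("recovered Hill coefficients preserve the true ordering", {
  f138 <- fit_dose_response(simulate_dose_response(assay_config(
    true_params = c(a = 36000, b = 10000, ec50 = 3.93e-9, h = 1.38),
    noise_cv = 0))$plate)
  f141 <- fit_dose_response(simulate_dose_response(assay_config(
    true_params = c(a = 36000, b = 10000, ec50 = 2.68e-9, h = 1.41),
    noise_cv = 0))$plate)
  expect_equal(f138$summary$h_mean, 1.38, tolerance = 1e-4)
  expect_equal(f141$summary$h_mean, 1.41, tolerance = 1e-4)
  expect_lt(f138$summary$h_mean, f141$summary$h_mean)
})

test_that("degenerate plates are rejected with informative errors", {
  plate <- data.frame(concentration_molar = c(1e-9, 1e-8, 1e-7),
                      fluorescence = c(1, 2, 3), replicate = 1)
  expect_error(fit_dose_response(plate), "5 distinct")
  flat <- simulate_dose_response(assay_config(noise_cv = 0))$plate
  flat$fluorescence <- 100
  expect_error(fit_dose_response(flat), "unidentifiable")
})

test_that("noise-free titer estimation recovers the stock across dilutions", {
  curve <- c(a = 36000, b = 10000, ec50 = 1e-9, h = 1.4)
  ut <- simulate_unknown_titer(4e-7, c(200, 2000), curve, noise_cv = 0)
  est <- estimate_titer(ut$plate, curve)
  expect_equal(est$stock_molar, 4e-7, tolerance = 1e-6)
  expect_equal(est$n_usable, 2)
  # per-well stock estimates agree regardless of which dilution is used
  ok <- est$wells$flag == "ok"
  expect_equal(diff(range(est$wells$stock_molar[ok])), 0, tolerance = 1e-12)
})

test_that("saturated and below-range wells are flagged, never inverted", {
  curve <- c(a = 36000, b = 10000, ec50 = 1e-9, h = 1.4)
  sat <- simulate_unknown_titer(1e-3, c(200, 2000), curve, noise_cv = 0)
  expect_error(estimate_titer(sat$plate, curve), "saturated")
  low <- simulate_unknown_titer(1e-13, c(200, 2000), curve, noise_cv = 0)
  expect_error(estimate_titer(low$plate, curve), "below_range|dynamic range")
  # mixed: saturated well flagged, in-range well still estimates
  mix <- simulate_unknown_titer(2e-7, c(2, 1000), curve, noise_cv = 0)
  est <- estimate_titer(mix$plate, curve)
  expect_equal(est$wells$flag, c("saturated_high", "ok"))
  expect_equal(est$stock_molar, 2e-7, tolerance = 1e-6)
})

test_that("titer estimation is equivariant under dilution/stock rescaling", {
  curve <- c(a = 36000, b = 10000, ec50 = 1e-9, h = 1.4)
  u1 <- simulate_unknown_titer(4e-7, c(200, 2000), curve, noise_cv = 0)
  u2 <- simulate_unknown_titer(2e-7, c(100, 1000), curve, noise_cv = 0)
  expect_equal(u1$plate$fluorescence, u2$plate$fluorescence)
  e1 <- estimate_titer(u1$plate, curve)
  e2 <- estimate_titer(u2$plate, curve)
  expect_equal(e2$stock_molar, e1$stock_molar / 2, tolerance = 1e-9)
})

test_that("yield conversion follows nM x ul / ul / 1000 and its identity case", {
  expect_equal(yield_per_inner_solution(458.5, 25, 5), 2.2925)
  expect_equal(yield_per_inner_solution(32.5, 25, 5), 0.1625)
  expect_equal(yield_per_inner_solution(0, 25, 5), 0)
  # equal volumes: 1 uM corresponds to 1 pmol/ul
  expect_equal(yield_per_inner_solution(17.9e3, 10, 10), 17.9)
  expect_error(yield_per_inner_solution(1, 0, 5), "volumes")
  expect_error(yield_per_inner_solution(-1, 5, 5), "conc_nM")
})
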