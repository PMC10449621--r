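# Synthetic 96-well receiver-cell assays: dose-response plates generated
# from a known Hill curve with multiplicative log-normal noise, and
# "unknown titer" dilution-series plates with a known stock concentration.

#' Configuration for synthetic dose-response plates
#'
#' Defaults emulate a receiver-cell characterization assay: a six-point
#' ten-fold serial dilution from 63.2 uM down to 632 pM, n = 3
#' independent replicates, a curve with EC50 = 1 nM, Hill coefficient 1.4
#' and a 3.6-fold ON/OFF dynamic range, and 10 percent multiplicative
#' (coefficient-of-variation) noise. A zero-concentration (carrier-only)
#' well per replicate measures the OFF state.
#'
#' @param true_params Named Hill parameters `c(a=, b=, ec50=, h=)` (see
#'   [hill_params()]).
#' @param concentration_series Strictly decreasing positive molarities;
#'   default [dilution_series()].
#' @param n_replicates Number of independent replicates.
#' @param noise_cv Multiplicative log-normal noise CV (>= 0).
#' @param include_zero_well Include a zero-concentration well per
#'   replicate.
#' @param od600_mean,od600_cv Simulated optical density (carried through
#'   the table but not used for normalization).
#' @param rng_seed Integer seed.
#' @return Validated list of class `assay_config`.
#' @export
assay_config <- function(true_params = c(a = 36000, b = 10000,
                                         ec50 = 1e-9, h = 1.4),
                         concentration_series = dilution_series(),
                         n_replicates = 3L,
                         noise_cv = 0.10,
                         include_zero_well = TRUE,
                         od600_mean = 0.05, od600_cv = 0.05,
                         rng_seed = 1L) {
  hill_params(true_params)
  if (any(concentration_series <= 0) ||
      any(diff(concentration_series) >= 0))
    stop("`concentration_series` must be strictly positive and decreasing")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  structure(list(true_params = true_params,
                 concentration_series = concentration_series,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv,
                 include_zero_well = isTRUE(include_zero_well),
                 od600_mean = od600_mean, od600_cv = od600_cv,
                 rng_seed = as.integer(rng_seed)),
            class = "assay_config")
}

# multiplicative log-normal noise factor with mean exactly 1 and the
# requested coefficient of variation
lnorm_noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

well_ids <- function(n) {
  sprintf("%s%02d", LETTERS[((seq_len(n) - 1) %/% 12) + 1],
          ((seq_len(n) - 1) %% 12) + 1)
}

#' Simulate a dose-response plate from a known Hill curve
#'
#' Fluorescence per well is the noise-free Hill evaluation times an
#' independent log-normal factor of mean 1 and CV `noise_cv`;
#' zero-concentration wells evaluate to the basal level `b` before noise.
#' Replicates are independent; output is seeded and fully reproducible.
#'
#' @param config An `assay_config`.
#' @return List with `plate` (tidy data frame: `well_id, replicate,
#'   concentration_molar, fluorescence, od600, condition_label`) and
#'   `truth` (the generating parameters).
#' @export
simulate_dose_response <- function(config) {
  if (!inherits(config, "assay_config")) stop("`config` must be an assay_config")
  set.seed(config$rng_seed)
  conc <- config$concentration_series
  if (config$include_zero_well) conc <- c(conc, 0)
  grid <- expand.grid(concentration_molar = conc,
                      replicate = seq_len(config$n_replicates))
  mu <- hill_forward(config$true_params, grid$concentration_molar)
  fl <- mu * lnorm_noise_factor(nrow(grid), config$noise_cv)
  od <- config$od600_mean *
    (1 + stats::rnorm(nrow(grid), 0, config$od600_cv))
  plate <- data.frame(well_id = well_ids(nrow(grid)),
                      replicate = grid$replicate,
                      concentration_molar = grid$concentration_molar,
                      fluorescence = fl, od600 = od,
                      condition_label = "dose_response")
  list(plate = plate, truth = config$true_params)
}

#' Simulate an unknown-titer dilution-series plate
#'
#' Emulates quantifying a biosynthetic ligand stock by serial dilution
#' into receiver cells: each well's assay concentration is
#' `stock_conc / dilution_factor`, fluorescence follows the Hill curve
#' plus multiplicative noise, and the truth records the stock.
#'
#' @param stock_conc True stock concentration, molar (> 0).
#' @param dilution_factors Dilution factors (>= 1), one well per factor
#'   per replicate.
#' @param curve Named Hill parameters of the receiver cells.
#' @param noise_cv Multiplicative noise CV.
#' @param n_replicates Number of replicates.
#' @param od600_mean,od600_cv Simulated optical density.
#' @param rng_seed Integer seed.
#' @return List with `plate` (data frame: `well_id, replicate,
#'   dilution_factor, concentration_molar, fluorescence, od600,
#'   condition_label`) and `truth` (`stock_conc`).
#' @export
simulate_unknown_titer <- function(stock_conc, dilution_factors,
                                   curve, noise_cv = 0.10,
                                   n_replicates = 1L,
                                   od600_mean = 0.05, od600_cv = 0.05,
                                   rng_seed = 1L) {
  if (stock_conc <= 0) stop("`stock_conc` must be > 0")
  if (any(dilution_factors < 1)) stop("dilution factors must be >= 1")
  hill_params(curve)
  set.seed(as.integer(rng_seed))
  grid <- expand.grid(dilution_factor = dilution_factors,
                      replicate = seq_len(n_replicates))
  conc <- stock_conc / grid$dilution_factor
  fl <- hill_forward(curve, conc) * lnorm_noise_factor(nrow(grid), noise_cv)
  od <- od600_mean * (1 + stats::rnorm(nrow(grid), 0, od600_cv))
  plate <- data.frame(well_id = well_ids(nrow(grid)),
                      replicate = grid$replicate,
                      dilution_factor = grid$dilution_factor,
                      concentration_molar = conc,
                      fluorescence = fl, od600 = od,
                      condition_label = "unknown_titer")
  list(plate = plate, truth = list(stock_conc = stock_conc))
}
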