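# Four-parameter logistic (Hill) dose-response model, per-replicate
# least-squares fitting, inverse prediction of ligand concentrations, and
# titer back-calculation from dilution series.
#
# Model: GFP(X) = b + (a - b) / (1 + 10^(h * (log10(EC50) - log10(X))))
# with GFP(0) = b, GFP(EC50) = (a + b)/2 and GFP -> a as X -> Inf.

#' Validate Hill parameters
#'
#' @param params Named numeric `c(a=, b=, ec50=, h=)`: maximal output `a`,
#'   basal output `b` (a > b >= 0), half-maximal concentration `ec50`
#'   (molar, > 0) and Hill coefficient `h` (> 0).
#' @return `params`, invisibly; errors otherwise.
#' @export
hill_params <- function(params) {
  req <- c("a", "b", "ec50", "h")
  if (!all(req %in% names(params)))
    stop("`params` must be named c(a=, b=, ec50=, h=)")
  p <- params[req]
  if (!all(is.finite(p))) stop("Hill parameters must be finite")
  if (p[["a"]] <= p[["b"]]) stop("require a > b")
  if (p[["b"]] < 0) stop("require b >= 0")
  if (p[["ec50"]] <= 0) stop("require ec50 > 0")
  if (p[["h"]] <= 0) stop("require h > 0")
  invisible(p)
}

#' Evaluate the Hill dose-response curve
#'
#' @param params Named numeric `c(a=, b=, ec50=, h=)` (see [hill_params()]).
#' @param x Ligand concentrations, molar (>= 0); `x = 0` evaluates to the
#'   basal level `b` (the zero-ligand limit).
#' @return Fluorescence output, same length as `x`.
#' @export
hill_forward <- function(params, x) {
  p <- hill_params(params)
  if (any(x < 0)) stop("`x` must be >= 0")
  out <- rep(p[["b"]], length(x))
  pos <- x > 0
  out[pos] <- p[["b"]] + (p[["a"]] - p[["b"]]) /
    (1 + 10^(p[["h"]] * (log10(p[["ec50"]]) - log10(x[pos]))))
  out
}

#' Invert the Hill curve: concentration from fluorescence
#'
#' Algebraic inverse `X = EC50 * ((a - b)/(GFP - b) - 1)^(-1/h)`, defined
#' on the open dynamic range `(b, a)`. Values at or outside the range
#' return `NA` (use [estimate_titer()] for margin-based flagging).
#'
#' @param params Named numeric `c(a=, b=, ec50=, h=)`.
#' @param gfp Fluorescence values.
#' @return Concentrations, molar; `NA` where `gfp` is outside `(b, a)`.
#' @export
hill_inverse <- function(params, gfp) {
  p <- hill_params(params)
  out <- rep(NA_real_, length(gfp))
  ok <- gfp > p[["b"]] & gfp < p[["a"]]
  out[ok] <- p[["ec50"]] *
    ((p[["a"]] - p[["b"]]) / (gfp[ok] - p[["b"]]) - 1)^(-1 / p[["h"]])
  out
}

#' Fit the Hill curve to a plate table, per replicate
#'
#' Each replicate is fitted independently by bounded Levenberg-Marquardt
#' least squares on `(a, b, log10 EC50, h)`; the cross-replicate summary
#' reports the mean and sample sd of EC50 and h, the convention for
#' reporting n independent experiments. Start values: `b0 = min(y)`,
#' `a0 = max(y)`, `EC50_0` = geometric mean of the positive
#' concentrations, `h0 = 1`; bounds `EC50 in [min conc/100, max conc*100]`
#' and `h in (0, 10]`. Zero-concentration wells enter the objective
#' through the `X -> 0` limit (`GFP = b`).
#'
#' @param plate Data frame with columns `concentration_molar`,
#'   `fluorescence` and `replicate`.
#' @return Object of class `dose_response_fit`: `per_replicate` (data
#'   frame of parameter estimates, residual norms and convergence flags),
#'   `summary` (means and sds across replicates) and `params` (the
#'   mean-parameter curve used for inversion).
#' @export
fit_dose_response <- function(plate) {
  require_columns(plate, c("concentration_molar", "fluorescence", "replicate"),
                  "plate table")
  reps <- sort(unique(plate$replicate))
  conc_all <- unique(plate$concentration_molar[plate$concentration_molar > 0])
  if (length(unique(plate$concentration_molar)) < 5)
    stop("need >= 5 distinct concentrations to identify the curve")
  fits <- lapply(reps, function(rep_i) {
    d <- plate[plate$replicate == rep_i, , drop = FALSE]
    x <- d$concentration_molar; y <- d$fluorescence
    if (diff(range(y)) <= 1e-9 * max(abs(y), 1))
      stop("all-flat fluorescence: EC50 is unidentifiable")
    hillf <- function(p) {
      out <- rep(p[2], length(x))
      pos <- x > 0
      out[pos] <- p[2] + (p[1] - p[2]) /
        (1 + 10^(p[4] * (p[3] - log10(x[pos]))))
      out
    }
    lower <- c(a = -Inf, b = -Inf, lec = log10(min(conc_all)) - 2,
               h = 1e-3)
    upper <- c(a = Inf, b = Inf, lec = log10(max(conc_all)) + 2, h = 10)
    # the least-squares surface has shallow/step-like local minima when few
    # concentrations land in the transition, so run a small multi-start
    # grid over (EC50, h) and keep the lowest-deviance converged fit
    lec_grid <- c(mean(log10(conc_all)),
                  stats::quantile(log10(conc_all), c(0.25, 0.75),
                                  names = FALSE))
    fit <- NULL
    for (lec0 in lec_grid) for (h0 in c(0.5, 1, 2, 4)) {
      start <- c(a = max(y), b = min(y), lec = lec0, h = h0)
      f <- minpack.lm::nls.lm(
        par = start, fn = function(p) y - hillf(p),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000))
      if (f$info %in% 1:3 && (is.null(fit) || f$deviance < fit$deviance))
        fit <- f
    }
    if (is.null(fit))
      stop(sprintf("replicate %s: Hill fit did not converge from any start",
                   rep_i))
    cf <- fit$par
    data.frame(replicate = rep_i, a = cf[["a"]], b = cf[["b"]],
               ec50 = 10^cf[["lec"]], h = cf[["h"]],
               rss = fit$deviance,
               converged = TRUE)
  })
  per_rep <- do.call(rbind, fits)
  rownames(per_rep) <- NULL
  sdv <- function(v) if (length(v) > 1) stats::sd(v) else 0
  summ <- list(n_replicates = nrow(per_rep),
               ec50_mean = mean(per_rep$ec50), ec50_sd = sdv(per_rep$ec50),
               h_mean = mean(per_rep$h), h_sd = sdv(per_rep$h),
               a_mean = mean(per_rep$a), b_mean = mean(per_rep$b))
  params <- c(a = summ$a_mean, b = summ$b_mean, ec50 = summ$ec50_mean,
              h = summ$h_mean)
  structure(list(per_replicate = per_rep, summary = summ, params = params),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<dose_response_fit> n=%d replicates\n",
                     "  EC50 = %.3g +/- %.2g M   h = %.3g +/- %.2g\n",
                     "  a = %.4g   b = %.4g\n"),
              s$n_replicates, s$ec50_mean, s$ec50_sd, s$h_mean, s$h_sd,
              s$a_mean, s$b_mean))
  invisible(x)
}

#' Estimate an unknown stock titer from a dilution series
#'
#' Each well's fluorescence is inverted through the fitted curve to an
#' assay concentration; multiplying by the well's dilution factor gives a
#' per-well stock estimate, and usable wells are pooled by geometric mean
#' (concentrations being log-scale quantities). Wells within a margin `m`
#' of the curve limits are flagged instead of inverted: `saturated_high`
#' if `GFP >= a - m (a - b)` (the "fully activated" situation) and
#' `below_range` if `GFP <= b + m (a - b)`.
#'
#' @param plate Data frame with columns `dilution_factor` (>= 1) and
#'   `fluorescence`.
#' @param curve A `dose_response_fit`, or named Hill parameters.
#' @param margin Dynamic-range margin `m` (default 0.05).
#' @return Object of class `titer_estimate`: `wells` (per-well table with
#'   estimated assay and stock concentrations and flags), `stock_molar`
#'   (pooled geometric mean), `stock_gsd` (geometric sd across usable
#'   wells), `n_usable`.
#' @export
estimate_titer <- function(plate, curve, margin = 0.05) {
  require_columns(plate, c("dilution_factor", "fluorescence"), "plate table")
  if (any(plate$dilution_factor < 1))
    stop("dilution factors must be >= 1")
  p <- if (inherits(curve, "dose_response_fit")) curve$params else curve
  p <- hill_params(p)
  rng <- p[["a"]] - p[["b"]]
  lo <- p[["b"]] + margin * rng
  hi <- p[["a"]] - margin * rng
  y <- plate$fluorescence
  flag <- ifelse(y >= hi, "saturated_high",
                 ifelse(y <= lo, "below_range", "ok"))
  conc <- rep(NA_real_, length(y))
  conc[flag == "ok"] <- hill_inverse(p, y[flag == "ok"])
  stock <- conc * plate$dilution_factor
  usable <- which(flag == "ok")
  if (length(usable) == 0)
    stop(sprintf(paste0("no wells inside the dynamic range; flags: %s ",
                        "(all wells saturated or below range)"),
                 paste(sprintf("%s=%d", names(table(flag)), table(flag)),
                       collapse = ", ")))
  lstock <- log(stock[usable])
  structure(list(
    wells = cbind(plate,
                  data.frame(assay_conc_molar = conc, stock_molar = stock,
                             flag = flag)),
    stock_molar = exp(mean(lstock)),
    stock_gsd = if (length(lstock) > 1) exp(stats::sd(lstock)) else 1,
    n_usable = length(usable)), class = "titer_estimate")
}

#' @export
print.titer_estimate <- function(x, ...) {
  cat(sprintf(paste0("<titer_estimate> stock = %.4g M (geometric sd %.3g) ",
                     "from %d usable well(s)\n"),
              x$stock_molar, x$stock_gsd, x$n_usable))
  invisible(x)
}

#' Convert a sample concentration to yield per microlitre inner solution
#'
#' A sample of `sample_ul` microlitres at `conc_nM` nanomolar contains
#' `conc_nM * sample_ul` femtomoles, i.e. `conc_nM * sample_ul / 1000`
#' picomoles; dividing by the encapsulated inner-solution volume gives the
#' biosynthetic yield in pmol per microlitre of inner solution. With equal
#' sample and reference volumes, 1 uM corresponds to 1 pmol/ul.
#'
#' @param conc_nM Sample concentration, nanomolar (>= 0).
#' @param sample_ul Sample volume, ul (> 0).
#' @param inner_ul Inner-solution volume, ul (> 0).
#' @return Yield in pmol per ul inner solution.
#' @export
yield_per_inner_solution <- function(conc_nM, sample_ul, inner_ul) {
  if (any(conc_nM < 0)) stop("`conc_nM` must be >= 0")
  if (sample_ul <= 0 || inner_ul <= 0) stop("volumes must be > 0")
  conc_nM * 1e-3 * sample_ul / inner_ul
}

#' Geometric serial-dilution concentration series
#'
#' @param top Highest concentration, molar.
#' @param bottom Lowest concentration, molar.
#' @param step Dilution step between adjacent concentrations (> 1).
#' @return Decreasing vector of concentrations from `top` down to the last
#'   value >= `bottom` (within rounding).
#' @export
dilution_series <- function(top = 63.2e-6, bottom = 632e-12, step = 10) {
  if (top <= 0 || bottom <= 0 || top <= bottom) stop("require top > bottom > 0")
  if (step <= 1) stop("`step` must be > 1")
  n <- floor(log(top / bottom) / log(step) + 1e-9) + 1
  top / step^(seq_len(n) - 1)
}
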