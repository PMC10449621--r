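# Population-level statistics: the negative-control expressing threshold
# (control mean + 3 sd), expressing-fraction classification, summary
# order statistics, and fold-activation arithmetic.

#' Expression threshold from a negative-control population
#'
#' Computes the classification threshold as the mean background-corrected
#' reporter intensity of no-DNA control vesicles plus three sample
#' standard deviations (n - 1 denominator). Corrected intensities may be
#' slightly negative through noise; the formula is unchanged.
#'
#' @param control_records Vesicle records of the negative-control
#'   population (requires `mean_gfp_corr`; flagged records are excluded).
#' @return List of class `control_threshold`: `control_mean`,
#'   `control_sd`, `threshold`, `n_control`.
#' @export
control_threshold <- function(control_records) {
  require_columns(control_records, "mean_gfp_corr", "control records")
  if ("flagged" %in% names(control_records))
    control_records <- control_records[!control_records$flagged, , drop = FALSE]
  x <- control_records$mean_gfp_corr
  if (length(x) < 2)
    stop("need at least 2 control records to estimate a threshold")
  m <- mean(x); s <- stats::sd(x)
  structure(list(control_mean = m, control_sd = s, threshold = m + 3 * s,
                 n_control = length(x)),
            class = "control_threshold")
}

#' @export
print.control_threshold <- function(x, ...) {
  cat(sprintf(paste0("<control_threshold> mean=%.4g sd=%.4g ",
                     "threshold=%.4g (n=%d)\n"),
              x$control_mean, x$control_sd, x$threshold, x$n_control))
  invisible(x)
}

#' Classify expressing vesicles and estimate the expressing fraction
#'
#' A vesicle is expressing iff its background-corrected reporter mean is
#' strictly greater than the control threshold; records exactly at the
#' threshold are not expressing, so a degenerate all-control population
#' yields fraction 0.
#'
#' @param records Vesicle records (requires `mean_gfp_corr`).
#' @param thr A `control_threshold` (or a single numeric threshold).
#' @return List: `fraction`, `n`, and logical `expressing` per unflagged
#'   record (in record order).
#' @export
expressing_fraction <- function(records, thr) {
  require_columns(records, "mean_gfp_corr", "records")
  if ("flagged" %in% names(records))
    records <- records[!records$flagged, , drop = FALSE]
  if (nrow(records) == 0) stop("no records to classify")
  t0 <- if (inherits(thr, "control_threshold")) thr$threshold else thr
  expressing <- records$mean_gfp_corr > t0
  list(fraction = mean(expressing), n = nrow(records),
       expressing = expressing)
}

#' Summarize a vesicle population
#'
#' Diameter mean/sd/median/IQR and per-channel intensity median/IQR, using
#' the linear-interpolation (type 7) quantile convention. Flagged records
#' are excluded. Invariant under record order.
#'
#' @param records Vesicle records.
#' @return List of class `population_summary`.
#' @export
summarize_population <- function(records) {
  require_columns(records, c("diameter_um", "mean_txr_corr", "mean_gfp_corr"),
                  "records")
  if ("flagged" %in% names(records))
    records <- records[!records$flagged, , drop = FALSE]
  if (nrow(records) == 0) stop("no records to summarize")
  iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE,
                                          type = 7))
  out <- list(
    n = nrow(records),
    diameter_mean_um = mean(records$diameter_um),
    diameter_sd_um = if (nrow(records) > 1) stats::sd(records$diameter_um)
      else 0,
    diameter_median_um = stats::median(records$diameter_um),
    diameter_iqr_um = iqr(records$diameter_um),
    txr_median = stats::median(records$mean_txr_corr),
    txr_iqr = iqr(records$mean_txr_corr),
    gfp_median = stats::median(records$mean_gfp_corr),
    gfp_iqr = iqr(records$mean_gfp_corr))
  if ("expressing" %in% names(records))
    out$expressing_fraction <- mean(records$expressing)
  structure(out, class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(paste0("<population_summary> n=%d  diameter %.2f +/- %.2f um ",
                     "(median %.2f)  GFP median %.3g\n"),
              x$n, x$diameter_mean_um, x$diameter_sd_um,
              x$diameter_median_um, x$gfp_median))
  if (!is.null(x$expressing_fraction))
    cat(sprintf("  expressing fraction = %.3f\n", x$expressing_fraction))
  invisible(x)
}

#' Fold activation (dynamic range) of a reporter
#'
#' @param on_level Reporter output in the ON state.
#' @param off_level Reporter output in the OFF state (> 0).
#' @return `on_level / off_level`.
#' @export
fold_activation <- function(on_level, off_level) {
  if (any(off_level <= 0)) stop("`off_level` must be > 0; ratio undefined")
  on_level / off_level
}

#' Compose a variant's fold activation from a reference and change factors
#'
#' A variant whose OFF state tightens by `off_change` and whose ON state
#' grows by `on_change` relative to a reference with dynamic range
#' `fold_ref` has dynamic range `fold_ref * off_change * on_change`.
#' The factors commute; `decompose_fold(f, 1, 1) == f`.
#'
#' @param fold_ref Reference fold activation (> 0).
#' @param off_change Factor by which the OFF state decreased (> 0).
#' @param on_change Factor by which the ON state increased (> 0).
#' @return The variant's fold activation.
#' @export
decompose_fold <- function(fold_ref, off_change, on_change) {
  if (any(c(fold_ref, off_change, on_change) <= 0))
    stop("all factors must be > 0")
  fold_ref * off_change * on_change
}
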