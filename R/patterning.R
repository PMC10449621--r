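# Photomask patterning analysis: decompose a binary mask into connected
# features with inscribed-disk widths, and score how faithfully an
# expression map follows the mask (contrast, fidelity, resolved features).

#' Decompose a binary mask into connected features
#'
#' Features are 4-connected components of the mask foreground. Each
#' feature's width is defined as twice its maximum Euclidean
#' distance-transform value (the largest inscribed disk), converted to
#' micrometres; a 1-px-wide line therefore has width 2 px-equivalents, and
#' an even-sided filled square of side s has width exactly s.
#'
#' @param mask Binary matrix (0/1).
#' @param pixel_size_um Grid pixel size, um.
#' @return Data frame: `feature, area_px, area_um2, width_um`.
#' @export
feature_decompose <- function(mask, pixel_size_um = 1) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("`mask` must be a binary (0/1) matrix")
  if (!any(mask == 1))
    return(data.frame(feature = integer(), area_px = integer(),
                      area_um2 = numeric(), width_um = numeric()))
  lab <- EBImage::bwlabel(mask)
  dm <- EBImage::distmap(mask)
  labs <- sort(unique(lab[lab > 0]))
  out <- lapply(labs, function(l) {
    sel <- lab == l
    data.frame(feature = as.integer(l), area_px = sum(sel),
               area_um2 = sum(sel) * pixel_size_um^2,
               width_um = 2 * max(dm[sel]) * pixel_size_um)
  })
  do.call(rbind, out)
}

#' Score an expression pattern against a photomask
#'
#' Vesicle membership is decided by the mask value at the (rounded)
#' vesicle center, consistent with the simulator's activation rule.
#' The score reports: `contrast`, the ratio of mean background-corrected
#' reporter intensity of vesicles inside the mask to those outside
#' (flagged `NA` when no outside population exists); `fidelity`, the
#' fraction of expressing vesicles whose centers lie inside the mask; and
#' per-feature resolution, where a feature is resolved iff it contains at
#' least `k` expressing vesicles and its local contrast (mean reporter
#' intensity of its vesicles over the outside-mask mean) is at least
#' `c_min`. `min_resolved_width_um` is the smallest width among resolved
#' features.
#'
#' @param records Vesicle records with `row`, `col`, `mean_gfp_corr` and a
#'   logical `expressing` column (e.g. from [expressing_fraction()]).
#' @param mask Binary matrix registered to the image grid.
#' @param pixel_size_um Grid pixel size, um.
#' @param k Minimum expressing-vesicle count per resolved feature.
#' @param c_min Minimum local contrast per resolved feature.
#' @return Object of class `pattern_score`: `contrast`,
#'   `contrast_flag`, `fidelity`, `features` (decomposition with
#'   `n_expressing`, `local_contrast`, `resolved`),
#'   `min_resolved_width_um`.
#' @export
score_pattern <- function(records, mask, pixel_size_um, k = 3, c_min = 2) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("`mask` must be a binary (0/1) matrix")
  if (!any(mask == 1)) stop("empty mask")
  require_columns(records, c("row", "col", "mean_gfp_corr", "expressing"),
                  "records")
  if ("flagged" %in% names(records))
    records <- records[!records$flagged, , drop = FALSE]
  if (nrow(records) == 0) stop("no records to score")

  idx <- cbind(pmin(pmax(round(records$row), 1L), nrow(mask)),
               pmin(pmax(round(records$col), 1L), ncol(mask)))
  inside <- mask[idx] > 0

  out_mean <- if (any(!inside)) mean(records$mean_gfp_corr[!inside]) else NA
  in_mean <- if (any(inside)) mean(records$mean_gfp_corr[inside]) else NA
  contrast_flag <- if (!any(!inside)) "no_outside_population" else
    if (!any(inside)) "no_inside_population" else "ok"
  contrast <- if (contrast_flag == "ok" && out_mean > 0)
    in_mean / out_mean else NA_real_

  n_expr <- sum(records$expressing)
  fidelity <- if (n_expr > 0) sum(records$expressing & inside) / n_expr
    else NA_real_

  feats <- feature_decompose(mask, pixel_size_um)
  lab <- EBImage::bwlabel(mask)
  rec_lab <- lab[idx]
  feats$n_expressing <- vapply(feats$feature, function(l)
    sum(records$expressing & rec_lab == l), numeric(1))
  feats$local_contrast <- vapply(feats$feature, function(l) {
    v <- records$mean_gfp_corr[rec_lab == l]
    if (length(v) == 0 || is.na(out_mean) || out_mean <= 0) return(NA_real_)
    mean(v) / out_mean
  }, numeric(1))
  feats$resolved <- feats$n_expressing >= k &
    !is.na(feats$local_contrast) & feats$local_contrast >= c_min
  min_w <- if (any(feats$resolved)) min(feats$width_um[feats$resolved])
    else NA_real_

  structure(list(contrast = contrast, contrast_flag = contrast_flag,
                 fidelity = fidelity, features = feats,
                 min_resolved_width_um = min_w,
                 k = k, c_min = c_min),
            class = "pattern_score")
}

#' @export
print.pattern_score <- function(x, ...) {
  cat(sprintf(paste0("<pattern_score> fidelity=%.3f contrast=%.3g (%s)\n",
                     "  %d feature(s), %d resolved; min resolved width ",
                     "= %.3g um (rule: >=%d expressing, contrast >= %g)\n"),
              x$fidelity, x$contrast, x$contrast_flag,
              nrow(x$features), sum(x$features$resolved),
              x$min_resolved_width_um, x$k, x$c_min))
  invisible(x)
}
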