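# Per-vesicle measurement: diameter in physical units and raw /
# background-corrected mean intensity per channel over a circular ROI.

#' Measure one detected vesicle
#'
#' The ROI is the set of pixels whose centers lie within the detected
#' circle (no partial weighting, mirroring a manual circular-ROI
#' measurement). Mean intensity is taken over the ROI in each channel;
#' corrected values subtract the per-channel scalar background and are
#' deliberately not clipped, so noise can push them slightly negative.
#' ROIs of fewer than 5 pixels are flagged (and later excluded from
#' population statistics) rather than dropped, keeping counts auditable.
#'
#' @param images `image_set` holding TXR and GFP channels on a shared grid.
#' @param det One-row detection (fields `row`, `col`, `radius_px`).
#' @param bg Named numeric background scalars, `c(TXR=, GFP=)`.
#' @return One-row data frame: `row, col, radius_px, diameter_um,
#'   mean_txr_raw, mean_gfp_raw, mean_txr_corr, mean_gfp_corr, roi_px,
#'   flagged`.
#' @export
measure_vesicle <- function(images, det, bg) {
  txr <- get_channel(images, "TXR")
  gfp <- get_channel(images, "GFP")
  if (!identical(dim(txr$pixels), dim(gfp$pixels)))
    stop("TXR and GFP channels must share one grid")
  nr <- nrow(txr$pixels); nc <- ncol(txr$pixels)
  if (det$row < 1 || det$row > nr || det$col < 1 || det$col > nc)
    stop("detection center outside image bounds")
  if (!all(c("TXR", "GFP") %in% names(bg)))
    stop("`bg` must be named c(TXR=, GFP=)")
  r <- det$radius_px
  r0 <- max(1, floor(det$row - r)); r1 <- min(nr, ceiling(det$row + r))
  c0 <- max(1, floor(det$col - r)); c1 <- min(nc, ceiling(det$col + r))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - det$row)^2, (cc - det$col)^2, "+")
  roi <- d2 <= r^2
  n_roi <- sum(roi)
  mt <- if (n_roi > 0) mean(txr$pixels[rr, cc][roi]) else NA_real_
  mg <- if (n_roi > 0) mean(gfp$pixels[rr, cc][roi]) else NA_real_
  data.frame(row = det$row, col = det$col, radius_px = r,
             diameter_um = 2 * r * txr$pixel_size_um,
             mean_txr_raw = mt, mean_gfp_raw = mg,
             mean_txr_corr = mt - bg[["TXR"]],
             mean_gfp_corr = mg - bg[["GFP"]],
             roi_px = n_roi, flagged = n_roi < 5)
}

#' Measure every detection in an image set
#'
#' Batch wrapper around [measure_vesicle()] with stable ordering and
#' sequential record ids; pathological (tiny-ROI) records are flagged, not
#' dropped.
#'
#' @param images `image_set` with TXR and GFP channels.
#' @param detections Detection table from [detect_vesicles()] (or a truth
#'   table recast as detections).
#' @param bg Named numeric background scalars, `c(TXR=, GFP=)`.
#' @param image_id Identifier copied into every record.
#' @param condition_label Condition label copied into every record.
#' @return Data frame of `VesicleRecord` rows: `id, image_id,
#'   condition_label` plus the [measure_vesicle()] fields.
#' @export
quantify_image_set <- function(images, detections, bg, image_id = "img1",
                               condition_label = NA_character_) {
  if (nrow(detections) == 0) {
    out <- cbind(data.frame(id = integer(), image_id = character(),
                            condition_label = character()),
                 measure_vesicle(images,
                                 data.frame(row = 1, col = 1, radius_px = 1),
                                 bg)[0, ])
    return(out)
  }
  rows <- lapply(seq_len(nrow(detections)), function(i)
    measure_vesicle(images, detections[i, ], bg))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(id = seq_len(nrow(out)),
                          image_id = image_id,
                          condition_label = condition_label), out)
  rownames(out) <- NULL
  out
}

#' Recast a ground-truth table as a detection table
#'
#' Useful for isolating measurement behavior from detection behavior in
#' benchmarks: feeds the simulator's exact circles to the quantifier.
#'
#' @param truth Truth table from [simulate_field()].
#' @param pixel_size_um Pixel size, um.
#' @return Detection data frame (`row, col, radius_px, score`).
#' @export
truth_as_detections <- function(truth, pixel_size_um) {
  data.frame(row = truth$row, col = truth$col,
             radius_px = truth$diameter_um / 2 / pixel_size_um,
             score = rep(1, nrow(truth)))
}
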