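# Vesicle detection on the reference dye (TXR) channel: per-experiment
# brightness normalization, scalar background estimation from vesicle-free
# regions, and a gradient-voting circular Hough detector for filled disks.

#' Normalize channel brightness across an experiment
#'
#' Applies one common linear map per (experiment, channel): the pooled 1st
#' percentile of all pixels maps to 0 and the pooled 99.9th percentile to 1
#' (robust to hot pixels). Because a single affine map is shared by every
#' image in the group, relative intensities across images are preserved,
#' and the map is idempotent (re-running on its own output is the
#' identity). Values are not clipped, so intensity linearity is retained.
#'
#' @param images An `image_set`; all images sharing `experiment_id` and
#'   `channel` are normalized together.
#' @param lo_q,hi_q Quantiles anchoring the map (defaults 0.01, 0.999).
#' @return List with `images` (normalized `image_set`) and `model` (data
#'   frame: `experiment_id, channel, low_anchor, high_anchor`).
#' @export
normalize_experiment <- function(images, lo_q = 0.01, hi_q = 0.999) {
  if (!inherits(images, "image_set") || length(images) == 0)
    stop("`images` must be a non-empty image_set")
  keys <- vapply(images, function(im) paste(im$experiment_id, im$channel,
                                            sep = "\r"), character(1))
  model <- list()
  out <- unclass(images)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    pooled <- unlist(lapply(out[idx], function(im) as.vector(im$pixels)))
    anchors <- stats::quantile(pooled, c(lo_q, hi_q), names = FALSE)
    if (anchors[2] <= anchors[1])
      stop(sprintf(paste0("channel %s of experiment %s has a degenerate ",
                          "intensity range (high anchor <= low anchor); ",
                          "cannot normalize a constant-valued channel"),
                   out[[idx[1]]]$channel, out[[idx[1]]]$experiment_id))
    # values below the low anchor map to small negatives; they are kept
    # (not clipped) so the shared map stays affine and idempotent
    for (i in idx)
      out[[i]]$pixels <- (out[[i]]$pixels - anchors[1]) /
        (anchors[2] - anchors[1])
    model[[length(model) + 1L]] <- data.frame(
      experiment_id = out[[idx[1]]]$experiment_id,
      channel = out[[idx[1]]]$channel,
      low_anchor = anchors[1], high_anchor = anchors[2])
  }
  list(images = structure(out, class = "image_set"),
       model = do.call(rbind, model))
}

#' Estimate a scalar channel background from a vesicle-free region
#'
#' The background is the arithmetic mean pixel intensity over the selected
#' region, mirroring the practice of measuring manually selected
#' vesicle-free areas of the field.
#'
#' @param image A `channel_image`.
#' @param rows,cols Integer vectors defining a rectangular region
#'   (`rows` x `cols`), or `region` a logical matrix.
#' @param region Optional logical matrix selecting pixels directly.
#' @param detections Optional detection table; if any detection center
#'   falls inside the region a warning (not an error) is raised, since
#'   region selection is a judgement call.
#' @return List of class `background_model`: `channel`, `value`, `n_pixels`.
#' @export
estimate_background <- function(image, rows = NULL, cols = NULL,
                                region = NULL, detections = NULL) {
  px <- image$pixels
  if (is.null(region)) {
    if (is.null(rows) || is.null(cols) || length(rows) == 0 ||
        length(cols) == 0)
      stop("empty background region")
    if (min(rows) < 1 || max(rows) > nrow(px) ||
        min(cols) < 1 || max(cols) > ncol(px))
      stop("background region out of image bounds")
    vals <- px[rows, cols]
    inside <- function(r, c) r >= min(rows) & r <= max(rows) &
      c >= min(cols) & c <= max(cols)
  } else {
    if (!identical(dim(region), dim(px)))
      stop("`region` must match the image grid")
    if (!any(region)) stop("empty background region")
    vals <- px[region]
    inside <- function(r, c) region[cbind(pmax(1, round(r)),
                                          pmax(1, round(c)))]
  }
  if (!is.null(detections) && nrow(detections) > 0 &&
      any(inside(detections$row, detections$col)))
    warning("background region overlaps detected vesicles")
  structure(list(channel = image$channel, value = mean(vals),
                 n_pixels = length(vals)), class = "background_model")
}

# zero-padded integer shift of a matrix
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

box3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out + shift_mat(m, dr, dc)
  out
}

#' Detect circular vesicles by gradient-voting circular Hough transform
#'
#' The image is lightly smoothed, gradient magnitude and direction are
#' computed by central differences, and every edge pixel (gradient
#' magnitude above a robust noise threshold) casts one vote per candidate
#' radius at the point one radius along its gradient direction (for bright
#' filled disks the gradient points from the dark surround toward the
#' lumen). Accumulator layers are scanned per radius (step 1 px); peaks
#' above `sensitivity` (score = 3x3-pooled votes / circumference) become
#' candidate circles, refined to sub-pixel centers by the centroid of the
#' accumulator peak's 3x3 neighborhood and to sub-grid radii by a
#' score-weighted mean over adjacent radius layers. Candidates are then
#' screened by an interior-contrast check (a filled disk must be brighter
#' inside than in its surrounding annulus) and overlap-suppressed: of any
#' pair with center distance < 0.8 x (r1 + r2), only the higher-scoring
#' detection is kept. Output is sorted by score, descending; the whole
#' procedure is deterministic for a fixed input.
#'
#' @param image A (typically normalized) TXR `channel_image`.
#' @param radius_range_um Search range for the vesicle radius, um. The
#'   default 0.75-12.5 um covers 1.5-25 um diameters, bracketing the
#'   3-20 um GUV population with margin.
#' @param sensitivity Minimum accumulator score (votes per circumference
#'   unit) for a candidate peak.
#' @param sigma_px Gaussian pre-smoothing sd, px.
#' @param min_contrast Required ratio of mean interior intensity to mean
#'   annulus intensity, relative to the image's background floor; set to
#'   `NULL` to disable the screen.
#' @return Data frame of class `vesicle_detections`: `row, col, radius_px,
#'   score`, sorted by score descending.
#' @export
detect_vesicles <- function(image, radius_range_um = c(0.75, 12.5),
                            sensitivity = 0.5, sigma_px = 1,
                            min_contrast = 1.15) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  psz <- image$pixel_size_um
  if (any(radius_range_um <= 0) || diff(radius_range_um) <= 0)
    stop("`radius_range_um` must be positive and increasing")
  rmin <- radius_range_um[1] / psz
  rmax <- radius_range_um[2] / psz
  if (rmax > min(nr, nc) / 2)
    stop("radius range out of bounds: image is smaller than twice the maximum search radius")

  empty <- data.frame(row = numeric(), col = numeric(),
                      radius_px = numeric(), score = numeric())
  class(empty) <- c("vesicle_detections", "data.frame")

  sm <- EBImage::imageData(EBImage::gblur(px, sigma = sigma_px))
  gr <- (shift_mat(sm, -1, 0) - shift_mat(sm, 1, 0)) / 2  # d/drow
  gc <- (shift_mat(sm, 0, -1) - shift_mat(sm, 0, 1)) / 2  # d/dcol
  gr[c(1, nr), ] <- 0; gr[, c(1, nc)] <- 0
  gc[c(1, nr), ] <- 0; gc[, c(1, nc)] <- 0
  mag <- sqrt(gr^2 + gc^2)
  # robust noise-driven threshold, floored at 2% of the robust intensity
  # range so noise-free images do not admit faint anti-aliasing gradients
  rng <- diff(stats::quantile(sm, c(0.01, 0.999), names = FALSE))
  thr <- max(stats::median(mag) + 6 * stats::mad(mag), 0.02 * rng)
  edge <- which(mag > thr)
  if (length(edge) == 0) return(empty)
  er <- ((edge - 1) %% nr) + 1
  ec <- ((edge - 1) %/% nr) + 1
  ur <- gr[edge] / mag[edge]
  uc <- gc[edge] / mag[edge]

  radii <- seq(max(2, floor(rmin)), max(2, ceiling(rmax)), by = 1)
  layers <- vector("list", length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    vr <- round(er + r * ur)
    vc <- round(ec + r * uc)
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    acc <- matrix(tabulate(vr[ok] + (vc[ok] - 1L) * nr, nbins = nr * nc),
                  nr, nc)
    layers[[k]] <- box3(acc) / (2 * pi * r)
  }

  peaks <- list()
  for (k in seq_along(radii)) {
    m <- layers[[k]]
    cand <- which(m >= sensitivity)
    if (length(cand) == 0) next
    pr <- ((cand - 1) %% nr) + 1
    pc <- ((cand - 1) %/% nr) + 1
    inb <- pr > 1 & pr < nr & pc > 1 & pc < nc
    cand <- cand[inb]; pr <- pr[inb]; pc <- pc[inb]
    if (length(cand) == 0) next
    ismax <- rep(TRUE, length(cand))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ismax <- ismax & m[cand] >= m[cbind(pr + dr, pc + dc)]
    }
    cand <- cand[ismax]; pr <- pr[ismax]; pc <- pc[ismax]
    if (length(cand) == 0) next
    for (i in seq_along(cand)) {
      rr <- (pr[i] - 1):(pr[i] + 1)
      cc <- (pc[i] - 1):(pc[i] + 1)
      w <- m[rr, cc]
      sw <- sum(w)
      cr <- sum(outer(rr, rep(1, 3)) * w) / sw
      ccol <- sum(outer(rep(1, 3), cc) * w) / sw
      peaks[[length(peaks) + 1L]] <- c(cr, ccol, radii[k], m[pr[i], pc[i]])
    }
  }
  if (length(peaks) == 0) return(empty)
  det <- do.call(rbind, peaks)
  det <- data.frame(row = det[, 1], col = det[, 2], radius_px = det[, 3],
                    score = det[, 4])
  det <- det[order(-det$score), , drop = FALSE]

  # interior-contrast screen: a filled disk is brighter inside its circle
  # than in the surrounding annulus (both measured above the image floor)
  if (!is.null(min_contrast)) {
    floor_val <- stats::quantile(px, 0.05, names = FALSE)
    keep <- vapply(seq_len(nrow(det)), function(i) {
      r <- det$radius_px[i]
      r0 <- max(1, floor(det$row[i] - 1.6 * r))
      r1 <- min(nr, ceiling(det$row[i] + 1.6 * r))
      c0 <- max(1, floor(det$col[i] - 1.6 * r))
      c1 <- min(nc, ceiling(det$col[i] + 1.6 * r))
      rr <- r0:r1; cc <- c0:c1
      d <- sqrt(outer((rr - det$row[i])^2, (cc - det$col[i])^2, "+"))
      inside <- px[rr, cc][d <= 0.7 * r]
      ann <- px[rr, cc][d > 1.2 * r & d <= 1.6 * r]
      if (length(inside) == 0 || length(ann) == 0) return(TRUE)
      (mean(inside) - floor_val) >=
        min_contrast * max(mean(ann) - floor_val, 1e-12)
    }, logical(1))
    det <- det[keep, , drop = FALSE]
  }

  # sub-grid radius refinement: the azimuthally averaged radial intensity
  # profile of a filled disk crosses the midpoint between lumen and
  # surround exactly at the true radius under symmetric blur, so the
  # half-height crossing is an unbiased radius estimator
  det$radius_px <- vapply(seq_len(nrow(det)), function(i) {
    # two passes: the first recovers from a coarse accumulator radius,
    # the second polishes with a well-centred profile window
    r1 <- refine_radius(px, det$row[i], det$col[i], det$radius_px[i])
    refine_radius(px, det$row[i], det$col[i], r1)
  }, numeric(1))
  det <- det[det$radius_px >= rmin & det$radius_px <= rmax, , drop = FALSE]

  # overlap suppression: drop the lower-scoring of any pair with center
  # distance < 0.8 x (r1 + r2); additionally drop any detection whose
  # center lies inside a kept detection's circle (rim artifacts of large
  # disks masquerade as small circles there, while true neighbouring
  # vesicles keep their centers mutually outside one another)
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- which(keep)
    d <- sqrt((det$row[kept] - det$row[i])^2 + (det$col[kept] - det$col[i])^2)
    keep[i] <- all(d >= 0.8 * (det$radius_px[kept] + det$radius_px[i])) &&
      all(d >= det$radius_px[kept])
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  class(det) <- c("vesicle_detections", "data.frame")
  det
}

# half-height radial profile radius refinement around (row0, col0)
refine_radius <- function(px, row0, col0, r0) {
  nr <- nrow(px); nc <- ncol(px)
  ext <- ceiling(2.6 * r0 + 2)
  rr <- max(1, floor(row0 - ext)):min(nr, ceiling(row0 + ext))
  cc <- max(1, floor(col0 - ext)):min(nc, ceiling(col0 + ext))
  d <- sqrt(outer((rr - row0)^2, (cc - col0)^2, "+"))
  v <- px[rr, cc]
  lumen <- v[d <= 0.5 * r0]
  ann <- v[d >= 2 * r0 & d <= 2.6 * r0]
  if (length(lumen) == 0 || length(ann) == 0) return(r0)
  # median surround is robust to intruding neighbours
  level <- (mean(lumen) + stats::median(ann)) / 2
  bins <- seq(0.4 * r0, 2 * r0, by = 0.25)
  prof <- vapply(seq_len(length(bins) - 1), function(j)
    mean(v[d >= bins[j] & d < bins[j + 1]]), numeric(1))
  mid <- (bins[-length(bins)] + bins[-1]) / 2
  ok <- !is.na(prof)
  prof <- prof[ok]; mid <- mid[ok]
  below <- which(prof < level)
  if (length(below) == 0 || below[1] == 1) return(r0)
  j <- below[1]
  mid[j - 1] + (prof[j - 1] - level) / (prof[j - 1] - prof[j]) *
    (mid[j] - mid[j - 1])
}

#' Match detections to ground truth and score recall/precision
#'
#' Evaluation convention: a detection matches a true vesicle when their
#' centers are within `center_tol_px` and the radii agree within
#' `radius_tol_frac` (relative). Matching is greedy in score order, one
#' truth per detection.
#'
#' @param detections Output of [detect_vesicles()].
#' @param truth Ground-truth table from [simulate_field()].
#' @param pixel_size_um Pixel size used to convert truth diameters to px.
#' @param center_tol_px Center distance tolerance, px.
#' @param radius_tol_frac Relative radius tolerance.
#' @return List: `recall`, `precision`, `n_matched`, and `matches` (data
#'   frame with per-match center and diameter errors in px).
#' @export
match_detections <- function(detections, truth, pixel_size_um,
                             center_tol_px = 2, radius_tol_frac = 0.15) {
  tr_r <- truth$diameter_um / 2 / pixel_size_um
  used <- rep(FALSE, nrow(truth))
  rows <- list()
  for (i in seq_len(nrow(detections))) {
    d <- sqrt((truth$row - detections$row[i])^2 +
                (truth$col - detections$col[i])^2)
    ok <- !used & d <= center_tol_px &
      abs(detections$radius_px[i] - tr_r) <= radius_tol_frac * tr_r
    if (!any(ok)) next
    j <- which(ok)[which.min(d[ok])]
    used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      detection = i, truth_id = truth$id[j], center_err_px = d[j],
      diameter_err_px = 2 * (detections$radius_px[i] - tr_r[j]))
  }
  matches <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(detection = integer(), truth_id = integer(),
               center_err_px = numeric(), diameter_err_px = numeric())
  list(recall = if (nrow(truth) > 0) nrow(matches) / nrow(truth) else NA_real_,
       precision = if (nrow(detections) > 0)
         nrow(matches) / nrow(detections) else NA_real_,
       n_matched = nrow(matches), matches = matches)
}
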