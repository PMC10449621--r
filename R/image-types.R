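#' Construct a single-channel microscopy image
#'
#' A `channel_image` is the basic raster unit of the package: one 2-D pixel
#' matrix carrying its channel role (the reference dye channel `"TXR"`, the
#' reporter channel `"GFP"`, or brightfield `"BF"`), the physical pixel size
#' and experiment/condition labels used for grouping during normalization.
#'
#' @param pixels Numeric matrix of non-negative, finite pixel intensities
#'   (rows x cols).
#' @param channel Channel role, one of `"TXR"`, `"GFP"`, `"BF"`.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param experiment_id Experiment grouping label; images sharing an
#'   `experiment_id` are normalized with a common map.
#' @param condition_label Free-text condition label (e.g. `"+UV"`).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("TXR", "GFP", "BF"),
                          pixel_size_um, experiment_id = "exp1",
                          condition_label = NA_character_) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite")
  if (any(pixels < 0))
    stop("`pixels` must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size_um = as.numeric(pixel_size_um),
         experiment_id = as.character(experiment_id),
         condition_label = as.character(condition_label)),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px  %.3g um/px  experiment=%s\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, x$experiment_id))
  invisible(x)
}

#' Bundle channel images into an image set
#'
#' @param ... `channel_image` objects.
#' @return An object of class `image_set` (a list of `channel_image`s).
#' @export
image_set <- function(...) {
  imgs <- list(...)
  if (length(imgs) == 1 && is.list(imgs[[1]]) &&
      !inherits(imgs[[1]], "channel_image"))
    imgs <- imgs[[1]]
  ok <- vapply(imgs, inherits, logical(1), what = "channel_image")
  if (length(imgs) == 0 || !all(ok))
    stop("`image_set()` takes one or more channel_image objects")
  structure(imgs, class = "image_set")
}

#' Extract one channel from an image set
#'
#' @param images An `image_set`.
#' @param channel Channel role to extract.
#' @return The matching `channel_image`; errors if absent or ambiguous.
#' @export
get_channel <- function(images, channel) {
  hits <- Filter(function(im) im$channel == channel, unclass(images))
  if (length(hits) == 0)
    stop(sprintf("no %s channel in image set", channel))
  if (length(hits) > 1)
    stop(sprintf("multiple %s channels in image set; extract by index", channel))
  hits[[1]]
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d channel image(s): %s\n", length(x),
              paste(vapply(x, function(im) im$channel, character(1)),
                    collapse = ", ")))
  invisible(x)
}
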