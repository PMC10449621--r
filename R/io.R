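# File contracts: 16-bit TIFF rasters, PNG binary masks, tidy CSV tables.
# Rasters are real-valued in memory (gray units) and quantized to 16 bit on
# disk against a fixed full scale, so writes are bit-reproducible.

.TIFF_FULL_SCALE <- 65535

#' Write a channel image as 16-bit TIFF
#'
#' Pixel values (gray units) are quantized against a fixed full scale of
#' 65535, so round-trips are deterministic and images from one experiment
#' remain mutually comparable on disk.
#'
#' @param image A `channel_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  px <- image$pixels / .TIFF_FULL_SCALE
  if (any(px > 1))
    stop("pixel values exceed the 16-bit full scale (65535 gray units)")
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit TIFF written by [write_channel_tiff()]
#'
#' @param path File path.
#' @param channel Channel role of the stored image.
#' @param pixel_size_um Physical pixel size, um.
#' @param experiment_id,condition_label Grouping labels.
#' @return A `channel_image` with values back in gray units.
#' @export
read_channel_tiff <- function(path, channel, pixel_size_um,
                              experiment_id = "exp1",
                              condition_label = NA_character_) {
  px <- tiff::readTIFF(path)
  if (is.array(px) && length(dim(px)) == 3) px <- px[, , 1]
  channel_image(px * .TIFF_FULL_SCALE, channel, pixel_size_um,
                experiment_id, condition_label)
}

#' Write / read a binary mask as PNG
#'
#' @param mask Binary matrix (0/1).
#' @param path File path.
#' @return `path` invisibly (write); binary matrix (read).
#' @export
write_mask_png <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary (0/1)")
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  m <- round(m)
  if (!all(m %in% c(0, 1))) stop("PNG at `path` is not a binary mask")
  m
}

#' Write a data frame as CSV with stable formatting
#'
#' Plain `write.csv` with `row.names = FALSE`; numeric formatting is R's
#' default 15-significant-digit rendering, so identical tables produce
#' identical bytes.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Check that a CSV-backed table carries required columns
#'
#' @param df Data frame to check.
#' @param columns Required column names.
#' @param what Label used in the error message.
#' @return `df`, invisibly; errors citing the first missing column.
#' @export
require_columns <- function(df, columns, what = "table") {
  missing <- setdiff(columns, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s is missing required column `%s`", what, missing[1]))
  invisible(df)
}
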