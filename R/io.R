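#' Read a two-channel section image from TIFF/PNG files
#'
#' Loads the laminin and MY-32 channels (TIFF, first plane of multi-page
#' files) and an optional binary mask (PNG or TIFF), scaling intensities to
#' 0--255. Requires the `tiff` (and for PNG masks, `png`) package.
#'
#' @param laminin_path,my32_path paths to single-channel TIFF files.
#' @param mask_path optional path to a mask image (PNG or TIFF); pixels
#'   above 0.5 (on the 0-1 scale) are inside the region.
#' @param microns_per_pixel pixel size (um/px).
#' @return a [section_image].
#' @export
read_section_image <- function(laminin_path, my32_path, mask_path = NULL,
                               microns_per_pixel) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read section images")
  rd <- function(path) {
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("the 'png' package is required to read PNG masks")
      x <- png::readPNG(path)
    } else {
      x <- tiff::readTIFF(path)
      if (is.list(x)) x <- x[[1]]
    }
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x
  }
  lam <- rd(laminin_path) * 255
  my <- rd(my32_path) * 255
  mask <- if (!is.null(mask_path)) rd(mask_path) > 0.5 else NULL
  section_image(lam, my, mask, microns_per_pixel)
}

#' Write a label map to TIFF
#'
#' Stores the integer label map as a 16-bit grayscale TIFF (labels scaled
#' into the unit range; divide by the stored maximum to recover ids).
#'
#' @param label_map integer matrix from [segment_fibres()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(label_map, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write label maps")
  m <- max(label_map)
  tiff::writeTIFF(matrix(as.numeric(label_map) / max(1, m),
                         nrow(label_map), ncol(label_map)),
                  path, bits.per.sample = 16)
  invisible(path)
}
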