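# Raster plumbing shared by every stage. An RGB image is a numeric
# h x w x 3 array with values in [0, 255]; a gray image is a numeric h x w
# matrix. Matrix element [row, col] is pixel (x = col - 1, y = row - 1).

#' Video/image frame
#'
#' Wrap an RGB raster together with its identity (source and temporal index),
#' the unit that flows through detection and mosaicing.
#'
#' @param pixels A numeric `h x w x 3` array, channel values in `[0, 255]`.
#' @param source_id Character scalar naming the video or directory of origin.
#' @param index Non-negative integer frame index within the source.
#' @return An object of class `frame`.
#' @export
frame <- function(pixels, source_id = "unknown", index = 0L) {
  pixels <- validate_rgb(pixels)
  stopifnot(is.character(source_id), length(source_id) == 1L,
            index >= 0, index == round(index))
  structure(list(pixels = pixels, source_id = source_id,
                 index = as.integer(index)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<frame %s #%d  %dx%d px>\n", x$source_id, x$index, d[2], d[1]))
  invisible(x)
}

validate_rgb <- function(pixels) {
  if (inherits(pixels, "frame")) pixels <- pixels$pixels
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("RGB image must be an h x w x 3 array")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) stop("empty image")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "double"
  pixels
}

# accept a frame or a bare array/matrix
as_pixels <- function(img) {
  if (inherits(img, "frame")) img$pixels else img
}

img_width <- function(img) dim(as_pixels(img))[2]
img_height <- function(img) dim(as_pixels(img))[1]

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# quantize a float raster to 8-bit, rounding half away from zero
quantize8 <- function(x) clamp255(round_half_up(x))

#' Convert an RGB raster to grayscale
#'
#' Equal-weight channel mean; sufficient for keypoint detection where
#' perceptual weighting is irrelevant.
#'
#' @param img A [frame()] or RGB array.
#' @return A numeric matrix in `[0, 255]`.
#' @export
to_gray <- function(img) {
  px <- validate_rgb(as_pixels(img))
  (px[, , 1] + px[, , 2] + px[, , 3]) / 3
}
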