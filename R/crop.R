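# Crop the detected retinal window and standardize the canvas without ever
# resampling retinal pixels: mosaicing assumes all crops share one scale.

#' Crop a detected region and pad it onto a fixed square canvas
#'
#' The box content is copied unchanged (no resampling) onto a black square
#' canvas, centered. A crop larger than the canvas in some dimension is
#' center-cropped in that dimension, with a warning — scale preservation
#' wins over completeness.
#'
#' @param img A [frame()] or RGB array.
#' @param b A [bbox()] lying within the image.
#' @param canvas_side Square canvas side in pixels (default 400).
#' @return A list of class `cropped_retina`: `pixels`
#'   (`canvas_side x canvas_side x 3`), `offset` (`c(dx, dy)` of the crop's
#'   top-left inside the canvas) and `bbox` (the source box actually used).
#' @export
crop_and_pad <- function(img, b, canvas_side = 400L) {
  px <- validate_rgb(as_pixels(img))
  stopifnot(inherits(b, "bbox"), canvas_side >= 1)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (b[["x_max"]] > w || b[["y_max"]] > h) {
    stop("bbox extends outside the image")
  }
  canvas_side <- as.integer(canvas_side)
  crop <- px[(b[["y_min"]] + 1):b[["y_max"]],
             (b[["x_min"]] + 1):b[["x_max"]], , drop = FALSE]
  ch <- dim(crop)[1]; cw <- dim(crop)[2]
  used <- b
  if (cw > canvas_side || ch > canvas_side) {
    warning(sprintf("crop %dx%d exceeds canvas %d; center-cropping",
                    cw, ch, canvas_side))
    if (cw > canvas_side) {
      x0 <- (cw - canvas_side) %/% 2L
      crop <- crop[, (x0 + 1):(x0 + canvas_side), , drop = FALSE]
    }
    if (ch > canvas_side) {
      y0 <- (ch - canvas_side) %/% 2L
      crop <- crop[(y0 + 1):(y0 + canvas_side), , , drop = FALSE]
    }
    ch <- dim(crop)[1]; cw <- dim(crop)[2]
  }
  dx <- (canvas_side - cw) %/% 2L
  dy <- (canvas_side - ch) %/% 2L
  canvas <- array(0, dim = c(canvas_side, canvas_side, 3L))
  canvas[(dy + 1):(dy + ch), (dx + 1):(dx + cw), ] <- crop
  structure(list(pixels = canvas, offset = c(dx = dx, dy = dy), bbox = used),
            class = "cropped_retina")
}

#' Resize an image to a percentage of its original size
#'
#' Output dimensions are `floor(dim * pct / 100)` per side (so a 2912-pixel
#' side at 15% becomes 436); resampling is bilinear.
#'
#' @param img A [frame()], RGB array or grayscale matrix.
#' @param pct Percentage in `(0, 100]`.
#' @return The resized raster (same kind as the input pixels).
#' @export
resize_percent <- function(img, pct) {
  if (!is.finite(pct) || pct <= 0 || pct > 100) {
    stop("pct must lie in (0, 100]")
  }
  px <- as_pixels(img)
  h <- dim(as.matrix(if (is.matrix(px)) px else px[, , 1]))[1]
  h <- if (is.matrix(px)) nrow(px) else dim(px)[1]
  w <- if (is.matrix(px)) ncol(px) else dim(px)[2]
  oh <- max(1L, as.integer(floor(h * pct / 100)))
  ow <- max(1L, as.integer(floor(w * pct / 100)))
  if (oh == h && ow == w) return(px)
  if (is.matrix(px)) {
    cpp_resize_bilinear(px, oh, ow)
  } else {
    out <- array(0, dim = c(oh, ow, dim(px)[3]))
    for (c in seq_len(dim(px)[3])) {
      out[, , c] <- cpp_resize_bilinear(px[, , c], oh, ow)
    }
    out
  }
}
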