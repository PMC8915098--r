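# Set-wise intensity normalization. Smartphone-ophthalmoscope frames drift
# in brightness from frame to frame; before thresholding or blending, every
# frame in a set is scaled down to the set's lowest mean intensity:
#   out_X = (I_min / I_Xmean) * in_X
# so all frames share the same mean. The scale is a set statistic, so the
# whole set must be visible before any image is emitted.

#' Mean intensity of a frame
#'
#' Arithmetic mean over all pixels and all three channels, in 8-bit units.
#'
#' @param img A [frame()] or RGB array.
#' @return A scalar in `[0, 255]`.
#' @export
mean_intensity <- function(img) {
  px <- validate_rgb(as_pixels(img))
  mean(px)
}

#' Normalize the intensity of a set of frames to the lowest set mean
#'
#' Computes each image's mean intensity, finds the set minimum `I_min`, and
#' scales every image by `I_min / own_mean` (a ratio in (0, 1]). The scaled
#' float means are all exactly `I_min`; with `round = TRUE` the output is
#' additionally quantized to 8-bit (round half up), which perturbs the means
#' by less than half an intensity level.
#'
#' @param imgs A list of [frame()] objects or RGB arrays (at least one).
#' @param round Quantize outputs to 8-bit integers? Default `TRUE`; set
#'   `FALSE` to keep the exact float rasters.
#' @return A list with elements
#'   \describe{
#'     \item{images}{the normalized frames (same classes as the input),}
#'     \item{context}{a list with `per_image_mean`, `min_mean` and `ratios`.}
#'   }
#' @export
normalize_set <- function(imgs, round = TRUE) {
  stopifnot(is.list(imgs), length(imgs) >= 1L)
  means <- vapply(imgs, mean_intensity, numeric(1))
  zero <- which(means <= 0)
  if (length(zero) > 0L) {
    stop(sprintf("cannot normalize: image(s) %s have zero mean intensity",
                 paste(zero, collapse = ", ")))
  }
  min_mean <- min(means)
  ratios <- min_mean / means
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    px <- as_pixels(imgs[[i]]) * ratios[i]
    if (round) px <- quantize8(px)
    if (inherits(imgs[[i]], "frame")) {
      out[[i]] <- frame(px, imgs[[i]]$source_id, imgs[[i]]$index)
    } else {
      out[[i]] <- px
    }
  }
  list(images = out,
       context = list(per_image_mean = means, min_mean = min_mean,
                      ratios = ratios))
}
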