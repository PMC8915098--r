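# Classical retinal-region detector. In a smartphone-ophthalmoscope frame
# the visible retina is a small bright circle on a near-black surround, and
# the red channel carries most of its contrast. The chain is:
#   red channel -> Gaussian blur -> Otsu threshold -> contour image ->
#   Circle Hough Transform -> enclosing square (clipped to the frame).
# A learned detector can be swapped in: anything that maps a frame to a
# `detection_result` honours the same contract.

#' Circle Hough Transform parameters
#'
#' Radius limits are fractions of `min(height, width)`; the candidate
#' separation is a fraction of the image diagonal. `accumulator_threshold`
#' is the minimum supported fraction of a candidate circle's perimeter
#' (1 = every boundary pixel present), which makes the threshold
#' radius-invariant.
#'
#' @param min_radius_frac,max_radius_frac Radius window as fractions of the
#'   smaller image dimension; `0 < min < max <= 0.5`.
#' @param accumulator_threshold Minimum perimeter-support fraction in (0, 1].
#' @param min_center_distance_frac Candidate-center separation as a fraction
#'   of the image diagonal.
#' @param blur_kernel Odd Gaussian kernel width (pixels) used by
#'   [detect_retina()]; 1 disables blurring.
#' @param radius_step Accumulator radius stride in pixels.
#' @param working_width Internal working size for [detect_retina()]: frames
#'   larger than this on their longest side are downscaled before the chain
#'   runs, and the detected geometry is scaled back. Full-resolution video
#'   frames carry no extra information at the scale of the retinal window,
#'   so this only buys speed.
#' @return A list of class `cht_params`.
#' @export
cht_params <- function(min_radius_frac = 0.10, max_radius_frac = 0.45,
                       accumulator_threshold = 0.25,
                       min_center_distance_frac = 0.10,
                       blur_kernel = 9L, radius_step = 1L,
                       working_width = 480L) {
  stopifnot(min_radius_frac > 0, min_radius_frac < max_radius_frac,
            max_radius_frac <= 0.5,
            accumulator_threshold > 0,
            min_center_distance_frac > 0,
            blur_kernel >= 1, blur_kernel %% 2 == 1,
            radius_step >= 1, working_width >= 32)
  structure(list(min_radius_frac = min_radius_frac,
                 max_radius_frac = max_radius_frac,
                 accumulator_threshold = accumulator_threshold,
                 min_center_distance_frac = min_center_distance_frac,
                 blur_kernel = as.integer(blur_kernel),
                 radius_step = as.integer(radius_step),
                 working_width = as.integer(working_width)),
            class = "cht_params")
}

#' Extract the red channel
#'
#' @param img A [frame()] or RGB array.
#' @return A numeric matrix equal to the R plane.
#' @export
extract_red_channel <- function(img) {
  px <- validate_rgb(as_pixels(img))
  px[, , 1]
}

#' Gaussian blur of a grayscale image
#'
#' Separable Gaussian with a square kernel and replicate borders. The
#' standard deviation follows the usual kernel-size heuristic
#' `0.3 * ((k - 1) / 2 - 1) + 0.8`. A kernel of 1 is the identity.
#'
#' @param img Numeric matrix.
#' @param kernel Odd integer kernel width, `>= 1`.
#' @return Blurred numeric matrix (float; not quantized).
#' @export
blur <- function(img, kernel = 9L) {
  img <- as.matrix(img)
  if (kernel < 1 || kernel %% 2 == 0) stop("blur kernel must be odd and >= 1")
  if (kernel == 1L) return(img)
  sigma <- 0.3 * ((kernel - 1) * 0.5 - 1) + 0.8
  cpp_gaussian_blur(img, as.integer(kernel), sigma)
}

#' Otsu automatic threshold
#'
#' Chooses the 8-bit threshold maximizing the between-class variance of the
#' 256-bin histogram; pixels strictly above the threshold are foreground.
#' On a plateau of equally good thresholds the plateau midpoint is taken.
#'
#' @param img Numeric matrix with values in `[0, 255]` (floats are binned by
#'   rounding).
#' @return A list with `mask` (a [binary_mask()], 1 = above threshold) and
#'   `threshold` (numeric).
#' @export
otsu_threshold <- function(img) {
  img <- as.matrix(img)
  vals <- round_half_up(clamp255(img))
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    stop("degenerate input: constant image has no valid Otsu split")
  }
  levels <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)               # class {<= t}
  m0 <- cumsum(counts * levels)
  mu_total <- m0[256] / n
  # between-class variance for t = 0..254 (split below/above t)
  t_idx <- 1:255
  w0t <- w0[t_idx] / n
  w1t <- 1 - w0t
  mu0 <- ifelse(w0[t_idx] > 0, m0[t_idx] / w0[t_idx], 0)
  mu1 <- ifelse(w1t > 0, (m0[256] - m0[t_idx]) / (n - w0[t_idx]), 0)
  sigma_b <- w0t * w1t * (mu0 - mu1)^2
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  thr <- mean(range(levels[best]))   # plateau midpoint
  mask <- binary_mask(vals > thr)
  list(mask = mask, threshold = thr)
}

#' Contour image of a binary mask
#'
#' Marks the 8-connected boundary of every foreground component: a pixel is
#' a boundary pixel iff it is foreground and touches background (or the
#' image border). Output follows the white-background / black-lines
#' convention used by the detector chain.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @return A numeric matrix with 255 background and 0 on boundaries.
#' @export
contour_image <- function(mask) {
  m <- unclass(as.matrix(mask))
  storage.mode(m) <- "integer"
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)   # border counts as background
  pad[2:(h + 1), 2:(w + 1)] <- m
  nb <- matrix(0L, h, w)              # min over the 8-neighbourhood
  nbmin <- matrix(1L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    nbmin <- pmin(nbmin, pad[(2:(h + 1)) + dy, (2:(w + 1)) + dx])
  }
  boundary <- m == 1L & nbmin == 0L
  out <- matrix(255, h, w)
  out[boundary] <- 0
  nb <- NULL
  out
}

# interpret either a contour image (white bg / black lines) or a 0/1 edge
# mask as a binary edge matrix (1 = edge pixel)
as_edge_matrix <- function(edges) {
  e <- unclass(as.matrix(edges))
  if (max(e) > 1) {
    edge <- e < 128          # contour convention: black lines are edges
    if (all(edge)) edge[] <- FALSE   # all-black image carries no contour
  } else {
    edge <- e == 1
  }
  storage.mode(edge) <- "integer"
  edge
}

#' Circle Hough Transform
#'
#' Accumulates center votes from every edge pixel over the configured radius
#' window and returns candidate circles ranked by perimeter-support score.
#' Ties are broken deterministically: larger radius first, then smaller
#' center y, then smaller center x. Candidates closer than the configured
#' center distance to a better one are suppressed.
#'
#' @param edges A contour image (white background, black lines) or a 0/1
#'   edge mask.
#' @param p [cht_params()].
#' @return A list of [circle()] objects, each with a `score` attribute
#'   (supported perimeter fraction); empty when nothing passes threshold.
#' @export
hough_circle <- function(edges, p = cht_params()) {
  edge <- as_edge_matrix(edges)
  h <- nrow(edge); w <- ncol(edge)
  r_min <- max(2, round(p$min_radius_frac * min(h, w)))
  r_max <- max(r_min, round(p$max_radius_frac * min(h, w)))
  radii <- seq(r_min, r_max, by = p$radius_step)
  cand <- cpp_hough_circle(edge, as.numeric(radii), p$accumulator_threshold)
  if (nrow(cand) == 0L) return(list())
  ord <- order(-cand[, 4], -cand[, 3], cand[, 2], cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  min_dist <- p$min_center_distance_frac * sqrt(h^2 + w^2)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) == 0L) { keep <- i; next }
    d <- sqrt((cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2)
    if (all(d >= min_dist)) keep <- c(keep, i)
  }
  lapply(keep, function(i) {
    ci <- circle(cand[i, 1], cand[i, 2], cand[i, 3])
    attr(ci, "score") <- cand[i, 4]
    ci
  })
}

#' Enclosing square of a circle, clipped to the image
#'
#' Rounds each side half away from zero, then clips to the image; clipping
#' at a border may break exact squareness.
#'
#' @param c A [circle()].
#' @param img_w,img_h Image width and height in pixels.
#' @return A [bbox()].
#' @export
circle_to_bbox <- function(c, img_w, img_h) {
  stopifnot(inherits(c, "circle"), img_w >= 1, img_h >= 1)
  x0 <- max(0, round_half_up(c$cx - c$r))
  y0 <- max(0, round_half_up(c$cy - c$r))
  x1 <- min(img_w, round_half_up(c$cx + c$r))
  y1 <- min(img_h, round_half_up(c$cy + c$r))
  if (x0 >= x1 || y0 >= y1) stop("circle lies entirely outside the image")
  bbox(x0, y0, x1, y1)
}

#' Detect the retinal region in a frame
#'
#' Runs the full classical chain and promotes the top-voted circle to a
#' detection. Frames whose Otsu split is degenerate (e.g. all black) or in
#' which no circle passes the accumulator threshold yield a no-detection
#' result rather than an error — the known failure mode of this method on
#' very poor frames.
#'
#' @param img A [frame()] or RGB array.
#' @param p [cht_params()].
#' @return A list of class `detection_result` with elements `circle`
#'   ([circle()] or `NULL`), `bbox` ([bbox()] or `NULL`), `method` (`"cht"`)
#'   and `diagnostics` (Otsu `threshold`, `n_candidates`).
#' @export
detect_retina <- function(img, p = cht_params()) {
  px <- validate_rgb(as_pixels(img))
  h <- dim(px)[1]; w <- dim(px)[2]
  red <- px[, , 1]
  scale <- 1
  if (max(h, w) > p$working_width) {
    scale <- p$working_width / max(h, w)
    red <- cpp_resize_bilinear(red, max(1L, as.integer(round(h * scale))),
                               max(1L, as.integer(round(w * scale))))
  }
  no_detection <- function(thr, ncand) {
    structure(list(circle = NULL, bbox = NULL, method = "cht",
                   diagnostics = list(threshold = thr,
                                      n_candidates = ncand)),
              class = "detection_result")
  }
  blurred <- blur(red, p$blur_kernel)
  ot <- tryCatch(otsu_threshold(blurred), error = function(e) NULL)
  if (is.null(ot)) return(no_detection(NA_real_, 0L))
  edges <- contour_image(ot$mask)
  circles <- hough_circle(edges, p)
  if (length(circles) == 0L) return(no_detection(ot$threshold, 0L))
  top <- circles[[1]]
  full <- circle(top$cx / scale, top$cy / scale, top$r / scale)
  b <- tryCatch(circle_to_bbox(full, w, h), error = function(e) NULL)
  if (is.null(b)) return(no_detection(ot$threshold, length(circles)))
  structure(list(circle = full, bbox = b, method = "cht",
                 diagnostics = list(threshold = ot$threshold,
                                    n_candidates = length(circles))),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (is.null(x$bbox)) {
    cat(sprintf("<detection: none (method=%s, candidates=%d)>\n",
                x$method, x$diagnostics$n_candidates))
  } else {
    cat(sprintf("<detection: circle (%.1f, %.1f) r=%.1f, bbox (%d,%d)-(%d,%d)>\n",
                x$circle$cx, x$circle$cy, x$circle$r,
                x$bbox[["x_min"]], x$bbox[["y_min"]],
                x$bbox[["x_max"]], x$bbox[["y_max"]]))
  }
  invisible(x)
}

#' Single-class YOLO layer configuration arithmetic
#'
#' Derives the three values a YOLO config file needs per detected class
#' count: `max_batches = max(2000 * classes, 6000)`, `steps` at 80% and 90%
#' of `max_batches`, and `filters = (classes + 5) * 3` for the convolutional
#' layers feeding each YOLO head. Provided for interoperability with a
#' learned detector; no network is shipped or trained here.
#'
#' @param classes Positive integer number of object classes.
#' @return A list with `classes`, `max_batches`, `steps` (length-2 integer)
#'   and `filters`.
#' @export
derive_yolo_config <- function(classes) {
  if (length(classes) != 1L || !is.finite(classes) || classes < 1 ||
      classes != round(classes)) {
    stop("classes must be a positive integer")
  }
  classes <- as.integer(classes)
  max_batches <- max(2000L * classes, 6000L)
  list(classes = classes,
       max_batches = max_batches,
       steps = as.integer(round(c(0.8, 0.9) * max_batches)),
       filters = (classes + 5L) * 3L)
}
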