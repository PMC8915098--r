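#' @useDynLib retistitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile
#' @importFrom utils read.csv write.csv
NULL

# Coordinate convention, used everywhere: 0-based, origin at the top-left
# pixel, x rightward, y downward. A raster matrix element [row, col] is pixel
# (x = col - 1, y = row - 1). Boxes are half-open: column x_max and row y_max
# are excluded.

#' Axis-aligned bounding box
#'
#' Construct a half-open, 0-based integer bounding box, the currency of
#' detection output, cropping and evaluation. Pixel column `x_max` and row
#' `y_max` are excluded, so the covered pixel set is
#' `{x_min, ..., x_max - 1} x {y_min, ..., y_max - 1}`.
#'
#' @param x_min,y_min,x_max,y_max Integer pixel coordinates with
#'   `0 <= x_min < x_max` and `0 <= y_min < y_max`.
#' @return An object of class `bbox`: a named integer vector.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' bbox_area(b)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  v <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (anyNA(v) || any(v != round(v))) {
    stop("bbox coordinates must be non-missing integers")
  }
  v <- as.integer(round(v))
  names(v) <- c("x_min", "y_min", "x_max", "y_max")
  if (v[["x_min"]] < 0L || v[["y_min"]] < 0L) {
    stop("bbox coordinates must be non-negative")
  }
  if (v[["x_min"]] >= v[["x_max"]] || v[["y_min"]] >= v[["y_max"]]) {
    stop("bbox must satisfy x_min < x_max and y_min < y_max")
  }
  structure(v, class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox (%d,%d)-(%d,%d) area=%d>\n",
              x[["x_min"]], x[["y_min"]], x[["x_max"]], x[["y_max"]],
              bbox_area(x)))
  invisible(x)
}

#' Bounding-box area in pixels
#'
#' @param b A [bbox()].
#' @return Non-negative integer: `(x_max - x_min) * (y_max - y_min)`.
#' @export
bbox_area <- function(b) {
  stopifnot(inherits(b, "bbox"))
  as.integer((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' Intersection of two bounding boxes
#'
#' @param a,b [bbox()] objects.
#' @return The half-open intersection `bbox`, or `NULL` when the boxes are
#'   disjoint (including boxes that only share an edge, which is an empty
#'   pixel set under the half-open convention).
#' @export
bbox_intersection <- function(a, b) {
  stopifnot(inherits(a, "bbox"), inherits(b, "bbox"))
  x0 <- max(a[["x_min"]], b[["x_min"]])
  y0 <- max(a[["y_min"]], b[["y_min"]])
  x1 <- min(a[["x_max"]], b[["x_max"]])
  y1 <- min(a[["y_max"]], b[["y_max"]])
  if (x0 >= x1 || y0 >= y1) return(NULL)
  bbox(x0, y0, x1, y1)
}

#' Circle with sub-pixel center
#'
#' @param cx,cy Center in pixels (floats allowed).
#' @param r Radius in pixels, strictly positive.
#' @return An object of class `circle`.
#' @export
circle <- function(cx, cy, r) {
  if (!is.finite(cx) || !is.finite(cy) || !is.finite(r) || r <= 0) {
    stop("circle requires finite center and r > 0")
  }
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("<circle center=(%.2f, %.2f) r=%.2f>\n", x$cx, x$cy, x$r))
  invisible(x)
}

#' Planar projective transform (homography)
#'
#' A 3x3 invertible matrix mapping following-image coordinates to
#' base-image coordinates, normalized so the bottom-right entry is 1.
#'
#' @param h A 3x3 numeric matrix with `h[3,3] != 0`.
#' @return An object of class `homography` (the normalized matrix).
#' @export
homography <- function(h) {
  h <- as.matrix(h)
  stopifnot(all(dim(h) == c(3L, 3L)), all(is.finite(h)))
  if (abs(h[3, 3]) < 1e-12) stop("homography has (near-)zero h33")
  if (abs(det(h)) < 1e-12) stop("homography must be invertible")
  structure(h / h[3, 3], class = "homography")
}

#' Apply a homography to 0-based point coordinates
#'
#' @param h A [homography()] (or plain 3x3 matrix).
#' @param pts An n x 2 matrix of (x, y) coordinates.
#' @return An n x 2 matrix of transformed (x, y) coordinates.
#' @export
apply_homography <- function(h, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- cbind(pts, 1) %*% t(unclass(h))
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Binary mask constructor
#'
#' @param m A matrix whose entries are 0/1 (or logical).
#' @return An integer 0/1 matrix of class `binary_mask`.
#' @export
binary_mask <- function(m) {
  m <- as.matrix(m)
  if (is.logical(m)) m <- m + 0L
  if (!all(m %in% c(0L, 1L))) stop("binary mask values must be exactly 0 or 1")
  storage.mode(m) <- "integer"
  structure(m, class = c("binary_mask", "matrix"))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
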