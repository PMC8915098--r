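# Registration and feathering blending. Registration estimates a planar
# homography from matched keypoints (normalized DLT inside RANSAC, then
# least-squares and Gauss-Newton refinement on the inliers). Blending
# weights each image in the overlap by its Euclidean distance transform:
#   w1 = d2 / (d1 + d2),  w2 = d1 / (d1 + d2)
# where d_i is the distance to the nearest pixel of image i outside the
# overlap, so each image fades out toward its own boundary and the weights
# sum to 1 everywhere both images are valid.

#' Mosaicing parameters
#'
#' @param ratio Lowe ratio-test threshold for matching.
#' @param ransac_tol RANSAC inlier reprojection tolerance, pixels.
#' @param min_inliers Minimum RANSAC consensus for accepting a pairwise
#'   registration inside [mosaic_sequence()].
#' @param max_iter RANSAC iteration cap.
#' @param max_keypoints Per-image keypoint budget.
#' @return A list of class `mosaic_params`.
#' @export
mosaic_params <- function(ratio = 0.8, ransac_tol = 3, min_inliers = 10L,
                          max_iter = 2000L, max_keypoints = 1500L) {
  stopifnot(ratio > 0, ratio <= 1, ransac_tol > 0, min_inliers >= 4,
            max_iter >= 1, max_keypoints >= 10)
  structure(list(ratio = ratio, ransac_tol = ransac_tol,
                 min_inliers = as.integer(min_inliers),
                 max_iter = as.integer(max_iter),
                 max_keypoints = as.integer(max_keypoints)),
            class = "mosaic_params")
}

# normalized DLT from >= 4 correspondences; from/to are n x 2
dlt_homography <- function(from, to) {
  n <- nrow(from)
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    t <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
    list(t = t, p = cbind((p[, 1] - ctr[1]) * s, (p[, 2] - ctr[2]) * s))
  }
  nf <- norm_pts(from); nt <- norm_pts(to)
  x <- nf$p[, 1]; y <- nf$p[, 2]; u <- nt$p[, 1]; v <- nt$p[, 2]
  a <- matrix(0, 2 * n, 9)
  a[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  a[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  h <- svd(a, nu = 0, nv = 9)$v[, 9]
  hn <- matrix(h, 3, 3, byrow = TRUE)
  hh <- solve(nt$t) %*% hn %*% nf$t
  if (abs(hh[3, 3]) < 1e-12) return(NULL)
  hh / hh[3, 3]
}

# symmetric-free geometric refinement: Gauss-Newton on forward transfer error
refine_homography <- function(h, from, to, iters = 5) {
  p <- c(h[1, ], h[2, ], h[3, 1:2])  # 8 dof, h33 = 1
  n <- nrow(from)
  for (it in seq_len(iters)) {
    den <- p[7] * from[, 1] + p[8] * from[, 2] + 1
    px <- (p[1] * from[, 1] + p[2] * from[, 2] + p[3]) / den
    py <- (p[4] * from[, 1] + p[5] * from[, 2] + p[6]) / den
    r <- c(to[, 1] - px, to[, 2] - py)
    j <- matrix(0, 2 * n, 8)
    j[1:n, 1] <- from[, 1] / den
    j[1:n, 2] <- from[, 2] / den
    j[1:n, 3] <- 1 / den
    j[1:n, 7] <- -px * from[, 1] / den
    j[1:n, 8] <- -px * from[, 2] / den
    j[(n + 1):(2 * n), 4] <- from[, 1] / den
    j[(n + 1):(2 * n), 5] <- from[, 2] / den
    j[(n + 1):(2 * n), 6] <- 1 / den
    j[(n + 1):(2 * n), 7] <- -py * from[, 1] / den
    j[(n + 1):(2 * n), 8] <- -py * from[, 2] / den
    step <- tryCatch(solve(crossprod(j) + diag(1e-9, 8), crossprod(j, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    p <- p + as.numeric(step)
  }
  matrix(c(p[1:3], p[4:6], p[7:8], 1), 3, 3, byrow = TRUE)
}

collinear4 <- function(p) {
  for (i in 1:2) for (j in (i + 1):3) for (k in (j + 1):4) {
    area <- abs((p[j, 1] - p[i, 1]) * (p[k, 2] - p[i, 2]) -
                (p[k, 1] - p[i, 1]) * (p[j, 2] - p[i, 2]))
    if (area < 1e-6) return(TRUE)
  }
  FALSE
}

#' Estimate a homography from matched keypoints
#'
#' RANSAC over normalized-DLT 4-point hypotheses, followed by a
#' least-squares DLT refit on the consensus set and Gauss-Newton refinement
#' of the geometric transfer error. The result maps following-image
#' coordinates into base-image coordinates.
#'
#' @param m A `match_set` from [match_descriptors()] with at least 4 pairs.
#' @param base,following The `keypoint_set`s the match indices refer to.
#' @param p [mosaic_params()] (tolerance and iteration cap are used here).
#' @return A [homography()] with attributes `inliers` (logical per match)
#'   and `rms` (inlier reprojection RMS in pixels).
#' @export
estimate_homography <- function(m, base, following, p = mosaic_params()) {
  stopifnot(inherits(m, "match_set"))
  n <- nrow(m$pairs)
  if (n < 4L) stop("insufficient correspondences: need >= 4 matches")
  pb <- base$locations[m$pairs[, 1], , drop = FALSE]
  pf <- following$locations[m$pairs[, 2], , drop = FALSE]
  tol2 <- p$ransac_tol^2
  best_inl <- NULL
  best_cnt <- 0L
  iter <- 0L
  max_iter <- p$max_iter
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- sample.int(n, 4L)
    if (collinear4(pf[s, , drop = FALSE]) || collinear4(pb[s, , drop = FALSE])) next
    h <- tryCatch(dlt_homography(pf[s, , drop = FALSE], pb[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(h)) next
    pr <- apply_homography(h, pf)
    err2 <- rowSums((pr - pb)^2)
    inl <- err2 < tol2
    cnt <- sum(inl)
    if (cnt > best_cnt) {
      best_cnt <- cnt
      best_inl <- inl
      if (cnt >= 4L) {
        # adaptive termination at 99.9% confidence
        ratio <- cnt / n
        need <- log(0.001) / log(pmax(1e-12, 1 - ratio^4))
        max_iter <- min(p$max_iter, max(iter, ceiling(need)))
      }
    }
  }
  if (best_cnt < 4L) stop("homography estimation failed: no consensus set")
  # refit + refine on inliers, then one re-classification pass
  for (pass in 1:2) {
    h <- dlt_homography(pf[best_inl, , drop = FALSE],
                        pb[best_inl, , drop = FALSE])
    if (is.null(h)) stop("homography estimation failed: degenerate refit")
    h <- refine_homography(h, pf[best_inl, , drop = FALSE],
                           pb[best_inl, , drop = FALSE])
    err2 <- rowSums((apply_homography(h, pf) - pb)^2)
    new_inl <- err2 < tol2
    if (sum(new_inl) < 4L) break
    best_inl <- new_inl
  }
  out <- homography(h)
  attr(out, "inliers") <- best_inl
  attr(out, "rms") <- sqrt(mean(err2[best_inl]))
  out
}

#' Warp an image into a reference canvas
#'
#' Inverse-maps every canvas pixel through the homography and samples the
#' source bilinearly. The mask marks exactly the canvas pixels covered by
#' the source.
#'
#' @param img A [frame()], RGB array or grayscale matrix.
#' @param h A [homography()] mapping image coordinates to canvas coordinates.
#' @param canvas_w,canvas_h Canvas dimensions in pixels.
#' @return A list with `pixels` (warped raster) and `mask` (a
#'   [binary_mask()]).
#' @export
warp_to_reference <- function(img, h, canvas_w, canvas_h) {
  px <- as_pixels(img)
  if (is.matrix(px)) { dim(px) <- c(dim(px), 1L) }
  hinv <- solve(unclass(h))
  res <- cpp_warp_bilinear(px, hinv, as.integer(canvas_h),
                           as.integer(canvas_w))
  pixels <- res$pixels
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 1L) {
    pixels <- pixels[, , 1]
  }
  list(pixels = pixels, mask = binary_mask(res$mask))
}

#' Feathering blend weights from two validity masks
#'
#' For each image, computes the exact Euclidean distance from every pixel to
#' that image's nearest valid pixel *outside* the overlap, then converts the
#' two distance fields into complementary weights: inside the overlap
#' `w1 = d2 / (d1 + d2)` and `w2 = d1 / (d1 + d2)`; outside it each image
#' keeps weight 1 on its own territory and 0 elsewhere. An image entirely
#' contained in the overlap has no such outside pixel; both weights then
#' fall back to 0.5 inside the overlap (with a warning).
#'
#' @param m1,m2 [binary_mask()]s on a shared canvas.
#' @return A list of class `blend_field`: `m1`, `m2`, `R` (overlap mask),
#'   `d1`, `d2` (distance fields) and `w1`, `w2` (weights in `[0, 1]`).
#' @export
compute_blend_weights <- function(m1, m2) {
  m1 <- unclass(as.matrix(m1)); m2 <- unclass(as.matrix(m2))
  stopifnot(all(dim(m1) == dim(m2)))
  storage.mode(m1) <- "integer"; storage.mode(m2) <- "integer"
  r <- m1 * m2
  f1 <- m1 * (1L - r)   # image-1 pixels outside the overlap
  f2 <- m2 * (1L - r)
  deg1 <- sum(f1) == 0L && sum(m1) > 0L && sum(r) > 0L
  deg2 <- sum(f2) == 0L && sum(m2) > 0L && sum(r) > 0L
  d1 <- cpp_edt(f1)
  d2 <- cpp_edt(f2)
  w1 <- matrix(0, nrow(m1), ncol(m1))
  w2 <- matrix(0, nrow(m1), ncol(m1))
  w1[m1 == 1L & r == 0L] <- 1
  w2[m2 == 1L & r == 0L] <- 1
  ov <- r == 1L
  if (any(ov)) {
    if (deg1 || deg2) {
      warning("image fully contained in the overlap; using uniform 0.5 weights")
      w1[ov] <- 0.5
      w2[ov] <- 0.5
    } else {
      s <- d1[ov] + d2[ov]
      w1[ov] <- d2[ov] / s
      w2[ov] <- d1[ov] / s
    }
  }
  structure(list(m1 = binary_mask(m1), m2 = binary_mask(m2),
                 R = binary_mask(r), d1 = d1, d2 = d2, w1 = w1, w2 = w2),
            class = "blend_field")
}

#' Blend two images with precomputed feathering weights
#'
#' Per-pixel, per-channel weighted sum `w1 * I1 + w2 * I2`, computed in
#' float and quantized to 8-bit. Pixels outside both masks come out 0.
#'
#' @param i1,i2 Rasters of identical shape (RGB arrays or matrices).
#' @param f A `blend_field` from [compute_blend_weights()].
#' @return The blended raster.
#' @export
blend <- function(i1, i2, f) {
  p1 <- as_pixels(i1); p2 <- as_pixels(i2)
  if (!identical(dim(p1), dim(p2))) stop("blend inputs must share a shape")
  if (is.matrix(p1)) {
    return(quantize8(f$w1 * p1 + f$w2 * p2))
  }
  out <- array(0, dim = dim(p1))
  for (c in seq_len(dim(p1)[3])) {
    out[, , c] <- f$w1 * p1[, , c] + f$w2 * p2[, , c]
  }
  quantize8(out)
}

#' Mosaic a sequence of frames
#'
#' The first frame is the base referential. Each following frame is
#' registered against the most recent successfully registered frame
#' (keypoints, ratio-test matching, RANSAC homography), its transform is
#' composed onto the accumulated chain, the canvas grows to the union of
#' warped extents, and the newcomer is feather-blended into the mosaic.
#' Frames that fail registration (too few matches or inliers) are skipped
#' with a warning.
#'
#' @param imgs List of at least 2 [frame()]s or RGB arrays, already
#'   intensity-normalized (see [normalize_set()]).
#' @param p [mosaic_params()].
#' @return A list of class `mosaic_result`: `canvas` (RGB raster),
#'   `valid_mask` ([binary_mask()]), `homographies` (one per input frame,
#'   mapping that frame into the base referential; `NULL` for skipped
#'   frames; the first is the identity), `offset` (`c(ox, oy)`: add to
#'   base-referential coordinates to get canvas coordinates) and `skipped`
#'   (integer indices).
#' @export
mosaic_sequence <- function(imgs, p = mosaic_params()) {
  stopifnot(is.list(imgs), length(imgs) >= 2L)
  n <- length(imgs)
  kp_ref <- detect_and_describe(imgs[[1]], max_keypoints = p$max_keypoints)
  canvas <- as_pixels(imgs[[1]])
  mask <- binary_mask(matrix(1L, dim(canvas)[1], dim(canvas)[2]))
  offset <- c(ox = 0, oy = 0)
  homs <- vector("list", n)
  homs[[1]] <- homography(diag(3))
  h_ref_to_base <- diag(3)   # most recent registered frame -> base
  skipped <- integer(0)
  for (i in 2:n) {
    kp_i <- detect_and_describe(imgs[[i]], max_keypoints = p$max_keypoints)
    reg <- tryCatch({
      m <- match_descriptors(kp_ref, kp_i, ratio = p$ratio)
      if (nrow(m$pairs) < 4L) stop("too few matches")
      h <- estimate_homography(m, kp_ref, kp_i, p)
      if (sum(attr(h, "inliers")) < p$min_inliers) stop("too few inliers")
      h
    }, error = function(e) e)
    if (inherits(reg, "error")) {
      warning(sprintf("frame %d skipped: %s", i, conditionMessage(reg)))
      skipped <- c(skipped, i)
      homs[i] <- list(NULL)
      next
    }
    h_i_to_base <- h_ref_to_base %*% unclass(reg)
    homs[[i]] <- homography(h_i_to_base)
    # grow the canvas to the union of extents (in base coordinates)
    px_i <- as_pixels(imgs[[i]])
    hi <- dim(px_i)[1]; wi <- dim(px_i)[2]
    corners <- apply_homography(h_i_to_base,
                                rbind(c(0, 0), c(wi - 1, 0),
                                      c(0, hi - 1), c(wi - 1, hi - 1)))
    cur_x0 <- -offset[["ox"]]; cur_y0 <- -offset[["oy"]]
    cur_x1 <- cur_x0 + dim(canvas)[2] - 1
    cur_y1 <- cur_y0 + dim(canvas)[1] - 1
    # small epsilon so sub-hundredth registration jitter does not grow the
    # canvas by a phantom row/column
    new_x0 <- floor(min(cur_x0, corners[, 1] + 0.01))
    new_y0 <- floor(min(cur_y0, corners[, 2] + 0.01))
    new_x1 <- ceiling(max(cur_x1, corners[, 1] - 0.01))
    new_y1 <- ceiling(max(cur_y1, corners[, 2] - 0.01))
    new_w <- as.integer(new_x1 - new_x0 + 1)
    new_h <- as.integer(new_y1 - new_y0 + 1)
    if (new_w * new_h > 6e7) stop("mosaic canvas grew unreasonably large")
    shift_x <- as.integer(cur_x0 - new_x0)
    shift_y <- as.integer(cur_y0 - new_y0)
    big <- array(0, dim = c(new_h, new_w, 3L))
    big[(shift_y + 1):(shift_y + dim(canvas)[1]),
        (shift_x + 1):(shift_x + dim(canvas)[2]), ] <- canvas
    bigm <- matrix(0L, new_h, new_w)
    bigm[(shift_y + 1):(shift_y + dim(canvas)[1]),
         (shift_x + 1):(shift_x + dim(canvas)[2])] <- unclass(mask)
    offset <- c(ox = -new_x0, oy = -new_y0)
    t_off <- matrix(c(1, 0, offset[["ox"]], 0, 1, offset[["oy"]], 0, 0, 1),
                    3, 3, byrow = TRUE)
    wr <- warp_to_reference(px_i, homography(t_off %*% h_i_to_base),
                            new_w, new_h)
    f <- suppressWarnings(
      compute_blend_weights(binary_mask(bigm), wr$mask))
    canvas <- blend(big, wr$pixels, f)
    mask <- binary_mask((bigm | unclass(wr$mask)) + 0L)
    kp_ref <- kp_i
    h_ref_to_base <- h_i_to_base
  }
  if (length(skipped) == n - 1L) {
    warning("all following frames failed registration; single-image mosaic")
  }
  structure(list(canvas = canvas, valid_mask = mask, homographies = homs,
                 offset = offset, skipped = skipped),
            class = "mosaic_result")
}

#' @export
print.mosaic_result <- function(x, ...) {
  d <- dim(x$canvas)
  cat(sprintf("<mosaic %dx%d px, %d/%d frames registered>\n", d[2], d[1],
              sum(!vapply(x$homographies, is.null, logical(1))),
              length(x$homographies)))
  invisible(x)
}
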