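# Keypoint detection and description for registration. The shipped detector
# is a classical multi-scale Harris corner detector with sub-pixel
# refinement; description is SIFT-style 4x4x8 gradient histograms
# post-processed to root-SIFT (L1-normalize then element-wise square root,
# leaving unit L2 norm, compared with Euclidean distance). Any stage
# producing the same `keypoint_set` shape — e.g. a learned detector — can be
# substituted upstream of matching.

gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  cpp_gaussian_blur(img, k, sigma)
}

gradient_xy <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  if (h >= 3) gy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Detect and describe keypoints
#'
#' Multi-scale Harris corners (structure-tensor response, scale-normalized,
#' 3x3 sub-pixel refined) described by 128-dimensional root-SIFT vectors.
#' A featureless (constant) image yields an empty set.
#'
#' @param img A [frame()], RGB array or grayscale matrix.
#' @param max_keypoints Keep at most this many strongest corners.
#' @param scales Detection scales (Gaussian sigmas, pixels).
#' @param response_frac Relative response threshold: corners weaker than
#'   this fraction of the strongest response are dropped.
#' @return A list of class `keypoint_set`: `locations` (n x 2 matrix of
#'   0-based x, y), `scales`, `responses`, `orientations` (radians),
#'   `descriptors` (n x 128, unit L2 rows) and `source_id`.
#' @export
detect_and_describe <- function(img, max_keypoints = 1500L,
                                scales = c(1.5, 3, 6),
                                response_frac = 1e-4) {
  src <- if (inherits(img, "frame")) img$source_id else "image"
  px <- as_pixels(img)
  gray <- if (is.matrix(px)) px else to_gray(px)
  empty <- structure(list(locations = matrix(numeric(0), 0, 2),
                          scales = numeric(0), responses = numeric(0),
                          orientations = numeric(0),
                          descriptors = matrix(numeric(0), 0, 128),
                          source_id = src),
                     class = "keypoint_set")
  if (stats::sd(gray) < 1e-9) return(empty)
  all_kp <- NULL
  smoothed <- list()
  for (si in seq_along(scales)) {
    s <- scales[si]
    g <- gauss_smooth(gray, s)
    smoothed[[si]] <- g
    gr <- gradient_xy(g)
    # structure-tensor integration: iterated box blur approximating a
    # Gaussian of sigma = 1.5 * s (kernel shape is irrelevant here)
    br <- max(1L, as.integer(round(1.5 * s)))
    sxx <- cpp_box_blur(gr$gx * gr$gx, br, 3L)
    syy <- cpp_box_blur(gr$gy * gr$gy, br, 3L)
    sxy <- cpp_box_blur(gr$gx * gr$gy, br, 3L)
    resp <- (sxx * syy - sxy^2 - 0.04 * (sxx + syy)^2) * s^4
    mx <- max(resp)
    if (mx <= 0) next
    border <- as.integer(ceiling(3 * s)) + 1L
    if (2L * border >= min(dim(gray))) next
    pk <- cpp_local_maxima(resp, response_frac * mx, border)
    if (nrow(pk) == 0L) next
    all_kp <- rbind(all_kp, cbind(pk[, 1], pk[, 2], s, pk[, 3], si))
  }
  if (is.null(all_kp) || nrow(all_kp) == 0L) return(empty)
  ord <- order(-all_kp[, 4], all_kp[, 2], all_kp[, 1])
  all_kp <- all_kp[ord, , drop = FALSE]
  if (nrow(all_kp) > max_keypoints) {
    all_kp <- all_kp[seq_len(max_keypoints), , drop = FALSE]
  }
  descs <- matrix(0, nrow(all_kp), 128)
  oris <- numeric(nrow(all_kp))
  keep <- logical(nrow(all_kp))
  for (si in seq_along(scales)) {
    idx <- which(all_kp[, 5] == si)
    if (length(idx) == 0L) next
    dd <- cpp_describe_keypoints(smoothed[[si]],
                                 all_kp[idx, 1:3, drop = FALSE])
    # root-SIFT: L1-normalize then sqrt -> unit L2
    d <- dd$descriptors
    l1 <- rowSums(d)
    ok <- dd$keep & l1 > 0
    d[ok, ] <- sqrt(d[ok, , drop = FALSE] / l1[ok])
    descs[idx, ] <- d
    oris[idx] <- dd$orientations
    keep[idx] <- ok
  }
  structure(list(locations = all_kp[keep, 1:2, drop = FALSE],
                 scales = all_kp[keep, 3],
                 responses = all_kp[keep, 4],
                 orientations = oris[keep],
                 descriptors = descs[keep, , drop = FALSE],
                 source_id = src),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set %s: %d keypoints>\n", x$source_id,
              nrow(x$locations)))
  invisible(x)
}

#' Match descriptors between two keypoint sets
#'
#' Nearest-neighbour matching under Euclidean descriptor distance with the
#' Lowe ratio test: a base keypoint is matched to its nearest following
#' keypoint iff `best / second_best < ratio`. Each following keypoint is
#' used at most once (the closest claimant wins).
#'
#' @param base,following `keypoint_set` objects.
#' @param ratio Ratio-test threshold in (0, 1].
#' @return A list of class `match_set` with `pairs`: an n x 3 matrix of
#'   (base index, following index, descriptor distance); possibly 0 rows.
#' @export
match_descriptors <- function(base, following, ratio = 0.8) {
  stopifnot(inherits(base, "keypoint_set"),
            inherits(following, "keypoint_set"),
            ratio > 0, ratio <= 1)
  nb <- nrow(base$descriptors); nf <- nrow(following$descriptors)
  empty <- structure(list(pairs = matrix(numeric(0), 0, 3,
                                         dimnames = list(NULL, c("base", "following", "distance")))),
                     class = "match_set")
  if (nb == 0L || nf == 0L) return(empty)
  # unit vectors: d^2 = 2 - 2 <a, b>
  d2 <- 2 - 2 * tcrossprod(base$descriptors, following$descriptors)
  d2[d2 < 0] <- 0
  best_j <- max.col(-d2, ties.method = "first")
  best_d <- sqrt(d2[cbind(seq_len(nb), best_j)])
  if (nf >= 2) {
    d2[cbind(seq_len(nb), best_j)] <- Inf
    second_d <- sqrt(d2[cbind(seq_len(nb), max.col(-d2, ties.method = "first"))])
    pass <- second_d == 0 | best_d < ratio * second_d
  } else {
    pass <- rep(ratio >= 1, nb)   # no second neighbour to test against
  }
  sel <- cbind(which(pass), best_j[pass], best_d[pass])
  if (nrow(sel) > 1L) {
    # enforce injectivity on following indices: keep the closest claimant
    sel <- sel[order(sel[, 3]), , drop = FALSE]
    sel <- sel[!duplicated(sel[, 2]), , drop = FALSE]
    sel <- sel[order(sel[, 1]), , drop = FALSE]
  }
  colnames(sel) <- c("base", "following", "distance")
  structure(list(pairs = sel), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set: %d pairs>\n", nrow(x$pairs)))
  invisible(x)
}
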