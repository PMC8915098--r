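# Synthetic fundus frames and sequences with exact ground truth. The
# generator emulates what a smartphone ophthalmoscope records: a small
# bright circular retinal window on a near-black noisy surround, red-
# dominant tissue with radial falloff, a brighter optic-disc blob, dark
# vessel curves radiating from it, plus mild choroidal-like texture so the
# keypoint detector has something to latch onto. Sequences apply small
# similarity transforms (the low-motion regime of hand-held video of a
# steady eye) and per-frame illumination jitter — exactly the variation the
# set-wise normalization is designed to remove.

# evaluate code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fundus-like frame
#'
#' Deterministic for a given seed, with the retina circle known exactly.
#' The red-channel mean inside the circle exceeds the outside mean by at
#' least the stated contrast factor, which guarantees the classical
#' detection chain has signal.
#'
#' @param width,height Frame dimensions in pixels.
#' @param circle The retina window as a [circle()]; must fit inside the
#'   frame (radius below `min(width, height) / 2`).
#' @param n_vessels Number of vessel curves radiating from the optic disc.
#' @param seed Integer seed fixing all randomness.
#' @param bg_noise_sd Sensor-noise standard deviation on the dark surround.
#' @return A list of class `synthetic_scene`: `image` (8-bit RGB array),
#'   `circle`, `bbox` (the enclosing ground-truth square) and `seed`.
#' @export
make_fundus_frame <- function(width = 1920L, height = 1080L,
                              circle = NULL, n_vessels = 6L, seed = 1L,
                              bg_noise_sd = 3) {
  if (is.null(circle)) {
    circle <- circle(width / 2, height / 2, round(0.14 * min(width, height)))
  }
  stopifnot(width >= 32, height >= 32, inherits(circle, "circle"))
  if (circle$r >= min(width, height) / 2) {
    stop("retina radius must be below min(width, height) / 2")
  }
  if (circle$cx - circle$r < -0.1 * circle$r ||
      circle$cx + circle$r > width - 1 + 0.1 * circle$r ||
      circle$cy - circle$r < -0.1 * circle$r ||
      circle$cy + circle$r > height - 1 + 0.1 * circle$r) {
    stop("retina circle must lie (mostly) inside the frame")
  }
  img <- with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
    yg <- matrix(0:(h - 1), h, w)
    d <- sqrt((xg - circle$cx)^2 + (yg - circle$cy)^2)
    inside <- pmin(pmax((circle$r - d) / 2, 0), 1)  # soft 2-px rim
    falloff <- 1 - 0.45 * pmin(d / circle$r, 1)^2
    # choroidal-like texture: band-limited noise, ~6% multiplicative
    tex <- gauss_smooth(matrix(stats::rnorm(h * w), h, w), 2.5)
    tex <- tex / max(stats::sd(tex), 1e-9)
    shade <- falloff * (1 + 0.06 * tex)
    # optic disc: bright blob offset from the retina center
    od_ang <- stats::runif(1, 0, 2 * pi)
    od_r <- 0.35 * circle$r
    odx <- circle$cx + od_r * cos(od_ang)
    ody <- circle$cy + od_r * sin(od_ang)
    od_sig <- 0.18 * circle$r
    od <- exp(-((xg - odx)^2 + (yg - ody)^2) / (2 * od_sig^2))
    # vessels: random curved walks from the optic disc outward
    vmap <- matrix(0, h, w)
    if (n_vessels > 0) {
      for (v in seq_len(n_vessels)) {
        theta <- stats::runif(1, 0, 2 * pi)
        px <- odx; py <- ody
        step <- max(2, circle$r / 40)
        wid <- stats::runif(1, 1.5, 3.5)
        nsteps <- as.integer(ceiling(1.9 * circle$r / step))
        for (k in seq_len(nsteps)) {
          theta <- theta + stats::rnorm(1, 0, 0.15)
          px <- px + step * cos(theta)
          py <- py + step * sin(theta)
          dd <- sqrt((px - circle$cx)^2 + (py - circle$cy)^2)
          if (dd > 0.95 * circle$r) break
          ww <- max(1, wid * (1 - 0.5 * k / nsteps))
          xi <- as.integer(round(px)); yi <- as.integer(round(py))
          rad <- as.integer(ceiling(ww))
          xs <- max(0, xi - rad):min(w - 1, xi + rad)
          ys <- max(0, yi - rad):min(h - 1, yi + rad)
          if (length(xs) == 0 || length(ys) == 0) next
          sub <- outer((ys - py)^2, (xs - px)^2, `+`)
          vmap[ys + 1, xs + 1] <- pmax(vmap[ys + 1, xs + 1],
                                       pmin(pmax((ww - sqrt(sub)) / 1, 0), 1))
        }
      }
      vmap <- gauss_smooth(vmap, 0.8)
      vmap <- pmin(vmap / max(max(vmap), 1e-9), 1)
    }
    base_col <- c(195, 95, 45)          # red-dominant tissue
    od_col <- c(55, 75, 55)             # optic-disc brightening
    vess_att <- c(0.55, 0.70, 0.60)     # vessel darkening per channel
    out <- array(0, dim = c(h, w, 3L))
    for (c in 1:3) {
      tissue <- base_col[c] * shade + od_col[c] * od
      tissue <- tissue * (1 - vess_att[c] * vmap)
      bg <- 8 + stats::rnorm(h * w, 0, bg_noise_sd)
      out[, , c] <- inside * tissue + (1 - inside) * bg
    }
    quantize8(out)
  })
  structure(list(image = img, circle = circle,
                 bbox = circle_to_bbox(circle, width, height),
                 seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<synthetic_scene %dx%d, retina (%.0f, %.0f) r=%.0f, seed %d>\n",
              d[2], d[1], x$circle$cx, x$circle$cy, x$circle$r, x$seed))
  invisible(x)
}

#' Generate a synthetic video sequence with exact ground truth
#'
#' Frame 1 is the master scene itself; each later frame is the scene warped
#' by a random similarity transform (translation up to `max_shift`, rotation
#' up to `max_rot_deg` about the retina center, isotropic scale within
#' `1 +/- max_scale_dev`) and intensity-scaled by `1 +/- illum_jitter`.
#' Ground-truth boxes and homographies are recorded exactly.
#'
#' @param scene A `synthetic_scene` from [make_fundus_frame()].
#' @param n_frames Number of frames (>= 1).
#' @param max_shift Maximum |translation| per axis, pixels.
#' @param max_rot_deg Maximum |rotation|, degrees.
#' @param illum_jitter Relative illumination jitter amplitude in `[0, 1)`.
#' @param seed Integer seed.
#' @param max_scale_dev Maximum relative scale deviation.
#' @return A list of class `synthetic_sequence`: `frames` (list of
#'   [frame()]), `gt_boxes` (list of [bbox()]), `gt_homographies` (list of
#'   [homography()] mapping frame i coordinates to frame 1 coordinates;
#'   the first is the identity), `illum_factors` and `scene`.
#' @export
make_sequence <- function(scene, n_frames = 5L, max_shift = 30,
                          max_rot_deg = 5, illum_jitter = 0.1, seed = 1L,
                          max_scale_dev = 0.05) {
  stopifnot(inherits(scene, "synthetic_scene"), n_frames >= 1,
            max_shift >= 0, max_rot_deg >= 0, illum_jitter >= 0,
            illum_jitter < 1, max_scale_dev >= 0, max_scale_dev < 1)
  img <- scene$image
  h <- dim(img)[1]; w <- dim(img)[2]
  cc <- scene$circle
  r_worst <- cc$r * (1 + max_scale_dev)
  if (cc$cx - max_shift - r_worst < 0 || cc$cx + max_shift + r_worst > w - 1 ||
      cc$cy - max_shift - r_worst < 0 || cc$cy + max_shift + r_worst > h - 1) {
    stop("motion bounds can push the retina off-frame")
  }
  with_seed(seed, {
    frames <- vector("list", n_frames)
    gt_boxes <- vector("list", n_frames)
    gt_h <- vector("list", n_frames)
    illum <- numeric(n_frames)
    frames[[1]] <- frame(img, "synthetic", 0L)
    gt_boxes[[1]] <- scene$bbox
    gt_h[[1]] <- homography(diag(3))
    illum[1] <- 1
    if (n_frames >= 2) for (i in 2:n_frames) {
      tx <- stats::runif(1, -max_shift, max_shift)
      ty <- stats::runif(1, -max_shift, max_shift)
      th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
      s <- stats::runif(1, 1 - max_scale_dev, 1 + max_scale_dev)
      # scene coords -> frame-i coords: rotate/scale about the retina
      # center, then translate
      a <- s * cos(th); b <- s * sin(th)
      hm <- matrix(c(a, -b, cc$cx - a * cc$cx + b * cc$cy + tx,
                     b,  a, cc$cy - b * cc$cx - a * cc$cy + ty,
                     0,  0, 1),
                   3, 3, byrow = TRUE)
      wr <- warp_to_reference(img, homography(hm), w, h)
      illum[i] <- 1 + stats::runif(1, -illum_jitter, illum_jitter)
      frames[[i]] <- frame(quantize8(wr$pixels * illum[i]), "synthetic",
                           i - 1L)
      gt_h[[i]] <- homography(solve(hm))   # frame i -> frame 1 (scene)
      ci <- circle(cc$cx + tx, cc$cy + ty, s * cc$r)
      gt_boxes[[i]] <- circle_to_bbox(ci, w, h)
    }
    structure(list(frames = frames, gt_boxes = gt_boxes,
                   gt_homographies = gt_h, illum_factors = illum,
                   scene = scene),
              class = "synthetic_sequence")
  })
}

#' @export
print.synthetic_sequence <- function(x, ...) {
  cat(sprintf("<synthetic_sequence: %d frames>\n", length(x$frames)))
  invisible(x)
}
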