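test_that("detect_and_describe: empty on constant images, unit descriptors", {
  expect_identical(nrow(detect_and_describe(matrix(128, 60, 60))$locations), 0L)
  sc <- test_scene(seed = 41, w = 200, h = 200, r = 80)
  kp <- detect_and_describe(sc$image)
  expect_gt(nrow(kp$locations), 20)
  norms <- sqrt(rowSums(kp$descriptors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
})

test_that("descriptors are stable under a 90-degree rotation", {
  sc <- test_scene(seed = 42, w = 200, h = 200, r = 80)
  g <- (sc$image[, , 1] + sc$image[, , 2] + sc$image[, , 3]) / 3
  rot <- t(g)[, nrow(g):1]      # 90 deg counter-clockwise image rotation
  k1 <- detect_and_describe(g)
  k2 <- detect_and_describe(rot)
  m <- match_descriptors(k1, k2)
  expect_gt(nrow(m$pairs), 15)
  # rot[i, j] = g[h - j, i]: source pixel (x, y) lands at (H-1-y, x)
  p1 <- k1$locations[m$pairs[, 1], , drop = FALSE]
  p2 <- k2$locations[m$pairs[, 2], , drop = FALSE]
  pred <- cbind(nrow(g) - 1 - p1[, 2], p1[, 1])
  err <- sqrt(rowSums((pred - p2)^2))
  expect_gt(mean(err < 2), 0.8)
  expect_lt(median(m$pairs[, 3]), 0.5)
})

test_that("match_descriptors agrees with a brute-force all-pairs oracle", {
  mk <- function(d, id) {
    structure(list(locations = matrix(0, nrow(d), 2),
                   scales = rep(1, nrow(d)), responses = rep(1, nrow(d)),
                   orientations = rep(0, nrow(d)), descriptors = d,
                   source_id = id), class = "keypoint_set")
  }
  set.seed(43)
  d1 <- matrix(rnorm(5 * 128), 5); d1 <- d1 / sqrt(rowSums(d1^2))
  # following set: jittered copies (matchable) + decoys
  d2 <- d1 + matrix(rnorm(5 * 128, 0, 0.02), 5)
  d2 <- d2 / sqrt(rowSums(d2^2))
  m <- match_descriptors(mk(d1, "a"), mk(d2, "b"), ratio = 0.8)
  # oracle: exhaustive distance table + ratio test + injectivity
  dist <- as.matrix(stats::dist(rbind(d1, d2)))[1:5, 6:10]
  keep <- list()
  for (i in 1:5) {
    o <- order(dist[i, ])
    if (dist[i, o[1]] / dist[i, o[2]] < 0.8) keep[[length(keep) + 1]] <-
        c(i, o[1], dist[i, o[1]])
  }
  orc <- do.call(rbind, keep)
  orc <- orc[order(orc[, 3]), , drop = FALSE]
  orc <- orc[!duplicated(orc[, 2]), , drop = FALSE]
  orc <- orc[order(orc[, 1]), , drop = FALSE]
  expect_equal(unname(m$pairs), unname(orc), tolerance = 1e-12)
})

test_that("identical keypoint sets match one-to-one; random ones barely", {
  sc <- test_scene(seed = 44, w = 200, h = 200, r = 80)
  kp <- detect_and_describe(sc$image)
  m <- match_descriptors(kp, kp, ratio = 0.8)
  expect_identical(nrow(m$pairs), nrow(kp$locations))
  expect_true(all(m$pairs[, 1] == m$pairs[, 2]))
  expect_true(all(m$pairs[, 3] < 1e-6))
  # near-orthogonal random unit descriptors: the ratio test rejects almost all
  mk <- function(d, id) structure(list(locations = matrix(0, nrow(d), 2),
                                       scales = rep(1, nrow(d)),
                                       responses = rep(1, nrow(d)),
                                       orientations = rep(0, nrow(d)),
                                       descriptors = d, source_id = id),
                                  class = "keypoint_set")
  set.seed(45)
  r1 <- matrix(rnorm(40 * 128), 40); r1 <- r1 / sqrt(rowSums(r1^2))
  r2 <- matrix(rnorm(40 * 128), 40); r2 <- r2 / sqrt(rowSums(r2^2))
  expect_lt(nrow(match_descriptors(mk(r1, "a"), mk(r2, "b"))$pairs), 5)
})

test_that("estimate_homography recovers identity and known transforms", {
  sc <- test_scene(seed = 46, w = 300, h = 300, r = 120)
  kp <- detect_and_describe(sc$image)
  m <- match_descriptors(kp, kp)
  set.seed(1)
  h <- estimate_homography(m, kp, kp)
  expect_true(max(abs(unclass(h) - diag(3))) < 1e-3)
  # known warp: translation (12, 7) + rotation 3 degrees about the center
  th <- 3 * pi / 180; a <- cos(th); b <- sin(th); cx <- 150; cy <- 150
  hm <- matrix(c(a, -b, cx - a * cx + b * cy + 12,
                 b, a, cy - b * cx - a * cy + 7,
                 0, 0, 1), 3, 3, byrow = TRUE)
  wr <- warp_to_reference(sc$image, homography(hm), 300, 300)
  k2 <- detect_and_describe(wr$pixels)
  m2 <- match_descriptors(kp, k2)
  set.seed(2)
  h2 <- estimate_homography(m2, kp, k2)   # maps warped -> original
  corners <- rbind(c(0, 0), c(299, 0), c(0, 299), c(299, 299))
  err <- sqrt(rowSums((apply_homography(h2, corners) -
                       apply_homography(homography(solve(hm)), corners))^2))
  expect_lt(max(err), 1)
  # too few matches
  m3 <- structure(list(pairs = m$pairs[1:3, , drop = FALSE]),
                  class = "match_set")
  expect_error(estimate_homography(m3, kp, kp), "insufficient")
})

test_that("warp_to_reference behaves as identity, shift, and round trip", {
  sc <- test_scene(seed = 47, w = 160, h = 120, r = 50)
  img <- sc$image
  idw <- warp_to_reference(img, homography(diag(3)), 160, 120)
  expect_equal(idw$pixels, img, tolerance = 1e-9)
  expect_true(all(unclass(idw$mask) == 1L))
  # pure translation (+10, +5)
  tr <- homography(matrix(c(1, 0, 10, 0, 1, 5, 0, 0, 1), 3, 3, byrow = TRUE))
  sh <- warp_to_reference(img, tr, 160, 120)
  expect_equal(sh$pixels[6:120, 11:160, ], img[1:115, 1:150, ],
               tolerance = 1e-9)
  expect_identical(sum(unclass(sh$mask)), (160L - 10L) * (120L - 5L))
  # warp then inverse-warp returns the interior within interpolation noise
  th <- 2 * pi / 180
  hm <- matrix(c(cos(th), -sin(th), 4, sin(th), cos(th), -3, 0, 0, 1),
               3, 3, byrow = TRUE)
  fw <- warp_to_reference(img, homography(hm), 160, 120)
  bw <- warp_to_reference(fw$pixels, homography(solve(hm)), 160, 120)
  interior <- unclass(bw$mask) == 1L & unclass(fw$mask) == 1L
  interior[c(1:10, 111:120), ] <- FALSE
  interior[, c(1:10, 151:160)] <- FALSE
  for (c in 1:3) {
    expect_lt(mean(abs(bw$pixels[, , c] - img[, , c])[interior]), 2)
  }
})

test_that("blend weights reproduce the 1-D toy and the partition of unity", {
  m1 <- matrix(0L, 3, 10); m1[, 1:6] <- 1L    # columns x = 0..5
  m2 <- matrix(0L, 3, 10); m2[, 4:9] <- 1L    # columns x = 3..8
  f <- compute_blend_weights(binary_mask(m1), binary_mask(m2))
  # x = 4: nearest m1-outside-overlap is x = 2 (d1 = 2), m2's is x = 6
  expect_equal(f$w1[2, 5], 0.5)
  # x = 3: d1 = 1 (to x = 2), d2 = 3 (to x = 6) -> w1 = 3/4
  expect_equal(f$w1[2, 4], 0.75)
  expect_equal(f$w2[2, 4], 0.25)
  # m1-only and m2-only territory
  expect_equal(f$w1[2, 1], 1); expect_equal(f$w2[2, 1], 0)
  expect_equal(f$w2[2, 9], 1); expect_equal(f$w1[2, 9], 0)
  ov <- unclass(f$R) == 1L
  expect_lt(max(abs(f$w1[ov] + f$w2[ov] - 1)), 1e-6)
})

test_that("an image swallowed by the overlap falls back to 0.5 weights", {
  m1 <- matrix(1L, 6, 6)
  m2 <- matrix(1L, 6, 6)
  expect_warning(f <- compute_blend_weights(binary_mask(m1), binary_mask(m2)),
                 "0.5")
  expect_true(all(f$w1 == 0.5) && all(f$w2 == 0.5))
})

test_that("blend applies the weighted sum per channel", {
  m1 <- matrix(0L, 4, 8); m1[, 1:5] <- 1L
  m2 <- matrix(0L, 4, 8); m2[, 3:8] <- 1L
  f <- compute_blend_weights(binary_mask(m1), binary_mask(m2))
  i1 <- const_rgb(4, 8, c(200, 200, 200)); i2 <- const_rgb(4, 8, c(100, 100, 100))
  out <- blend(i1, i2, f)
  # same content everywhere both weights act on equal pixels
  same <- blend(i1, i1, f)
  expect_true(all(same[rep(unclass(f$m1) == 1L, 3)] == 200))
  # hand-check one overlap pixel: w1 = 0.75 -> 0.75*200 + 0.25*100 = 175
  px <- which(abs(f$w1 - 0.75) < 1e-9, arr.ind = TRUE)[1, ]
  expect_equal(out[px[1], px[2], 2], 175)
  # outside both masks the result is black
  outside <- unclass(f$m1) == 0L & unclass(f$m2) == 0L
  if (any(outside)) expect_true(all(out[, , 1][outside] == 0))
  expect_error(blend(i1, const_rgb(5, 8, c(0, 0, 0)), f), "shape")
})

test_that("seam crossing between constant images is monotone", {
  m1 <- matrix(0L, 5, 30); m1[, 1:20] <- 1L
  m2 <- matrix(0L, 5, 30); m2[, 11:30] <- 1L
  f <- compute_blend_weights(binary_mask(m1), binary_mask(m2))
  a <- const_rgb(5, 30, c(220, 220, 220)); b <- const_rgb(5, 30, c(60, 60, 60))
  out <- blend(a, b, f)
  profile <- out[3, , 1]
  expect_true(all(diff(profile[1:30]) <= 0))   # fades from a down to b
  expect_equal(profile[1], 220)
  expect_equal(profile[30], 60)
})

test_that("mosaicing the same image twice reproduces it", {
  sc <- test_scene(seed = 48, w = 200, h = 200, r = 80)
  set.seed(3)
  suppressWarnings(mo <- mosaic_sequence(list(sc$image, sc$image)))
  expect_identical(dim(mo$canvas), dim(sc$image))
  expect_lt(mean(abs(mo$canvas - sc$image)), 1)
  expect_true(max(abs(unclass(mo$homographies[[2]]) - diag(3))) < 1e-2)
})

test_that("a 3-crop mosaic reprojects master landmarks within 2 px", {
  sc <- test_scene(seed = 49)
  sq <- make_sequence(sc, 3, max_shift = 25, max_rot_deg = 4,
                      illum_jitter = 0.1, seed = 50)
  nr <- normalize_set(lapply(sq$frames, `[[`, "pixels"))
  set.seed(4)
  mo <- mosaic_sequence(nr$images)
  expect_length(mo$skipped, 0)
  set.seed(5)
  ang <- runif(25, 0, 2 * pi); rad <- sqrt(runif(25)) * 140
  lm <- cbind(200 + rad * cos(ang), 200 + rad * sin(ang))
  for (i in 2:3) {
    p_i <- apply_homography(homography(solve(unclass(sq$gt_homographies[[i]]))),
                            lm)
    est <- apply_homography(mo$homographies[[i]], p_i)
    expect_lt(max(sqrt(rowSums((est - lm)^2))), 2)
  }
  expect_gt(sum(unclass(mo$valid_mask)), 400 * 400)
})

test_that("an unregisterable frame is skipped without changing the result", {
  sc <- test_scene(seed = 51, w = 250, h = 250, r = 100)
  sq <- make_sequence(sc, 2, max_shift = 15, max_rot_deg = 3,
                      illum_jitter = 0, seed = 52)
  black <- const_rgb(250, 250, c(0, 0, 0))
  set.seed(6)
  expect_warning(
    with_black <- mosaic_sequence(list(sq$frames[[1]]$pixels, black,
                                       sq$frames[[2]]$pixels)),
    "skipped")
  set.seed(6)
  without <- mosaic_sequence(list(sq$frames[[1]]$pixels,
                                  sq$frames[[2]]$pixels))
  expect_identical(with_black$skipped, 2L)
  expect_identical(with_black$canvas, without$canvas)
})

test_that("homography recovery holds across the small-motion regime", {
  # property sweep kept small here; the acceptance suite runs the full study
  errs <- vapply(1:8, function(s) {
    sc <- test_scene(seed = 60 + s)
    sq <- make_sequence(sc, 2, max_shift = 30, max_rot_deg = 5,
                        illum_jitter = 0, seed = 160 + s)
    k1 <- detect_and_describe(sq$frames[[1]])
    k2 <- detect_and_describe(sq$frames[[2]])
    set.seed(260 + s)
    h <- estimate_homography(match_descriptors(k1, k2), k1, k2)
    corners <- rbind(c(0, 0), c(399, 0), c(0, 399), c(399, 399))
    max(sqrt(rowSums((apply_homography(h, corners) -
                      apply_homography(sq$gt_homographies[[2]], corners))^2)))
  }, numeric(1))
  expect_gt(mean(errs < 1), 0.85)
})
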