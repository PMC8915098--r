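test_that("generation is bit-identical under a fixed seed", {
  a <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 81)
  b <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 81)
  expect_identical(a$image, b$image)
  c <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 82)
  expect_false(identical(a$image, c$image))
})

test_that("the retina window carries the required red-channel contrast", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 83)
  xg <- matrix(0:319, 240, 320, byrow = TRUE); yg <- matrix(0:239, 240, 320)
  inside <- sqrt((xg - 160)^2 + (yg - 120)^2) < 60
  expect_gt(mean(sc$image[, , 1][inside]),
            2 * mean(sc$image[, , 1][!inside]))
})

test_that("vessels add interior texture; none are drawn with n_vessels = 0", {
  with_v <- make_fundus_frame(320, 240, circle(160, 120, 70), 6, seed = 84)
  without <- make_fundus_frame(320, 240, circle(160, 120, 70), 0, seed = 84)
  xg <- matrix(0:319, 240, 320, byrow = TRUE); yg <- matrix(0:239, 240, 320)
  core <- sqrt((xg - 160)^2 + (yg - 120)^2) < 55
  expect_gt(var(with_v$image[, , 1][core]), var(without$image[, , 1][core]))
})

test_that("scene geometry is validated", {
  expect_error(make_fundus_frame(100, 100, circle(50, 50, 50), 3, seed = 1),
               "radius")
  expect_error(make_fundus_frame(200, 200, circle(10, 10, 60), 3, seed = 1),
               "inside")
})

test_that("a single-frame sequence is the scene itself", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 85)
  sq <- make_sequence(sc, 1, seed = 86)
  expect_identical(sq$frames[[1]]$pixels, sc$image)
  expect_equal(unclass(sq$gt_homographies[[1]]), diag(3))
  expect_identical(unclass(sq$gt_boxes[[1]]), unclass(sc$bbox))
})

test_that("motion bounds that could push the retina off-frame are rejected", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 100), 4, seed = 87)
  expect_error(make_sequence(sc, 3, max_shift = 40, seed = 88), "off-frame")
})

test_that("illumination jitter shows up in means and Eq-style removal works", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 89)
  sq <- make_sequence(sc, 5, max_shift = 15, max_rot_deg = 3,
                      illum_jitter = 0.2, seed = 90)
  means <- vapply(sq$frames, function(f) mean(f$pixels), numeric(1))
  expect_gt(max(means) - min(means), 0.5)
  norm <- normalize_set(lapply(sq$frames, `[[`, "pixels"), round = FALSE)
  nmeans <- vapply(norm$images, mean, numeric(1))
  expect_equal(nmeans, rep(norm$context$min_mean, 5), tolerance = 1e-12)
})

test_that("ground-truth homographies round-trip the warped frames", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 70), 5, seed = 91)
  sq <- make_sequence(sc, 3, max_shift = 10, max_rot_deg = 3,
                      illum_jitter = 0, seed = 92)
  for (i in 2:3) {
    # gt homography maps frame-i coords to frame-1 coords, so warping
    # frame i with it should re-create frame 1 where both are defined
    back <- warp_to_reference(sq$frames[[i]]$pixels, sq$gt_homographies[[i]],
                              320, 240)
    xg <- matrix(0:319, 240, 320, byrow = TRUE); yg <- matrix(0:239, 240, 320)
    core <- sqrt((xg - 160)^2 + (yg - 120)^2) < 50 & unclass(back$mask) == 1L
    diff <- abs(back$pixels[, , 1] - sc$image[, , 1])
    expect_lt(mean(diff[core]), 4)   # interpolation noise only
  }
})

test_that("sequences are deterministic and their boxes track the motion", {
  sc <- make_fundus_frame(320, 240, circle(160, 120, 60), 5, seed = 93)
  s1 <- make_sequence(sc, 4, seed = 94, max_shift = 15)
  s2 <- make_sequence(sc, 4, seed = 94, max_shift = 15)
  for (i in 1:4) expect_identical(s1$frames[[i]]$pixels, s2$frames[[i]]$pixels)
  # detected ground-truth boxes move with the stated translations
  expect_false(identical(unclass(s1$gt_boxes[[1]]), unclass(s1$gt_boxes[[2]])))
})
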