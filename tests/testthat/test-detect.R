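test_that("extract_red_channel returns exactly the R plane", {
  expect_true(all(extract_red_channel(const_rgb(4, 4, c(255, 0, 0))) == 255))
  expect_true(all(extract_red_channel(const_rgb(4, 4, c(0, 0, 255))) == 0))
  img <- random_rgb(6, 5, seed = 7)
  red <- extract_red_channel(img)
  for (y in 1:6) for (x in 1:5) expect_identical(red[y, x], img[y, x, 1])
  expect_error(extract_red_channel(matrix(0, 4, 4)), "h x w x 3")
})

test_that("blur is Gaussian with identity and fixed-point cases", {
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_identical(blur(img, 1L), img)
  expect_true(all(abs(blur(matrix(40, 9, 9), 5L) - 40) < 1e-9))
  expect_error(blur(img, 4L), "odd")
  # impulse response equals the separable Gaussian kernel (independent calc)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1000
  out <- blur(imp, 5L)
  sigma <- 0.3 * ((5 - 1) * 0.5 - 1) + 0.8
  k <- exp(-0.5 * ((-2:2) / sigma)^2); k <- k / sum(k)
  expect_equal(out[9:13, 9:13], outer(k, k) * 1000, tolerance = 1e-9)
  expect_equal(sum(out), 1000, tolerance = 1e-9)      # mass conserved
  expect_equal(which.max(out), which.max(imp))        # peak stays put
})

test_that("otsu_threshold separates a bimodal image and matches the oracle", {
  img <- matrix(10, 8, 8); img[, 5:8] <- 200
  res <- otsu_threshold(img)
  expect_true(res$threshold > 10 && res$threshold < 200)
  expect_identical(unclass(res$mask)[, , drop = FALSE],
                   matrix(as.integer(img > res$threshold), 8, 8))
  # 16-pixel toy histogram vs exhaustive scan
  toy <- matrix(c(3, 3, 7, 9, 12, 15, 18, 20, 150, 152, 160, 170,
                  180, 190, 200, 210), 4, 4)
  got <- otsu_threshold(toy)
  orc <- otsu_oracle(as.integer(toy))
  expect_true(round(got$threshold) %in%
                seq(min(orc$thresholds), max(orc$thresholds)))
  # our variance at the chosen threshold attains the oracle maximum
  n0 <- sum(toy <= got$threshold); n1 <- 16 - n0
  mu0 <- mean(toy[toy <= got$threshold]); mu1 <- mean(toy[toy > got$threshold])
  expect_equal((n0 / 16) * (n1 / 16) * (mu0 - mu1)^2, orc$variance,
               tolerance = 1e-9)
  # inversion symmetry, away from the two thresholds
  inv <- 255 - toy
  got_inv <- otsu_threshold(inv)
  off <- toy != round(got$threshold) & inv != round(got_inv$threshold)
  expect_identical(unclass(got$mask)[off], 1L - unclass(got_inv$mask)[off])
  expect_error(otsu_threshold(matrix(42, 4, 4)), "degenerate")
})

test_that("contour_image marks exactly the component boundaries", {
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L    # filled 10x10 square
  ci <- contour_image(binary_mask(m))
  boundary <- ci == 0
  expect_identical(sum(boundary), 36L)            # 4*10 - 4 perimeter pixels
  interior <- matrix(FALSE, 20, 20); interior[7:14, 7:14] <- TRUE
  expect_true(all(ci[interior] == 255))
  expect_true(all(contour_image(binary_mask(matrix(0L, 5, 5))) == 255))
  # filled disc: boundary pixel count close to the 2*pi*r perimeter
  xg <- matrix(0:59, 60, 60, byrow = TRUE); yg <- matrix(0:59, 60, 60)
  disc <- binary_mask((sqrt((xg - 30)^2 + (yg - 30)^2) <= 20) + 0L)
  nb <- sum(contour_image(disc) == 0)
  expect_true(abs(nb - 2 * pi * 20) < 0.25 * 2 * pi * 20)
})

test_that("hough_circle recovers rasterized circles within 2 px", {
  ring <- rasterize_ring(100, 80, 40, 200, 200)
  found <- hough_circle(binary_mask(ring + 0L))
  expect_gt(length(found), 0)
  top <- found[[1]]
  expect_lt(abs(top$cx - 100), 2.01)
  expect_lt(abs(top$cy - 80), 2.01)
  expect_lt(abs(top$r - 40), 2.01)
  # blank edge image yields an empty candidate list
  expect_length(hough_circle(binary_mask(matrix(0L, 50, 50))), 0)
  # radius window filtering: cap at 0.2 * 200 = 40 px keeps only r = 30
  two <- rasterize_ring(100, 100, 30, 200, 200) |
    rasterize_ring(100, 100, 60, 200, 200)
  found2 <- hough_circle(binary_mask(two + 0L),
                         cht_params(max_radius_frac = 0.2))
  expect_gt(length(found2), 0)
  for (c in found2) expect_lt(abs(c$r - 30), 3)
})

test_that("circle_to_bbox rounds, clips, and contains the disc", {
  expect_identical(unclass(circle_to_bbox(circle(100, 100, 50), 400, 400)),
                   unclass(bbox(50, 50, 150, 150)))
  expect_identical(unclass(circle_to_bbox(circle(10, 10, 50), 400, 400)),
                   unclass(bbox(0, 0, 60, 60)))
  b <- circle_to_bbox(circle(200, 200, 50), 400, 400)
  xg <- matrix(0:399, 400, 400, byrow = TRUE); yg <- matrix(0:399, 400, 400)
  disc <- which(sqrt((xg - 200)^2 + (yg - 200)^2) < 50, arr.ind = TRUE)
  expect_true(all(disc[, 2] - 1 >= b[["x_min"]] & disc[, 2] - 1 < b[["x_max"]]))
  expect_true(all(disc[, 1] - 1 >= b[["y_min"]] & disc[, 1] - 1 < b[["y_max"]]))
  expect_error(circle_to_bbox(circle(-100, -100, 20), 50, 50), "outside")
})

test_that("detect_retina recovers the synthetic retina and is deterministic", {
  sc <- test_scene(seed = 21, w = 640, h = 480, r = 90)
  d1 <- detect_retina(sc$image)
  expect_false(is.null(d1$bbox))
  expect_gt(iou(d1$bbox, sc$bbox), 0.8)
  d2 <- detect_retina(sc$image)
  expect_identical(d1, d2)
  # bbox lies within image bounds
  expect_true(d1$bbox[["x_max"]] <= 640 && d1$bbox[["y_max"]] <= 480)
})

test_that("detection tolerates uniform intensity rescaling (Otsu adapts)", {
  sc <- test_scene(seed = 22, w = 640, h = 480, r = 90)
  for (f in c(0.8, 1.2)) {
    scaled <- pmin(sc$image * f, 255)
    d <- detect_retina(scaled)
    expect_false(is.null(d$bbox))
    expect_gt(iou(d$bbox, sc$bbox), 0.6)
  }
})

test_that("an all-black frame yields a clean no-detection result", {
  d <- detect_retina(const_rgb(120, 160, c(0, 0, 0)))
  expect_null(d$circle)
  expect_null(d$bbox)
  expect_identical(d$diagnostics$n_candidates, 0L)
})

test_that("derive_yolo_config reproduces the closed-form rules", {
  one <- derive_yolo_config(1)
  expect_identical(one$max_batches, 6000L)
  expect_identical(one$steps, c(4800L, 5400L))
  expect_identical(one$filters, 18L)
  three <- derive_yolo_config(3)
  expect_identical(three$max_batches, 6000L)   # the 6000 floor binds
  expect_identical(three$filters, 24L)
  four <- derive_yolo_config(4)
  expect_identical(four$max_batches, 8000L)
  expect_identical(four$steps, c(6400L, 7200L))
  expect_identical(four$filters, 27L)
  for (k in 1:100) {
    cfg <- derive_yolo_config(k)
    expect_identical(cfg$max_batches, max(2000L * k, 6000L))
    expect_identical(cfg$steps,
                     as.integer(round(c(0.8, 0.9) * cfg$max_batches)))
    expect_identical(cfg$filters, (k + 5L) * 3L)
  }
  expect_error(derive_yolo_config(0), "positive")
})
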