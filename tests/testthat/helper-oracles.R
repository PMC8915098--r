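# Independent oracles and tiny fixture builders used across the suite.

# pixel-set rasterization of a half-open box on a w x h grid
rasterize_box <- function(b, w, h) {
  m <- matrix(FALSE, h, w)
  m[(b[["y_min"]] + 1):b[["y_max"]], (b[["x_min"]] + 1):b[["x_max"]]] <- TRUE
  m
}

# thin circle ring (edge pixels) on a w x h grid, 0-based center coords
rasterize_ring <- function(cx, cy, r, w, h, tol = 0.6) {
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1), h, w)
  abs(sqrt((xg - cx)^2 + (yg - cy)^2) - r) < tol
}

# exhaustive-scan Otsu oracle over a 256-bin histogram: returns the set of
# thresholds attaining the maximum between-class variance
otsu_oracle <- function(values) {
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  n <- sum(counts)
  best_v <- -Inf
  best_t <- integer(0)
  for (t in 0:254) {
    n0 <- sum(counts[1:(t + 1)])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / n0
    mu1 <- sum((t + 1):255 * counts[(t + 2):256]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
    else if (v > best_v - 1e-12) best_t <- c(best_t, t)
  }
  list(thresholds = best_t, variance = best_v)
}

# constant-color RGB array
const_rgb <- function(h, w, rgb = c(0, 0, 0)) {
  a <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) a[, , c] <- rgb[c]
  a
}

# seeded random 8-bit RGB array
random_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)),
        dim = c(h, w, 3L))
}

# random valid bbox on a w x h grid
random_bbox <- function(w, h) {
  x <- sort(sample(0:w, 2))
  y <- sort(sample(0:h, 2))
  while (x[1] == x[2]) x <- sort(sample(0:w, 2))
  while (y[1] == y[2]) y <- sort(sample(0:h, 2))
  bbox(x[1], y[1], x[2], y[2])
}

# small standard test scene (kept modest so the suite stays fast)
test_scene <- function(seed = 1, w = 400L, h = 400L, r = 160) {
  make_fundus_frame(w, h, circle(w / 2, h / 2, r), 6, seed = seed)
}
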