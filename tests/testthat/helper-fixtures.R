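# Small fixtures built in code.

# A constant-color MSX image.
const_image <- function(h, w, rgb) {
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

# Random binary mask at a given foreground probability.
random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Mask with a filled Euclidean disk.
disk_mask <- function(h, w, cy, cx, radius) {
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  (d2 <= radius^2) * 1L
}

# Stamp axis-aligned rectangles of 1s onto a mask.
stamp_rects <- function(h, w, n, seed) {
  set.seed(seed)
  mask <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    r0 <- sample(h - 4, 1); c0 <- sample(w - 4, 1)
    r1 <- min(h, r0 + sample(2:10, 1)); c1 <- min(w, c0 + sample(2:10, 1))
    mask[r0:r1, c0:c1] <- 1L
  }
  mask
}

# A quick separable 2-class feature set (two Gaussian blobs).
separable_blobs <- function(n_per_class, dist = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(
    cbind(stats::rnorm(n_per_class), stats::rnorm(n_per_class)),
    cbind(stats::rnorm(n_per_class) + dist, stats::rnorm(n_per_class) + dist)
  )
  colnames(x) <- c("contrast", "entropy")
  list(x = x, y = rep(c(-1L, 1L), each = n_per_class))
}

# Default-config scene with a fixed seed.
quick_scene <- function(seed, ...) {
  cfg <- synth_config(seed = seed, ...)
  generate_scene(cfg)
}
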