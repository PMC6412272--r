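# Independent brute-force oracles. These deliberately use naive loops and
# direct definitions, not the package's vectorized implementations.

# Otsu: exhaustive between-class variance over all 256 candidate thresholds,
# computed from the raw pixel vector (class membership v > t).
oracle_otsu <- function(gray) {
  v <- as.vector(gray)
  n <- length(v)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:255) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / n; w1 <- length(c1) / n
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Connected labeling by explicit flood fill, seeds visited in row-major order.
oracle_flood_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                    c(1, -1), c(1, 0), c(1, 1))
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 1 && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in offs) {
          rr <- p[1] + o[1]; cc <- p[2] + o[2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Brute-force binary erosion/dilation with a Euclidean disk, outside of the
# image treated as background.
oracle_disk_offsets <- function(radius) {
  r <- floor(radius)
  offs <- list()
  for (dr in -r:r) for (dc in -r:r)
    if (dr * dr + dc * dc <= radius^2) offs[[length(offs) + 1L]] <- c(dr, dc)
  offs
}

oracle_erode <- function(mask, radius) {
  offs <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ok <- TRUE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      inside <- rr >= 1 && rr <= h && cc >= 1 && cc <= w
      if (!inside || mask[rr, cc] != 1) { ok <- FALSE; break }
    }
    if (ok) out[r, c] <- 1L
  }
  out
}

oracle_dilate <- function(mask, radius) {
  offs <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] == 1) {
        hit <- TRUE; break
      }
    }
    if (hit) out[r, c] <- 1L
  }
  out
}

oracle_open <- function(mask, radius) oracle_dilate(oracle_erode(mask, radius), radius)

# GLCM by double-loop pair enumeration (symmetrized, normalized).
oracle_glcm_matrix <- function(q, offset, levels) {
  h <- nrow(q); w <- ncol(q)
  m <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + offset[1]; cc <- c + offset[2]
    if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
      a <- q[r, c]; b <- q[rr, cc]
      m[a + 1, b + 1] <- m[a + 1, b + 1] + 1
      m[b + 1, a + 1] <- m[b + 1, a + 1] + 1
    }
  }
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

oracle_glcm_features <- function(p, base = 2) {
  L <- nrow(p)
  contrast <- 0; entropy <- 0
  for (a in 1:L) for (b in 1:L) {
    contrast <- contrast + (a - b)^2 * p[a, b]
    if (p[a, b] > 0) entropy <- entropy - p[a, b] * log(p[a, b]) / log(base)
  }
  lev <- 0:(L - 1)
  pr <- rowSums(p); pc <- colSums(p)
  mu_r <- sum(lev * pr); mu_c <- sum(lev * pc)
  sd_r <- sqrt(sum((lev - mu_r)^2 * pr)); sd_c <- sqrt(sum((lev - mu_c)^2 * pc))
  correlation <- if (sd_r < 1e-12 || sd_c < 1e-12) 0 else {
    s <- 0
    for (a in 1:L) for (b in 1:L)
      s <- s + (lev[a] - mu_r) * (lev[b] - mu_c) * p[a, b]
    s / (sd_r * sd_c)
  }
  list(contrast = contrast, entropy = entropy, correlation = correlation)
}

# Overlap counts by per-pixel tally.
oracle_counts <- function(pred, manual) {
  s <- c(s_ic = 0L, s_il = 0L, s_oc = 0L, s_oo = 0L)
  for (i in seq_along(pred)) {
    p <- pred[i] == 1; m <- manual[i] == 1
    if (p && m) s["s_ic"] <- s["s_ic"] + 1L
    else if (!p && m) s["s_il"] <- s["s_il"] + 1L
    else if (p && !m) s["s_oo"] <- s["s_oo"] + 1L
    else s["s_oc"] <- s["s_oc"] + 1L
  }
  as.list(s)
}
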