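#' Crop a region to its minimum bounding rectangle
#'
#' Extracts one labeled connected region as a patch: the red component of
#' the restored pseudo-color image, cropped to the minimal axis-aligned
#' rectangle containing the region, with pixels outside the region set
#' to 0. Keeping the rectangle minimal keeps constant (zero) areas as small
#' as possible before texture computation.
#'
#' Bounding boxes are half-open `[r0, r1) x [c0, c1)`, 0-based, origin
#' top-left.
#'
#' @param labels H x W label map.
#' @param restored H x W x 3 restored pseudo-color image.
#' @param region_id label of the region to crop (1..n_regions).
#' @return an object of class `msx_patch` with elements `region_id`, `bbox`
#'   (r0, c0, r1, c1), `gray` (cropped matrix, zero outside the region),
#'   `mask` (cropped region mask) and `area` (pixels).
#' @export
crop_region_patch <- function(labels, restored, region_id) {
  validate_label_map(labels)
  validate_msx_image(restored)
  stopifnot_same_shape(labels, restored, "labels and restored image")
  if (length(region_id) != 1 || !region_id %in% seq_len(n_regions(labels)))
    msx_stop_validation("unknown region_id: ", region_id)
  sel <- labels == region_id
  rows <- which(rowSums(sel) > 0)
  cols <- which(colSums(sel) > 0)
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  mask <- (sel[r0:r1, c0:c1, drop = FALSE]) * 1L
  gray <- restored[r0:r1, c0:c1, 1L, drop = TRUE]
  gray <- matrix(gray, nrow(mask), ncol(mask)) * mask
  structure(
    list(region_id = as.integer(region_id),
         bbox = c(r0 = r0 - 1L, c0 = c0 - 1L, r1 = r1, c1 = c1),
         gray = gray, mask = mask, area = sum(mask)),
    class = "msx_patch"
  )
}

#' Quantize 8-bit gray values to L levels
#'
#' Uniform binning of \[0, 255\] into `levels` equal-width bins:
#' `q = floor(v * levels / 256)`.
#'
#' @param gray integer matrix (or vector) of values in \[0, 255\].
#' @param levels number of gray levels L >= 2.
#' @return integer data with values in {0, ..., L-1}, same shape as input.
#' @export
quantize_gray <- function(gray, levels = 16) {
  if (levels < 2) msx_stop_validation("levels must be >= 2")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    msx_stop_validation("gray values must be in [0, 255]")
  q <- floor(gray * levels / 256)
  if (is.matrix(gray)) matrix(as.integer(q), nrow(gray), ncol(gray))
  else as.integer(q)
}

# Angle-to-offset map at distance d (rows increase downward):
# 0 -> (0, d); 45 -> (-d, d); 90 -> (-d, 0); 135 -> (-d, -d).
angle_offset <- function(angle, distance) {
  d <- as.integer(distance)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         msx_stop_validation("unsupported GLCM angle: ", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized levels at a fixed pixel offset over a
#' patch rectangle, symmetrizes (both orderings counted) and normalizes to
#' sum 1. If no pixel pair fits inside the patch the GLCM is degenerate and
#' returned as the uniform distribution with `degenerate = TRUE`.
#'
#' @param qpatch integer matrix of quantized levels in {0, ..., L-1}.
#' @param offset integer (dr, dc) displacement.
#' @param levels number of gray levels L.
#' @param mask optional region mask; when supplied, pairs with either
#'   endpoint outside the region are excluded.
#' @return an object of class `msx_glcm`: list with `matrix` (L x L,
#'   sums to 1), `levels`, `offset`, `normalized`, `n_pairs`, `degenerate`.
#' @export
glcm <- function(qpatch, offset, levels, mask = NULL) {
  if (!is.matrix(qpatch)) msx_stop_validation("qpatch must be a matrix")
  if (max(abs(offset)) < 1) msx_stop_validation("offset magnitude must be >= 1")
  if (anyNA(qpatch) || min(qpatch) < 0 || max(qpatch) >= levels)
    msx_stop_validation("quantized values must be in {0, ..., levels-1}")
  h <- nrow(qpatch); w <- ncol(qpatch)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  rows <- seq_len(h); rows <- rows[rows + dr >= 1L & rows + dr <= h]
  cols <- seq_len(w); cols <- cols[cols + dc >= 1L & cols + dc <= w]
  if (length(rows) == 0L || length(cols) == 0L) {
    return(structure(list(
      matrix = matrix(1 / levels^2, levels, levels), levels = levels,
      offset = c(dr, dc), normalized = TRUE, n_pairs = 0L, degenerate = TRUE),
      class = "msx_glcm"))
  }
  a <- qpatch[rows, cols, drop = FALSE]
  b <- qpatch[rows + dr, cols + dc, drop = FALSE]
  if (!is.null(mask)) {
    ok <- mask[rows, cols, drop = FALSE] > 0 & mask[rows + dr, cols + dc, drop = FALSE] > 0
    a <- a[ok]; b <- b[ok]
    if (length(a) == 0L) {
      return(structure(list(
        matrix = matrix(1 / levels^2, levels, levels), levels = levels,
        offset = c(dr, dc), normalized = TRUE, n_pairs = 0L, degenerate = TRUE),
        class = "msx_glcm"))
    }
  }
  counts <- matrix(tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                            nbins = levels * levels), levels, levels)
  counts <- counts + t(counts)                 # symmetrize: both orderings
  structure(list(
    matrix = counts / sum(counts), levels = levels, offset = c(dr, dc),
    normalized = TRUE, n_pairs = as.integer(sum(counts) / 2L),
    degenerate = FALSE), class = "msx_glcm")
}

check_normalized_glcm <- function(g) {
  if (!inherits(g, "msx_glcm") || !isTRUE(g$normalized) ||
      abs(sum(g$matrix) - 1) > 1e-9)
    msx_stop_validation("input must be a normalized GLCM")
  invisible(g)
}

#' GLCM contrast
#'
#' Moment of squared level difference, `sum((a - b)^2 p(a, b))`: the depth
#' of the texture "groove" — rough surfaces score high.
#'
#' @param g a normalized `msx_glcm`.
#' @return non-negative scalar.
#' @export
glcm_contrast <- function(g) {
  check_normalized_glcm(g)
  L <- g$levels
  lev <- 0:(L - 1)
  diff2 <- outer(lev, lev, function(a, b) (a - b)^2)
  sum(diff2 * g$matrix)
}

#' GLCM entropy
#'
#' Shannon entropy of the co-occurrence distribution over its nonzero
#' entries; measures heterogeneity of the level-pair distribution.
#'
#' @param g a normalized `msx_glcm`.
#' @param base logarithm base (2 for bits, exp(1) for nats).
#' @return non-negative scalar.
#' @export
glcm_entropy <- function(g, base = 2) {
  check_normalized_glcm(g)
  p <- g$matrix[g$matrix > 0]
  -sum(p * log(p)) / log(base)
}

#' GLCM correlation
#'
#' Normalized covariance of the two marginal level distributions,
#' `sum((a - mu_r)(b - mu_c) p(a, b)) / (sd_r sd_c)`, in \[-1, 1\]. When a
#' marginal has zero variance the correlation is defined as 0.
#'
#' @param g a normalized `msx_glcm`.
#' @return scalar in \[-1, 1\].
#' @export
glcm_correlation <- function(g) {
  check_normalized_glcm(g)
  L <- g$levels
  lev <- 0:(L - 1)
  pr <- rowSums(g$matrix)
  pc <- colSums(g$matrix)
  mu_r <- sum(lev * pr); mu_c <- sum(lev * pc)
  sd_r <- sqrt(sum((lev - mu_r)^2 * pr))
  sd_c <- sqrt(sum((lev - mu_c)^2 * pc))
  if (sd_r < 1e-12 || sd_c < 1e-12) return(0)
  cov <- sum(outer(lev - mu_r, lev - mu_c) * g$matrix)
  max(-1, min(1, cov / (sd_r * sd_c)))
}

#' Direction-averaged texture features for one region
#'
#' Quantizes the patch, builds a GLCM at the configured step for each
#' configured angle, computes contrast, entropy and correlation per
#' direction, and returns their arithmetic means together with the
#' per-direction values. A patch with no valid pixel pair in any direction
#' is flagged degenerate with all features 0.
#'
#' @param patch an `msx_patch` from [crop_region_patch()].
#' @param cfg an [msx_config()] object.
#' @return an object of class `msx_features`: list with `region_id`,
#'   `contrast`, `entropy`, `correlation`, `per_direction` (data.frame with
#'   one row per angle) and `degenerate`.
#' @export
region_features <- function(patch, cfg = msx_config()) {
  if (!inherits(patch, "msx_patch")) msx_stop_validation("patch must be an msx_patch")
  validate_config(cfg)
  q <- quantize_gray(patch$gray, cfg$glcm_levels)
  mask <- if (isTRUE(cfg$glcm_masked)) patch$mask else NULL
  per <- lapply(cfg$glcm_angles, function(ang) {
    g <- glcm(q, angle_offset(ang, cfg$glcm_distance), cfg$glcm_levels, mask)
    if (g$degenerate)
      data.frame(angle = ang, contrast = 0, entropy = 0, correlation = 0,
                 degenerate = TRUE)
    else
      data.frame(angle = ang,
                 contrast = glcm_contrast(g),
                 entropy = glcm_entropy(g, cfg$entropy_log_base),
                 correlation = glcm_correlation(g),
                 degenerate = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(
    region_id = patch$region_id,
    contrast = mean(per$contrast),
    entropy = mean(per$entropy),
    correlation = mean(per$correlation),
    per_direction = per,
    degenerate = all(per$degenerate)), class = "msx_features")
}

#' Texture feature table for all regions of a pre-processed image
#'
#' @param pre an `msx_preprocess` result (or a list with `labels` and
#'   `restored`).
#' @param cfg an [msx_config()] object.
#' @return data.frame with one row per region: `region_id`, bounding box
#'   (`r0`, `c0`, `r1`, `c1`), `area`, averaged `contrast`, `entropy`,
#'   `correlation`, per-direction columns (e.g. `contrast_0`,
#'   `contrast_45`, ...) and `degenerate`.
#' @export
extract_features <- function(pre, cfg = msx_config()) {
  labels <- pre$labels
  restored <- pre$restored
  n <- n_regions(labels)
  rows <- lapply(seq_len(n), function(i) {
    patch <- crop_region_patch(labels, restored, i)
    f <- region_features(patch, cfg)
    per <- f$per_direction
    wide <- c(
      stats::setNames(per$contrast, paste0("contrast_", per$angle)),
      stats::setNames(per$entropy, paste0("entropy_", per$angle)),
      stats::setNames(per$correlation, paste0("correlation_", per$angle))
    )
    cbind(
      data.frame(region_id = patch$region_id,
                 r0 = patch$bbox[["r0"]], c0 = patch$bbox[["c0"]],
                 r1 = patch$bbox[["r1"]], c1 = patch$bbox[["c1"]],
                 area = patch$area,
                 contrast = f$contrast, entropy = f$entropy,
                 correlation = f$correlation),
      as.data.frame(as.list(wide)),
      data.frame(degenerate = f$degenerate)
    )
  })
  if (n == 0L) {
    return(data.frame(region_id = integer(), r0 = integer(), c0 = integer(),
                      r1 = integer(), c1 = integer(), area = integer(),
                      contrast = numeric(), entropy = numeric(),
                      correlation = numeric(), degenerate = logical()))
  }
  do.call(rbind, rows)
}
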