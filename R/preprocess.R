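#' Red-component grayscale
#'
#' Projects a pseudo-color MSX image onto its red channel. In the warm
#' ("Arctic"-style) palette, fruit render orange with a high red component,
#' so the red channel carries most of the fruit/background contrast.
#'
#' @param img H x W x 3 integer image.
#' @return H x W integer matrix equal to the red channel.
#' @export
to_red_gray <- function(img) {
  validate_msx_image(img)
  img[, , 1L]
}

#' Otsu threshold
#'
#' Returns the intensity level t in \[0, 255\] that maximizes the
#' between-class variance of the 256-bin histogram, with ties broken toward
#' the lowest maximizing threshold. The associated binarization rule is
#' `pixel > t -> foreground`. For a constant image every split leaves one
#' class empty; by convention t is then the constant value itself and the
#' result carries a `degenerate` attribute set to TRUE.
#'
#' @param gray H x W integer matrix in \[0, 255\].
#' @return integer threshold with logical attribute `degenerate`.
#' @export
otsu_threshold <- function(gray) {
  validate_gray_image(gray)
  h <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                 # P(value <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  w0 <- omega
  w1 <- 1 - omega
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) {                 # constant image: one class always empty
    t <- as.integer(which(h > 0)[1] - 1L)
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t <- as.integer(which.max(sigma_b) - 1L)   # which.max takes the first tie
  attr(t, "degenerate") <- FALSE
  t
}

#' Binarize a grayscale image at a threshold
#'
#' @param gray H x W integer matrix.
#' @param t threshold level.
#' @param polarity "bright" marks `pixel > t` as foreground (the default for
#'   warm-palette fruit); "dark" marks `pixel <= t`.
#' @return H x W matrix in {0, 1}.
#' @export
binarize <- function(gray, t, polarity = "bright") {
  validate_gray_image(gray)
  if (!polarity %in% c("bright", "dark"))
    msx_stop_validation("polarity must be 'bright' or 'dark'")
  if (polarity == "bright") (gray > t) * 1L else (gray <= t) * 1L
}

# Disk structuring element: all integer offsets with Euclidean norm <= r.
disk_kernel <- function(radius) {
  if (radius < 0) msx_stop_validation("disk radius must be >= 0")
  r <- floor(radius)
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  k * 1L
}

# Erosion/dilation with an explicit outside-is-background convention,
# enforced by zero-padding before calling EBImage.
morph_with_pad <- function(mask, radius, op) {
  validate_binary_mask(mask)
  if (radius < 0) msx_stop_validation("disk radius must be >= 0")
  r <- as.integer(floor(radius))
  if (r == 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2L * r, w + 2L * r)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- mask
  out <- op(padded, disk_kernel(radius))
  res <- (out[(r + 1L):(r + h), (r + 1L):(r + w)] > 0) * 1L
  matrix(res, h, w)
}

morph_erode_disk <- function(mask, radius)
  morph_with_pad(mask, radius, EBImage::erode)

morph_dilate_disk <- function(mask, radius)
  morph_with_pad(mask, radius, EBImage::dilate)

#' Morphological opening with a disk element
#'
#' Erosion followed by dilation with a disk structuring element (all offsets
#' of Euclidean norm at most `radius`; pixels outside the image count as
#' background). Removes foreground objects smaller than the element while
#' preserving larger shapes. Radius 0 is the identity.
#'
#' @param mask H x W matrix in {0, 1}.
#' @param radius disk radius in pixels (>= 0).
#' @return opened H x W matrix in {0, 1}.
#' @export
morph_open_disk <- function(mask, radius) {
  morph_dilate_disk(morph_erode_disk(mask, radius), radius)
}

#' Label connected regions
#'
#' Labels connected foreground components, assigning labels in raster-scan
#' (row-major) order of each component's first-encountered pixel, starting
#' at 1.
#'
#' @param mask H x W matrix in {0, 1}.
#' @param connectivity 4 or 8 (default 8).
#' @return H x W integer label matrix (0 = background) whose maximum is the
#'   number of regions.
#' @export
label_regions <- function(mask, connectivity = 8) {
  validate_binary_mask(mask)
  if (!connectivity %in% c(4, 8))
    msx_stop_validation("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(mask)          # 4-connected components
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L)
    lab <- merge_diagonal_labels(lab)
  relabel_raster_order(lab)
}

# Merge 4-connected components that touch diagonally (union-find over the
# diagonal adjacency pairs), yielding 8-connected components.
merge_diagonal_labels <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # \ diagonal
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  out
}

# Renumber labels to 1..n in order of first appearance in a row-major scan.
relabel_raster_order <- function(lab) {
  ids <- as.vector(t(lab))               # row-major traversal
  first <- ids[ids > 0L]
  if (length(first) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  order_ids <- unique(first)
  map <- integer(max(lab))
  map[order_ids] <- seq_along(order_ids)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  matrix(as.integer(out), nrow(lab), ncol(lab))
}

#' Remove small connected regions
#'
#' Computes the largest connected-component area A and keeps exactly the
#' components whose area is strictly greater than `fraction * A` (the
#' one-tenth-of-maximum rule at the default fraction).
#'
#' @param mask H x W matrix in {0, 1}.
#' @param fraction area threshold as a fraction of the maximum component
#'   area, in (0, 1].
#' @param connectivity 4 or 8.
#' @return filtered H x W matrix in {0, 1}.
#' @export
remove_small_regions <- function(mask, fraction = 0.1, connectivity = 8) {
  validate_binary_mask(mask)
  if (!(fraction > 0 && fraction <= 1))
    msx_stop_validation("fraction must be in (0, 1]")
  lab <- label_regions(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(mask * 0L)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas > fraction * max(areas))
  out <- (matrix(lab %in% keep, nrow(mask), ncol(mask))) * 1L
  out
}

#' Restore pseudo-color inside a mask
#'
#' Returns the original pseudo-color values where the mask is 1 and black
#' (0, 0, 0) elsewhere, restoring image detail inside the retained regions.
#'
#' @param img H x W x 3 integer image.
#' @param mask H x W matrix in {0, 1}.
#' @return H x W x 3 integer image.
#' @export
restore_color <- function(img, mask) {
  validate_msx_image(img)
  validate_binary_mask(mask)
  stopifnot_same_shape(img, mask, "image and mask")
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * mask
  out
}

#' Full pre-processing chain
#'
#' Applies, in order: red-component grayscale, Otsu binarization,
#' morphological opening with a disk element, small-area removal, region
#' labeling, and pseudo-color restoration. All intermediates are retained.
#'
#' @param img H x W x 3 integer MSX image.
#' @param cfg an [msx_config()] object.
#' @return an object of class `msx_preprocess` with elements `gray`,
#'   `otsu_threshold` (with `degenerate` attribute), `binary_raw`,
#'   `binary_clean`, `labels`, `restored`, and `cfg`.
#' @export
preprocess_image <- function(img, cfg = msx_config()) {
  validate_msx_image(img)
  validate_config(cfg)
  gray <- msx_timed("gray", to_red_gray(img))
  t <- otsu_threshold(gray)
  binary_raw <- msx_timed("binarize", binarize(gray, t, cfg$binarize_polarity))
  opened <- msx_timed("open", morph_open_disk(binary_raw, cfg$disk_radius))
  binary_clean <- msx_timed("small-area",
    remove_small_regions(opened, cfg$small_area_fraction, cfg$connectivity))
  labels <- msx_timed("label", label_regions(binary_clean, cfg$connectivity))
  restored <- msx_timed("restore", restore_color(img, binary_clean))
  structure(
    list(gray = gray, otsu_threshold = t, binary_raw = binary_raw,
         binary_clean = binary_clean, labels = labels, restored = restored,
         cfg = cfg),
    class = "msx_preprocess"
  )
}

#' @export
print.msx_preprocess <- function(x, ...) {
  cat(sprintf("MSX pre-processing result: %d x %d image, Otsu t = %d%s, %d region(s)\n",
              nrow(x$gray), ncol(x$gray), x$otsu_threshold,
              if (isTRUE(attr(x$otsu_threshold, "degenerate"))) " (degenerate)" else "",
              n_regions(x$labels)))
  invisible(x)
}
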