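#' @keywords internal
"_PACKAGE"

# Classed conditions so the CLI can map failures to exit codes
# (validation -> 1, I/O -> 2).
msx_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "msx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

msx_stop_validation <- function(...) msx_stop(paste0(...), "msx_validation_error")
msx_stop_io <- function(...) msx_stop(paste0(...), "msx_io_error")

#' Validate an MSX pseudo-color image
#'
#' An MSX image is stored as an integer array of dimension H x W x 3
#' (row-major, origin top-left), 8-bit per channel, channel order
#' red-green-blue.
#'
#' @param img object to validate.
#' @return `img`, invisibly, if valid; otherwise a validation error.
#' @export
validate_msx_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    msx_stop_validation("MSX image must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    msx_stop_validation("MSX image must have H >= 1 and W >= 1")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    msx_stop_validation("MSX image values must be in [0, 255]")
  if (any(img != round(img)))
    msx_stop_validation("MSX image values must be integers (8-bit)")
  invisible(img)
}

#' Validate an 8-bit grayscale image
#' @param gray object to validate.
#' @return `gray`, invisibly, if valid.
#' @export
validate_gray_image <- function(gray) {
  if (!is.matrix(gray))
    msx_stop_validation("gray image must be an H x W matrix")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255 || any(gray != round(gray)))
    msx_stop_validation("gray image values must be integers in [0, 255]")
  invisible(gray)
}

#' Validate a binary mask
#' @param mask object to validate.
#' @return `mask`, invisibly, if valid.
#' @export
validate_binary_mask <- function(mask) {
  if (!is.matrix(mask))
    msx_stop_validation("binary mask must be an H x W matrix")
  if (anyNA(mask) || !all(mask %in% c(0, 1)))
    msx_stop_validation("binary mask values must be in {0, 1}")
  invisible(mask)
}

#' Validate a label map
#'
#' Label 0 is background; region labels must be exactly 1..n with no gaps.
#'
#' @param labels object to validate.
#' @return `labels`, invisibly, if valid.
#' @export
validate_label_map <- function(labels) {
  if (!is.matrix(labels))
    msx_stop_validation("label map must be an H x W matrix")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    msx_stop_validation("label map values must be non-negative integers")
  n <- n_regions(labels)
  present <- sort(unique(labels[labels > 0]))
  if (length(present) && !identical(as.integer(present), seq_len(n)))
    msx_stop_validation("region labels must be exactly 1..n_regions with no gaps")
  invisible(labels)
}

#' Number of regions in a label map
#' @param labels label map matrix.
#' @return integer count of labeled regions.
#' @export
n_regions <- function(labels) {
  m <- max(labels)
  as.integer(if (is.finite(m)) m else 0L)
}

same_shape <- function(a, b) identical(dim(a)[1:2], dim(b)[1:2])

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!same_shape(a, b))
    msx_stop_validation(what, " must have identical height and width")
}
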