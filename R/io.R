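#' Read an MSX pseudo-color image
#'
#' Reads a PNG or JPG raster as an H x W x 3 8-bit integer array (channel
#' order red-green-blue). Single-channel files are replicated across the
#' three channels; an alpha channel is dropped; 16-bit PNG samples are
#' rescaled to 8-bit by integer division by 256.
#'
#' @param path path to a PNG or JPG file.
#' @return an integer H x W x 3 array with values in \[0, 255\].
#' @export
read_msx_image <- function(path) {
  px <- read_raster_8bit(path)
  if (length(dim(px)) == 2L) {
    px <- array(px, c(dim(px), 3L))                  # gray -> replicate
  } else if (dim(px)[3] == 2L) {
    px <- array(px[, , 1L], c(dim(px)[1:2], 3L))     # gray+alpha
  } else if (dim(px)[3] >= 4L) {
    px <- px[, , 1:3, drop = FALSE]                  # drop alpha
  }
  validate_msx_image(px)
  px
}

# Decode to integer data in [0,255]; keeps the channel layout of the file.
read_raster_8bit <- function(path) {
  if (!file.exists(path)) msx_stop_io("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- tryCatch({
    if (ext == "png") {
      r <- png::readPNG(path, info = TRUE)
      depth <- attr(r, "info")$bit.depth
      if (!is.null(depth) && depth == 16) {
        storage.mode(r) <- "double"
        array(as.integer(round(r * 65535)) %/% 256L, dim(r))
      } else {
        array(as.integer(round(r * 255)), dim(r))
      }
    } else if (ext %in% c("jpg", "jpeg")) {
      r <- jpeg::readJPEG(path)
      array(as.integer(round(r * 255)), dim(r))
    } else {
      msx_stop_validation("unsupported image format: .", ext)
    }
  }, error = function(e) {
    if (inherits(e, "msx_error")) stop(e)
    msx_stop_io("cannot decode image ", path, ": ", conditionMessage(e))
  })
  if (length(x) == 0L) msx_stop_validation("zero-sized raster: ", path)
  x
}

#' Write an MSX image as PNG
#' @param img H x W x 3 integer array in \[0, 255\].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_msx_image <- function(img, path) {
  validate_msx_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a binary ground-truth mask
#'
#' The file must decode to a single-channel raster (multi-channel mask
#' files are ambiguous and rejected). Nonzero pixels map to 1.
#'
#' @param path path to a single-channel PNG (or grayscale JPG).
#' @return an H x W matrix with values in {0, 1}.
#' @export
read_mask <- function(path) {
  px <- read_raster_8bit(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1L]           # gray+alpha: alpha dropped
    else msx_stop_validation("mask file must be single-channel: ", path)
  }
  mask <- (px != 0L) * 1L
  validate_binary_mask(mask)
  mask
}

#' Write a binary mask as single-channel PNG
#' @param mask H x W matrix in {0, 1}.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a label map as single-channel PNG
#'
#' Stored losslessly as 8-bit gray values equal to the labels, which limits
#' a stored map to 255 regions.
#'
#' @param labels H x W non-negative integer matrix (0 = background).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  validate_label_map(labels)
  if (max(labels) > 255)
    msx_stop_validation("cannot store more than 255 regions in an 8-bit label map")
  png::writePNG(matrix(labels / 255, nrow(labels), ncol(labels)), path)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path PNG path.
#' @return H x W integer matrix of labels.
#' @export
read_label_map <- function(path) {
  px <- read_raster_8bit(path)
  if (length(dim(px)) == 3L)
    msx_stop_validation("label map file must be single-channel: ", path)
  labels <- px
  validate_label_map(labels)
  labels
}

#' Render a detection overlay
#'
#' Tints detected pixels with a distinct color over the input image and,
#' if supplied, draws the contours of the manual ground-truth mask as
#' white lines.
#'
#' @param img input H x W x 3 image.
#' @param mask detected fruit mask (H x W, {0, 1}).
#' @param path output PNG path.
#' @param manual optional manual ground-truth mask whose contours are drawn
#'   in white.
#' @param color length-3 RGB tint for detected pixels.
#' @param alpha tint opacity in \[0, 1\].
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, mask, path, manual = NULL,
                          color = c(255, 140, 0), alpha = 0.5) {
  validate_msx_image(img)
  validate_binary_mask(mask)
  stopifnot_same_shape(img, mask, "image and mask")
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask == 1] <- round((1 - alpha) * plane[mask == 1] + alpha * color[ch])
    out[, , ch] <- plane
  }
  if (!is.null(manual)) {
    validate_binary_mask(manual)
    stopifnot_same_shape(img, manual, "image and manual mask")
    edge <- manual - morph_erode_disk(manual, 1)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[edge == 1] <- 255
      out[, , ch] <- plane
    }
  }
  write_msx_image(out, path)
}

# Structured logging to stderr with per-stage timings; enabled via
# options(msxfruit.verbose = TRUE) or the CLI --verbose flag.
msx_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("msxfruit.verbose", FALSE)))
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS2"),
                    stage, sprintf(fmt, ...)))
  invisible(NULL)
}

msx_timed <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  msx_log(stage, "done in %.3f s", proc.time()[["elapsed"]] - t0)
  res
}
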