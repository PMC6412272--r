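#' End-to-end fruit detection
#'
#' Composes the full recognition pipeline on one image: pre-processing
#' (red-component grayscale, Otsu binarization, opening, small-area
#' removal, labeling, color restoration), per-region GLCM texture
#' features, and linear region classification. Returns the detected fruit
#' mask together with all intermediates.
#'
#' @param img H x W x 3 integer MSX image.
#' @param model a trained `msx_classifier`.
#' @param cfg an [msx_config()] object.
#' @return an object of class `msx_detection`: `pre` (the
#'   `msx_preprocess` result), `features` (region feature table),
#'   `regions` (region_id, label, decision), `fruit_mask` (binary mask of
#'   regions classified -1).
#' @export
detect_fruit <- function(img, model, cfg = msx_config()) {
  pre <- preprocess_image(img, cfg)
  features <- msx_timed("features", extract_features(pre, cfg))
  regions <- msx_timed("classify",
                       classify_regions(features, model, pre$labels))
  fruit_mask <- attr(regions, "fruit_mask")
  attr(regions, "fruit_mask") <- NULL
  structure(list(pre = pre, features = features, regions = regions,
                 fruit_mask = fruit_mask), class = "msx_detection")
}

#' @export
print.msx_detection <- function(x, ...) {
  cat(sprintf("MSX fruit detection: %d region(s), %d classified as fruit (%d px)\n",
              nrow(x$regions), sum(x$regions$label == -1L), sum(x$fruit_mask)))
  invisible(x)
}
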