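#' Pixel overlap counts between predicted and manual fruit masks
#'
#' Decomposes the image into the four regions used by the overlap metrics:
#' inside the manual region, the correctly segmented pixels `s_ic` and the
#' leaked (missed) pixels `s_il`; outside it, the correctly rejected pixels
#' `s_oc` and the over-segmented pixels `s_oo`. The four counts always
#' partition the image.
#'
#' @param pred predicted H x W binary mask.
#' @param manual manual (ground-truth) H x W binary mask.
#' @return an object of class `msx_counts`: list with `s_ic`, `s_il`,
#'   `s_oc`, `s_oo` (integer pixel counts).
#' @export
overlap_counts <- function(pred, manual) {
  validate_binary_mask(pred)
  validate_binary_mask(manual)
  stopifnot_same_shape(pred, manual, "predicted and manual masks")
  p <- pred == 1; m <- manual == 1
  structure(list(
    s_ic = sum(p & m),
    s_il = sum(!p & m),
    s_oc = sum(!p & !m),
    s_oo = sum(p & !m)), class = "msx_counts")
}

#' Recognition metrics from overlap counts
#'
#' Computes the three ratios: recognition precision
#' `RP = s_ic / (s_ic + s_oo)` (share of detected pixels that are true
#' fruit), recognition sensitivity `RS = s_ic / (s_ic + s_il)` (share of
#' the manual fruit region recovered) and relative error
#' `RE = (s_oo + s_il) / (s_ic + s_il)`. When nothing is detected
#' (`s_ic + s_oo = 0`), RP is defined as 0 and the result is flagged.
#'
#' @param counts an `msx_counts` object (or list with the four counts).
#' @return an object of class `msx_metrics`: list with `rp`, `rs`, `re`
#'   and logical `nothing_detected`.
#' @export
seg_metrics <- function(counts) {
  s_ic <- counts$s_ic; s_il <- counts$s_il; s_oo <- counts$s_oo
  if (any(c(s_ic, s_il, counts$s_oc, s_oo) < 0))
    msx_stop_validation("overlap counts must be non-negative")
  if (s_ic + s_il == 0)
    msx_stop_validation("manual mask is empty: no ground truth to evaluate")
  nothing <- (s_ic + s_oo) == 0
  structure(list(
    rp = if (nothing) 0 else s_ic / (s_ic + s_oo),
    rs = s_ic / (s_ic + s_il),
    re = (s_oo + s_il) / (s_ic + s_il),
    nothing_detected = nothing), class = "msx_metrics")
}

# Assign every predicted pixel to a manual region: pixels inside a manual
# region belong to it; stray predicted pixels go to the nearest manual
# region by Euclidean distance to its support (ties to the lower region id).
attribute_pixels <- function(pred, manual_masks) {
  h <- nrow(pred); w <- ncol(pred)
  assign <- matrix(0L, h, w)
  for (j in rev(seq_along(manual_masks)))   # lower ids win on overlap
    assign[manual_masks[[j]] == 1] <- j
  stray <- pred == 1 & assign == 0L
  if (any(stray)) {
    best_d <- matrix(Inf, h, w)
    for (j in seq_along(manual_masks)) {
      dm <- EBImage::distmap(1 - manual_masks[[j]])   # distance to region j
      closer <- stray & (dm < best_d - 1e-9)          # strict: ties keep lower id
      assign[closer] <- j
      best_d <- pmin(best_d, dm)
    }
  }
  assign
}

#' Per-region evaluation of one scene
#'
#' Evaluates a predicted fruit mask against per-fruit manual masks.
#' Each predicted pixel is attributed to one manual region (its own if
#' inside one, else the nearest); per-region overlap counts and metrics
#' are then computed on that attribution. The complete/incomplete category
#' is taken from the annotations, never inferred from the masks.
#'
#' @param pred predicted H x W binary fruit mask.
#' @param manual_masks list of per-fruit binary masks (disjoint supports).
#' @param annotations data.frame with one row per manual region, containing
#'   at least `category` ("complete" or "incomplete").
#' @return data.frame with one row per manual region: `region_id`,
#'   `category`, the four counts, `rp`, `rs`, `re`.
#' @export
evaluate_scene <- function(pred, manual_masks, annotations) {
  validate_binary_mask(pred)
  if (length(manual_masks) == 0L)
    msx_stop_validation("no manual regions to evaluate")
  if (nrow(annotations) != length(manual_masks))
    msx_stop_validation("annotations must have one row per manual region")
  if (!all(annotations$category %in% c("complete", "incomplete")))
    msx_stop_validation("category must be 'complete' or 'incomplete'")
  for (m in manual_masks) {
    validate_binary_mask(m)
    stopifnot_same_shape(pred, m, "predicted and manual masks")
  }
  assign <- attribute_pixels(pred, manual_masks)
  rows <- lapply(seq_along(manual_masks), function(j) {
    m <- manual_masks[[j]] == 1
    pj <- pred == 1 & assign == j
    cnt <- list(s_ic = sum(pj & m), s_il = sum(m & !(pred == 1)),
                s_oo = sum(pj & !m))
    cnt$s_oc <- nrow(pred) * ncol(pred) - cnt$s_ic - cnt$s_il - cnt$s_oo
    met <- seg_metrics(cnt)
    data.frame(region_id = j, category = annotations$category[j],
               s_ic = cnt$s_ic, s_il = cnt$s_il, s_oc = cnt$s_oc,
               s_oo = cnt$s_oo, rp = met$rp, rs = met$rs, re = met$re)
  })
  do.call(rbind, rows)
}

#' Stratified evaluation of a dataset
#'
#' Pools per-region results over scenes and reports unweighted arithmetic
#' means of RP, RS and RE per stratum (complete vs. incomplete fruit
#' regions), with region counts — the layout of the standard results table
#' for this detector. With `pooling = "image"` the four counts are instead
#' summed per scene (whole-image masks) before computing metrics, and the
#' strata are replaced by a single "all" row.
#'
#' @param scenes list; each element is a list with `pred` (binary mask),
#'   `manual_masks` (list of per-fruit masks) and `annotations`
#'   (data.frame with `category`).
#' @param pooling "region" (default) or "image".
#' @return list with `per_region` (data.frame of all regions) and `summary`
#'   (data.frame: `stratum`, `n_regions`, `rp`, `rs`, `re`).
#' @export
evaluate_dataset <- function(scenes, pooling = c("region", "image")) {
  pooling <- match.arg(pooling)
  if (pooling == "image") {
    rows <- lapply(seq_along(scenes), function(i) {
      sc <- scenes[[i]]
      manual <- Reduce(`+`, sc$manual_masks)
      manual <- (manual > 0) * 1L
      met <- seg_metrics(overlap_counts(sc$pred, manual))
      data.frame(scene = i, rp = met$rp, rs = met$rs, re = met$re)
    })
    per <- do.call(rbind, rows)
    summary <- data.frame(stratum = "all", n_regions = nrow(per),
                          rp = mean(per$rp), rs = mean(per$rs),
                          re = mean(per$re))
    return(list(per_region = per, summary = summary))
  }
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    df <- evaluate_scene(sc$pred, sc$manual_masks, sc$annotations)
    df$scene <- i
    df
  })
  per <- do.call(rbind, rows)
  strata <- c("complete", "incomplete")
  summary <- do.call(rbind, lapply(strata, function(s) {
    sel <- per[per$category == s, , drop = FALSE]
    data.frame(stratum = s, n_regions = nrow(sel),
               rp = if (nrow(sel)) mean(sel$rp) else NA_real_,
               rs = if (nrow(sel)) mean(sel$rs) else NA_real_,
               re = if (nrow(sel)) mean(sel$re) else NA_real_)
  }))
  list(per_region = per, summary = summary)
}
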