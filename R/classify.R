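#' Train the linear max-margin region classifier
#'
#' Fits the two-class linear decision function
#' `f(x) = sign(w . x + b)` with labels -1 = fruit region and
#' +1 = non-fruit region (the field's convention for this detector is
#' preserved: fruit carry the negative tag). Features are standardized to
#' zero mean and unit spread before optimization; the maximum-margin
#' separator is found with a soft-margin linear SVM at a large
#' margin-violation penalty, so that linearly separable data are classified
#' with 100% training accuracy and the hard-margin condition holds, while
#' near-separable data still train rather than fail.
#'
#' @param x numeric matrix (n x d) or data.frame of feature vectors, one
#'   row per region; columns named after the features.
#' @param y integer vector of labels in {-1, +1}.
#' @param cost margin-violation penalty (default 1e4; effectively
#'   hard-margin on separable data).
#' @param tolerance optimizer termination tolerance. Training starts at
#'   this tolerance and relaxes it stepwise (up to 1e-2) if the quadratic
#'   programming solver hits its iteration cap, which happens when a large
#'   penalty meets clearly non-separable data; the tolerance actually used
#'   is stored in the model.
#' @return an object of class `msx_classifier`: `weights`, `bias` (on the
#'   standardized scale), `feature_order`, `center`, `scale` (per-feature
#'   standardization), `n_train`, `training_accuracy`.
#' @export
train_classifier <- function(x, y, cost = 1e4, tolerance = 1e-8) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    msx_stop_validation("feature matrix must be finite numeric")
  if (nrow(x) != length(y))
    msx_stop_validation("feature rows and labels must have the same length")
  if (!all(y %in% c(-1, 1)))
    msx_stop_validation("labels must be -1 (fruit) or +1 (non-fruit)")
  if (length(unique(y)) < 2)
    msx_stop_validation("training requires at least one example of each class")
  feature_order <- colnames(x)
  if (is.null(feature_order)) feature_order <- paste0("f", seq_len(ncol(x)))
  center <- colMeans(x)
  spread <- apply(x, 2, stats::sd)
  if (any(spread < 1e-12))
    msx_stop_validation("feature(s) with zero spread cannot be standardized: ",
                        paste(feature_order[spread < 1e-12], collapse = ", "))
  xs <- scale(x, center = center, scale = spread)
  tol_ladder <- unique(sort(c(tolerance, 1e-5, 1e-3, 1e-2)))
  tol_ladder <- tol_ladder[tol_ladder >= tolerance]
  fit <- NULL
  used_tol <- tolerance
  for (tol in tol_ladder) {
    hit_cap <- FALSE
    fit <- withCallingHandlers(
      e1071::svm(x = xs, y = factor(y, levels = c(-1, 1)),
                 kernel = "linear", cost = cost, scale = FALSE,
                 tolerance = tol),
      warning = function(cond) {
        if (grepl("max number of iterations", conditionMessage(cond))) {
          hit_cap <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    used_tol <- tol
    if (!hit_cap) break
    msx_log("train", "solver hit iteration cap at tolerance %g; relaxing", tol)
  }
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dec <- drop(xs %*% w + b)
  pred <- ifelse(dec > 0, 1L, -1L)     # sign(0) -> -1 (fruit)
  if (mean(pred == y) < 0.5) {         # orient the separator to the labels
    w <- -w; b <- -b
    dec <- -dec
    pred <- ifelse(dec > 0, 1L, -1L)
  }
  structure(list(
    weights = stats::setNames(as.numeric(w), feature_order),
    bias = as.numeric(b),
    feature_order = feature_order,
    center = stats::setNames(as.numeric(center), feature_order),
    scale = stats::setNames(as.numeric(spread), feature_order),
    cost = cost,
    tolerance = used_tol,
    n_train = nrow(x),
    training_accuracy = mean(pred == y)), class = "msx_classifier")
}

#' Predict region labels with a trained classifier
#'
#' Evaluates `sign(w . x_std + b)` on the standardized feature vector; a
#' decision value of exactly 0 maps to -1 (fruit) by the documented
#' tie-break.
#'
#' @param object an `msx_classifier`.
#' @param x numeric matrix/data.frame of raw (unstandardized) feature rows,
#'   or a single feature vector.
#' @param ... unused.
#' @return integer vector of labels in {-1, +1} with attribute `decision`
#'   (the affine decision values).
#' @export
predict.msx_classifier <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, object$feature_order))
  x <- as.matrix(x)
  if (ncol(x) != length(object$weights))
    msx_stop_validation("feature dimension mismatch: expected ",
                        length(object$weights), ", got ", ncol(x))
  if (anyNA(x) || any(!is.finite(x)))
    msx_stop_validation("feature values must be finite")
  if (!is.null(colnames(x)) && all(object$feature_order %in% colnames(x)))
    x <- x[, object$feature_order, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dec <- drop(xs %*% object$weights + object$bias)
  lab <- ifelse(dec > 0, 1L, -1L)
  attr(lab, "decision") <- dec
  lab
}

#' Classify the regions of a feature table and assemble the fruit mask
#'
#' Applies the classifier to each region's feature vector (the columns in
#' the model's `feature_order`). Regions flagged degenerate are labeled
#' +1 (non-fruit) without model evaluation. The fruit mask contains exactly
#' the pixels of regions labeled -1.
#'
#' @param features data.frame from [extract_features()] (must contain the
#'   model's feature columns, `region_id` and `degenerate`).
#' @param model an `msx_classifier`.
#' @param labels optional label map; when supplied the assembled fruit mask
#'   is returned as well.
#' @return data.frame `region_id`, `label`, `decision`; if `labels` is
#'   supplied, carries the fruit mask in attribute `fruit_mask`.
#' @export
classify_regions <- function(features, model, labels = NULL) {
  if (!inherits(model, "msx_classifier"))
    msx_stop_validation("model must be an msx_classifier")
  missing_cols <- setdiff(model$feature_order, names(features))
  if (length(missing_cols))
    msx_stop_validation("feature table lacks column(s): ",
                        paste(missing_cols, collapse = ", "))
  n <- nrow(features)
  out <- data.frame(region_id = features$region_id,
                    label = rep(1L, n), decision = rep(NA_real_, n))
  if (n > 0) {
    degen <- if ("degenerate" %in% names(features)) features$degenerate
             else rep(FALSE, n)
    live <- which(!degen)
    if (length(live)) {
      x <- as.matrix(features[live, model$feature_order, drop = FALSE])
      lab <- predict(model, x)
      out$label[live] <- as.integer(lab)
      out$decision[live] <- attr(lab, "decision")
    }
  }
  if (!is.null(labels)) {
    validate_label_map(labels)
    fruit_ids <- out$region_id[out$label == -1L]
    mask <- matrix(as.integer(labels %in% fruit_ids & labels > 0L),
                   nrow(labels), ncol(labels))
    attr(out, "fruit_mask") <- mask
  }
  out
}

#' Serialize a classifier to JSON
#' @param model an `msx_classifier`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  if (!inherits(model, "msx_classifier"))
    msx_stop_validation("model must be an msx_classifier")
  jsonlite::write_json(
    list(feature_order = model$feature_order,
         weights = as.list(model$weights),
         bias = model$bias,
         center = as.list(model$center),
         scale = as.list(model$scale),
         cost = model$cost,
         n_train = model$n_train,
         training_accuracy = model$training_accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier serialized by [write_classifier()]
#' @param path JSON path.
#' @return an `msx_classifier`.
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) msx_stop_io("model file not found: ", path)
  j <- jsonlite::fromJSON(path)
  structure(list(
    weights = unlist(j$weights),
    bias = j$bias,
    feature_order = j$feature_order,
    center = unlist(j$center),
    scale = unlist(j$scale),
    cost = j$cost,
    n_train = j$n_train,
    training_accuracy = j$training_accuracy), class = "msx_classifier")
}

#' @export
print.msx_classifier <- function(x, ...) {
  cat(sprintf("Linear max-margin region classifier (%d features, n = %d, training accuracy %.3f)\n",
              length(x$weights), x$n_train, x$training_accuracy))
  cat("  weights:", paste(sprintf("%s = %.4f", x$feature_order, x$weights),
                          collapse = ", "), "\n")
  cat(sprintf("  bias: %.4f\n", x$bias))
  invisible(x)
}
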