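# Classification metrics (accuracy, sensitivity, specificity, precision,
# F1), ROC/AUC, and segmentation quality (Dice, Hausdorff) with the
# pseudo-ground-truth and aggregation conventions used for datasets that
# ship no segmentation ground truth.

#' Confusion counts with carcinoma as the positive class
#'
#' @param y_true,y_pred Equal-length label vectors over
#'   `{carcinoma, non-carcinoma}`.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("confusion: label vectors differ in length")
  }
  if (!all(c(y_true, y_pred) %in% CLASS_LEVELS)) {
    stop("confusion: labels must be in {carcinoma, non-carcinoma}")
  }
  pos <- "carcinoma"
  structure(list(
    TP = sum(y_true == pos & y_pred == pos),
    TN = sum(y_true != pos & y_pred != pos),
    FP = sum(y_true != pos & y_pred == pos),
    FN = sum(y_true == pos & y_pred != pos)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`, reported as percentages rounded half
#' up to 2 decimals. A metric with a zero denominator is reported as
#' `NA` (undefined), not as 0.
#'
#' @param cc A `confusion_counts` object or a list with TP/TN/FP/FN.
#' @return A list of class `metrics_report` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1` (percent).
#' @export
classification_metrics <- function(cc) {
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  total <- tp + tn + fp + fn
  if (total < 1) stop("classification_metrics: empty confusion counts")
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 2)
  }
  structure(list(
    accuracy    = pct(tp + tn, total),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision   = pct(tp, tp + fp),
    f1          = pct(2 * tp, 2 * tp + fp + fn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Accuracy %.2f%% | Sensitivity %.2f%% | Specificity %.2f%% | Precision %.2f%% | F1 %.2f%%\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties grouped),
#' predicting carcinoma when `score >= threshold`; the AUC is the
#' trapezoid-rule area under the resulting (FPR, TPR) curve, which equals
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores Numeric decision scores (higher = more carcinoma-like).
#' @param labels Labels over `{carcinoma, non-carcinoma}`.
#' @return `list(points = data.frame(fpr, tpr), auc)`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "carcinoma"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("roc_auc: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nn, 0)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Dice coefficient of two binary masks
#'
#' `D = 2 |X & Y| / (|X| + |Y|)`; defined as 1 when both masks are empty
#' (the masks agree that there is nothing to segment).
#'
#' @param X,Y Binary matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("dice: mask shapes differ")
  sx <- sum(X > 0); sy <- sum(Y > 0)
  if (sx + sy == 0) return(1)
  2 * sum(X > 0 & Y > 0) / (sx + sy)
}

#' Hausdorff distance between two binary masks
#'
#' `H(X, Y) = max(h(X, Y), h(Y, X))` with
#' `h(X, Y) = max_{x in X} min_{y in Y} ||x - y||` over the foreground
#' pixel coordinate sets, Euclidean pixel distance. Computed exactly via
#' the Euclidean distance transform.
#'
#' @param X,Y Non-empty binary matrices of identical shape.
#' @return Hausdorff distance (pixels).
#' @export
hausdorff <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("hausdorff: mask shapes differ")
  bx <- X > 0; by <- Y > 0
  if (!any(bx) || !any(by)) stop("hausdorff: empty mask")
  dist_to <- function(m) EBImage::distmap((!m) * 1L)  # 0 on m, Euclidean off m
  h_xy <- max(dist_to(by)[bx])
  h_yx <- max(dist_to(bx)[by])
  max(h_xy, h_yx)
}

#' Fixed-threshold pseudo ground truth
#'
#' Binarizes the grayscale image with one global threshold shared by all
#' images of a run (the convention used to approximate ground truth on
#' classification-only datasets). Dark pixels (nuclei) map to 1 by
#' default.
#'
#' @param img RGB array.
#' @param threshold Shared threshold on the `[0, 1]` gray scale; when
#'   `NULL`, the Otsu threshold of this image is used (callers fix it
#'   from the first image of the run).
#' @param dark_objects If `TRUE` pixels below the threshold are
#'   foreground.
#' @return Binary matrix.
#' @export
pseudo_ground_truth <- function(img, threshold = NULL, dark_objects = TRUE) {
  gray <- clamp(luminance(img) / 255, 0, 1)
  if (is.null(threshold)) threshold <- EBImage::otsu(gray)
  m <- if (dark_objects) gray < threshold else gray > threshold
  m * 1L
}

#' Aggregate per-image Dice coefficients
#'
#' Overall mean plus, per category, the maximum Dice.
#'
#' @param dice_values Numeric vector of per-image Dice coefficients.
#' @param categories Category label per image.
#' @return `list(mean, max_per_category)` (named numeric vector).
#' @export
dice_aggregate <- function(dice_values, categories) {
  stopifnot(length(dice_values) >= 1,
            length(dice_values) == length(categories))
  list(mean = mean(dice_values),
       max_per_category = tapply(dice_values, categories, max))
}
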