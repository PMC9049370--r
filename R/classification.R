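# RBF-SVM on fused patch features with patch-to-image majority voting.
# Carcinoma is the positive class throughout.

CLASS_LEVELS <- c("carcinoma", "non-carcinoma")

#' SVM configuration
#'
#' Radial basis kernel `K(x, z) = exp(-g ||x - z||^2)` with penalty
#' `c = 2` and `g = 1` (libsvm gamma convention: `g` multiplies the
#' squared Euclidean distance).
#'
#' @param cost Soft-margin penalty `c` (default 2).
#' @param gamma Kernel parameter `g` (default 1).
#' @return Named list.
#' @export
svm_config <- function(cost = 2, gamma = 1) {
  stopifnot(cost > 0, gamma > 0)
  list(cost = cost, gamma = gamma)
}

#' Majority-vote rule
#'
#' @param patches_per_image Number of patch votes per image (default 20).
#' @param threshold Strict vote threshold: an image is non-carcinoma iff
#'   strictly more than `threshold` patches are non-carcinoma
#'   (default 10).
#' @return Named list.
#' @export
vote_rule <- function(patches_per_image = 20, threshold = 10) {
  stopifnot(threshold < patches_per_image)
  list(patches_per_image = patches_per_image, threshold = threshold)
}

#' Fit a per-dimension min-max scaler on training features
#'
#' Each dimension is mapped to `[0, 1]` by the training minimum and
#' maximum; constant dimensions map to 0 and test values are clipped to
#' `[0, 1]`.
#'
#' @param train_features Numeric matrix, rows = patches.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(train_features) {
  x <- as.matrix(train_features)
  if (nrow(x) == 0) stop("fit_scaler: empty training set")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(list(min = mins, range = maxs - mins), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler`.
#' @param features Numeric matrix to scale.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(features)
  if (ncol(x) != length(scaler$min)) {
    stop("apply_scaler: feature dimension mismatch")
  }
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  out[, scaler$range == 0] <- 0
  clamp(out, 0, 1)
}

#' Train the RBF-kernel SVM
#'
#' Soft-margin SVM with the configured radial kernel; deterministic for
#' fixed inputs.
#'
#' @param features Scaled feature matrix (rows = patches).
#' @param labels Character/factor labels in
#'   `{carcinoma, non-carcinoma}`.
#' @param cfg See [svm_config()].
#' @param seed RNG seed (the solver itself is deterministic; the seed
#'   guards any future stochastic extension).
#' @return An object of class `patch_svm`.
#' @export
train_svm <- function(features, labels, cfg = svm_config(), seed = 1) {
  y <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (any(is.na(y))) stop("train_svm: labels must be carcinoma/non-carcinoma")
  if (length(unique(y)) < 2L) stop("train_svm: both classes must be present")
  fit <- with_seed(seed, {
    e1071::svm(x = as.matrix(features), y = y, scale = FALSE,
               kernel = "radial", cost = cfg$cost, gamma = cfg$gamma)
  })
  structure(list(fit = fit, cfg = cfg), class = "patch_svm")
}

#' Predict patch labels and decision scores
#'
#' @param model A `patch_svm`.
#' @param features Scaled feature matrix.
#' @return `list(labels, scores)`; scores are signed decision values with
#'   positive = carcinoma.
#' @export
predict_patches <- function(model, features) {
  stopifnot(inherits(model, "patch_svm"))
  x <- as.matrix(features)
  if (ncol(x) != ncol(model$fit$SV)) {
    stop("predict_patches: feature dimension mismatch (",
         ncol(x), " vs ", ncol(model$fit$SV), ")")
  }
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # decision values are positive for the class named first in the column
  # header; normalize so positive = carcinoma
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  scores <- if (first == "carcinoma") dv[, 1] else -dv[, 1]
  list(labels = as.character(pr), scores = as.numeric(scores))
}

#' Aggregate patch votes to an image label
#'
#' An image is non-carcinoma iff strictly more than `threshold` of its
#' patches are predicted non-carcinoma; a tie at exactly `threshold`
#' votes goes to carcinoma.
#'
#' @param patch_labels Character vector of exactly
#'   `rule$patches_per_image` patch labels.
#' @param rule See [vote_rule()].
#' @return `"carcinoma"` or `"non-carcinoma"`.
#' @export
majority_vote <- function(patch_labels, rule = vote_rule()) {
  if (length(patch_labels) != rule$patches_per_image) {
    stop("majority_vote: expected ", rule$patches_per_image,
         " votes, got ", length(patch_labels))
  }
  if (!all(patch_labels %in% CLASS_LEVELS)) {
    stop("majority_vote: unknown labels")
  }
  if (sum(patch_labels == "non-carcinoma") > rule$threshold) {
    "non-carcinoma"
  } else {
    "carcinoma"
  }
}

#' Image-level decision score
#'
#' Mean of the patch decision scores (monotone in carcinoma evidence);
#' used for the image-wise ROC curve.
#'
#' @param patch_scores Numeric vector of exactly `n` patch scores.
#' @param n Expected number of patches (default 20).
#' @return Scalar mean score.
#' @export
image_score <- function(patch_scores, n = 20) {
  if (length(patch_scores) != n) {
    stop("image_score: expected ", n, " scores, got ", length(patch_scores))
  }
  mean(patch_scores)
}
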