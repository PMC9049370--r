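# End-to-end orchestration: preprocess -> stain separation -> nuclei
# segmentation -> patch features -> SVM -> majority vote -> evaluation.

#' Pipeline configuration
#'
#' Every field defaults to the method's standard value: `lambda = 0.2`,
#' `I0 = 255`, CLBP `P = 8, R = 1`, SVM `c = 2, g = 1`, 20 patches per
#' image and a strict vote threshold of 10.
#'
#' @param seed Global seed; all per-image randomness derives from it.
#' @param rescale Halve the input images before patching (the convention
#'   for 2048 x 1536 source images; disable for images already at patch
#'   scale).
#' @param n_patches Patches per image (default 20).
#' @param patch_size Patch side length (default 512; use 256 for 512 x
#'   512 sources).
#' @param I0 Reference intensity for the OD transform.
#' @param lambda SNMF sparsity weight.
#' @param stain Extra arguments for [estimate_stains()].
#' @param seg See [seg_config()].
#' @param clbp See [clbp_config()].
#' @param distances Correlogram distance set.
#' @param svm See [svm_config()].
#' @param vote See [vote_rule()].
#' @return Named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1, rescale = TRUE, n_patches = 20,
                            patch_size = 512, I0 = 255, lambda = 0.2,
                            stain = list(), seg = seg_config(),
                            clbp = clbp_config(), distances = c(1, 3),
                            svm = svm_config(), vote = NULL) {
  if (is.null(vote)) vote <- vote_rule(n_patches, n_patches %/% 2)
  structure(list(seed = seed, rescale = rescale, n_patches = n_patches,
                 patch_size = patch_size, I0 = I0, lambda = lambda,
                 stain = stain, seg = seg, clbp = clbp,
                 distances = distances, svm = svm, vote = vote),
            class = "pipeline_config")
}

# Segment one image and extract fused features for all its patches.
pipeline_image_features <- function(img, id, label, config, patch_seed) {
  if (config$rescale) img <- rescale_half(img)
  seg <- segment_nuclei(
    img,
    stain_cfg = c(list(lambda = config$lambda, I0 = config$I0,
                       seed = patch_seed), config$stain),
    seg_cfg = config$seg
  )
  recs <- random_patches(seg$nuclei, n = config$n_patches,
                         size = config$patch_size, seed = patch_seed,
                         parent_id = id, label = label)
  feats <- t(vapply(recs, function(rec) {
    fore_patch <- seg$foreground[(rec$y0 + 1):(rec$y0 + config$patch_size),
                                 (rec$x0 + 1):(rec$x0 + config$patch_size), ,
                                 drop = FALSE]
    patch_features(rec$patch, fore_patch, config$clbp, config$distances)
  }, numeric(118 + 64 * length(config$distances))))
  data.frame(image_id = id, patch_index = seq_len(config$n_patches) - 1L,
             label = label, feats, check.names = FALSE)
}

#' Run the full recognition pipeline
#'
#' Accepts either an in-memory dataset from [make_dataset()] or a
#' manifest CSV plus image directory, runs segmentation and feature
#' extraction on every image, trains the RBF-SVM on the training split,
#' predicts the test split patch-wise, aggregates image labels by
#' majority vote, and evaluates both modes. Fully determined by
#' `(inputs, config)`.
#'
#' @param dataset Result of [make_dataset()] (`list(entries, manifest)`),
#'   or `NULL` when `manifest_path` is given.
#' @param config See [pipeline_config()].
#' @param manifest_path Optional manifest CSV (columns `image_path`,
#'   `label`, `split`); paths are resolved relative to `image_dir`.
#' @param image_dir Base directory for manifest paths.
#' @return A results bundle: patch- and image-wise `metrics_report`s and
#'   ROC/AUC, the confusion counts, and per-patch / per-image prediction
#'   tables.
#' @export
run_pipeline <- function(dataset = NULL, config = pipeline_config(),
                         manifest_path = NULL, image_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(manifest_path)) {
      stop("run_pipeline: provide a dataset or a manifest_path")
    }
    manifest <- read_manifest(manifest_path)
    entries <- lapply(seq_len(nrow(manifest)), function(i) {
      p <- file.path(image_dir, manifest$image_path[i])
      if (!file.exists(p)) {
        stop("run_pipeline: image listed in manifest not found: ", p)
      }
      list(id = tools::file_path_sans_ext(basename(p)),
           label = manifest$label[i], split = manifest$split[i],
           image = load_image(p))
    })
  } else {
    entries <- dataset$entries
  }
  n <- length(entries)
  if (n == 0) stop("run_pipeline: empty dataset")
  img_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max - 1L, n))

  feats <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    feats[[i]] <- pipeline_image_features(e$image, e$id, e$label, config,
                                          img_seeds[i])
  }
  splits <- vapply(entries, function(e) e$split, "")
  meta_cols <- c("image_id", "patch_index", "label")
  train_df <- do.call(rbind, feats[splits == "train"])
  test_df <- do.call(rbind, feats[splits == "test"])
  if (is.null(train_df) || is.null(test_df)) {
    stop("run_pipeline: need both train and test splits")
  }
  xcols <- setdiff(names(train_df), meta_cols)
  scaler <- fit_scaler(as.matrix(train_df[, xcols]))
  xtr <- apply_scaler(scaler, as.matrix(train_df[, xcols]))
  xte <- apply_scaler(scaler, as.matrix(test_df[, xcols]))
  model <- train_svm(xtr, train_df$label, config$svm, seed = config$seed)
  pred <- predict_patches(model, xte)

  patch_tab <- data.frame(image_id = test_df$image_id,
                          patch_index = test_df$patch_index,
                          label = test_df$label,
                          predicted = pred$labels, score = pred$scores,
                          stringsAsFactors = FALSE)
  ids <- unique(patch_tab$image_id)
  image_tab <- do.call(rbind, lapply(ids, function(id) {
    sub <- patch_tab[patch_tab$image_id == id, ]
    data.frame(image_id = id, label = sub$label[1],
               predicted = majority_vote(sub$predicted, config$vote),
               score = image_score(sub$score, config$vote$patches_per_image),
               stringsAsFactors = FALSE)
  }))

  patch_cc <- confusion(patch_tab$label, patch_tab$predicted)
  image_cc <- confusion(image_tab$label, image_tab$predicted)
  list(
    patch_metrics = classification_metrics(patch_cc),
    image_metrics = classification_metrics(image_cc),
    patch_confusion = patch_cc,
    image_confusion = image_cc,
    patch_roc = roc_auc(patch_tab$score, patch_tab$label),
    image_roc = roc_auc(image_tab$score, image_tab$label),
    patch_predictions = patch_tab,
    image_predictions = image_tab,
    config = config
  )
}
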