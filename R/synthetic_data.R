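# Synthetic H&E image generator: the Beer-Lambert forward model with known
# stain vectors, so stain recovery, segmentation and end-to-end
# classification all have exact ground truth.
#
# Nuclei are random ellipses carrying hematoxylin density (feathered
# edges); the stroma outside nuclei carries eosin density. Carcinoma-like
# scenes are dense and pleomorphic (many nuclei, high size variance,
# overlaps allowed); non-carcinoma-like scenes are sparse and regular.

#' Reference H&E stain matrix
#'
#' Hematoxylin proportional to (0.65, 0.70, 0.29) and eosin to
#' (0.07, 0.99, 0.11) in OD space, unit-normalized (the classic H&E
#' reference vectors); the angle between the columns is about 40 degrees.
#'
#' @return A `stain_model`.
#' @export
make_stain_matrix <- function() {
  stain_model(cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11)),
              c("hematoxylin", "eosin"))
}

#' Scene specification for the synthetic generator
#'
#' @param image_size `c(height, width)` in pixels (default 512 x 512).
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range Semi-major axis range in pixels.
#' @param eccentricity_range Ellipse eccentricity range in `[0, 1)`.
#' @param overlap_fraction Maximum allowed pairwise overlap, as a
#'   fraction of the smaller nucleus area.
#' @param hematoxylin_density Peak hematoxylin OD inside nuclei.
#' @param eosin_background_density Eosin OD of the stroma outside nuclei.
#' @param noise_sd Gaussian noise s.d. added to the OD density maps.
#' @param baseline_h Small hematoxylin baseline everywhere (residual
#'   stain uptake).
#' @param feather_sigma Gaussian falloff of nucleus edges in pixels.
#' @param class_label `"carcinoma"` or `"non-carcinoma"` style scene.
#' @param seed RNG seed.
#' @return Named list (class `scene_spec`).
#' @export
scene_spec <- function(image_size = c(512, 512), n_nuclei = 25,
                       radius_range = c(10, 18),
                       eccentricity_range = c(0, 0.6),
                       overlap_fraction = 0,
                       hematoxylin_density = 0.85,
                       eosin_background_density = 0.25,
                       noise_sd = 0.01, baseline_h = 0.02,
                       feather_sigma = 2,
                       class_label = "non-carcinoma", seed = 1) {
  stopifnot(all(radius_range > 0),
            max(radius_range) < min(image_size) / 4,
            all(eccentricity_range >= 0), all(eccentricity_range < 1),
            overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(image_size = image_size, n_nuclei = n_nuclei,
                 radius_range = radius_range,
                 eccentricity_range = eccentricity_range,
                 overlap_fraction = overlap_fraction,
                 hematoxylin_density = hematoxylin_density,
                 eosin_background_density = eosin_background_density,
                 noise_sd = noise_sd, baseline_h = baseline_h,
                 feather_sigma = feather_sigma,
                 class_label = class_label, seed = seed),
            class = "scene_spec")
}

# Rasterize one ellipse into a logical matrix restricted to its bounding
# box; returns the pixel index vector.
ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  ext <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
  cc <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
  ry <- rep(rr, times = length(cc)) - cy
  rx <- rep(cc, each = length(rr)) - cx
  u <- ry * ct + rx * st
  v <- -ry * st + rx * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- (rep(cc, each = length(rr)) - 1L) * h + rep(rr, times = length(cc))
  idx[inside]
}

#' Generate a synthetic scene with ground truth
#'
#' Places `n_nuclei` random ellipses with rejection-controlled pairwise
#' overlap, builds the true density maps (hematoxylin inside nuclei with
#' feathered edges plus a small baseline, eosin outside), adds Gaussian
#' OD noise, and records the exact stain matrix. Reproducible per seed.
#'
#' @param spec A [scene_spec()].
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return `list(mask, instance_mask, W_true, H_true, class_label, spec)`
#'   where `H_true` is the `2 x n` true density matrix.
#' @export
make_scene <- function(spec, max_tries = 400) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    inst <- matrix(0L, h, w)
    areas <- integer(0)
    placed <- 0L
    for (i in seq_len(spec$n_nuclei)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
        e <- stats::runif(1, spec$eccentricity_range[1],
                          spec$eccentricity_range[2])
        b <- a * sqrt(1 - e^2)
        theta <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, a + 2, h - a - 2)
        cx <- stats::runif(1, a + 2, w - a - 2)
        idx <- ellipse_pixels(h, w, cy, cx, a, b, theta)
        if (length(idx) < 4) next
        hit <- inst[idx]
        ov_ids <- unique(hit[hit > 0])
        ok_overlap <- TRUE
        for (id in ov_ids) {
          inter <- sum(hit == id)
          frac <- inter / min(length(idx), areas[id])
          if (frac > spec$overlap_fraction) { ok_overlap <- FALSE; break }
        }
        if (!ok_overlap) next
        placed <- placed + 1L
        inst[idx] <- placed
        areas <- c(areas, length(idx))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("make_scene: could not place nucleus ", i, " after ",
             max_tries, " tries (packing too dense)")
      }
    }
    mask <- (inst > 0) * 1L
    hmap <- spec$baseline_h +
      spec$hematoxylin_density * gauss_blur(mask, spec$feather_sigma)
    emap <- spec$eosin_background_density *
      gauss_blur(1 - mask, spec$feather_sigma)
    if (spec$noise_sd > 0) {
      hmap <- hmap + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      emap <- emap + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    H_true <- rbind(pmax(c(hmap), 0), pmax(c(emap), 0))
    list(mask = mask, instance_mask = inst,
         W_true = make_stain_matrix(), H_true = H_true,
         class_label = spec$class_label, spec = spec)
  })
}

#' Render a synthetic scene to an 8-bit RGB image
#'
#' The exact Beer-Lambert inverse: `I = round(I0 * exp(-W_true H_true))`.
#'
#' @param gt Ground truth from [make_scene()].
#' @param I0 Reference intensity.
#' @return Integer RGB array.
#' @export
render_rgb <- function(gt, I0 = 255) {
  V <- gt$W_true$W %*% gt$H_true
  od_to_rgb(V, I0, dim_hw = gt$spec$image_size)
}

#' Default class parameter distributions for [make_dataset()]
#'
#' Carcinoma-like scenes are dense and pleomorphic (60-90 nuclei, wide
#' size range, pairwise overlap up to 0.4); non-carcinoma-like scenes are
#' sparse and regular (15-30 nuclei, narrow size range, overlap at most
#' 0.1).
#'
#' @return Named list of per-class sampling ranges.
#' @export
synthetic_class_params <- function() {
  list(
    carcinoma = list(n_nuclei = c(60, 90), radius_range = c(6, 26),
                     eccentricity_range = c(0, 0.8),
                     overlap_fraction = 0.4),
    `non-carcinoma` = list(n_nuclei = c(15, 30), radius_range = c(10, 16),
                           eccentricity_range = c(0, 0.4),
                           overlap_fraction = 0.1)
  )
}

#' Generate a balanced labeled synthetic dataset
#'
#' `n_per_class` images per class, each with its own scene seed derived
#' from `seed`; `test_fraction` of each class (the tail) is marked as the
#' test split in the manifest. When `dir` is given, images, masks and the
#' manifest CSV are written to disk.
#'
#' @param n_per_class Images per class.
#' @param class_params See [synthetic_class_params()].
#' @param seed Master seed.
#' @param test_fraction Fraction of each class assigned to the test
#'   split (default 0.5).
#' @param image_size Passed to [scene_spec()].
#' @param dir Optional output directory.
#' @return `list(entries, manifest)`: each entry has `id`, `label`,
#'   `split`, `image`, `gt`.
#' @export
make_dataset <- function(n_per_class = 20,
                         class_params = synthetic_class_params(),
                         seed = 1, test_fraction = 0.5,
                         image_size = c(512, 512), dir = NULL) {
  n_total <- 2L * n_per_class
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  draws <- with_seed(seed + 1L, {
    matrix(stats::runif(n_total * 4), n_total, 4)
  })
  entries <- vector("list", n_total)
  i <- 0L
  for (cls in names(class_params)) {
    cp <- class_params[[cls]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      u <- draws[i, ]
      spec <- scene_spec(
        image_size = image_size,
        n_nuclei = round(cp$n_nuclei[1] + u[1] * diff(cp$n_nuclei)),
        radius_range = cp$radius_range,
        eccentricity_range = cp$eccentricity_range,
        overlap_fraction = cp$overlap_fraction,
        class_label = cls,
        seed = seeds[i]
      )
      gt <- make_scene(spec)
      split <- if (j > n_per_class * (1 - test_fraction)) "test" else "train"
      entries[[i]] <- list(id = sprintf("%s_%02d", gsub("-", "", cls), j),
                           label = cls, split = split,
                           image = render_rgb(gt), gt = gt)
    }
  }
  manifest <- data.frame(
    image_path = vapply(entries, function(e) paste0(e$id, ".png"), ""),
    label = vapply(entries, function(e) e$label, ""),
    split = vapply(entries, function(e) e$split, ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (e in entries) {
      write_image(e$image, file.path(dir, paste0(e$id, ".png")))
      write_mask(e$gt$mask, file.path(dir, paste0(e$id, "_mask.png")))
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    gt_json <- list(stain_matrix = make_stain_matrix()$W,
                    images = lapply(entries, function(e) {
                      list(id = e$id, label = e$label,
                           n_nuclei = max(e$gt$instance_mask),
                           seed = e$gt$spec$seed)
                    }))
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(entries = entries, manifest = manifest)
}
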