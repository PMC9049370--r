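# Stage 2: nuclei segmentation on the stain-separated foreground image.
# Frequency-tuned saliency -> corner denoising -> Sobel gradient ->
# morphological-reconstruction markers -> marker-controlled watershed.

#' Frequency-tuned saliency map
#'
#' `S(x, y) = || I_mu - I_whc(x, y) ||_2` in CIELab, where `I_mu` is the
#' mean Lab vector of the image and `I_whc` the image after smoothing with
#' a 5x5 binomial kernel, converted to Lab. The map is min-max normalized
#' to `[0, 1]`; constant images give an all-zero map.
#'
#' @param img RGB array `H x W x 3` in `[0, 255]`.
#' @return An `H x W` matrix in `[0, 1]`.
#' @export
ft_saliency <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb01 <- cbind(c(img[, , 1]), c(img[, , 2]), c(img[, , 3])) / 255
  lab_mu <- colMeans(grDevices::convertColor(rgb01, from = "sRGB", to = "Lab"))

  b <- c(1, 4, 6, 4, 1) / 16                     # 5x5 binomial, separable
  kr <- matrix(0, 5, 5); kr[, 3] <- b
  kc <- matrix(0, 5, 5); kc[3, ] <- b
  blur <- vapply(1:3, function(ch) {
    conv2_reflect(conv2_reflect(img[, , ch], kr), kc)
  }, matrix(0, h, w))
  blur01 <- clamp(cbind(c(blur[, , 1]), c(blur[, , 2]), c(blur[, , 3])) / 255,
                  0, 1)
  lab_b <- grDevices::convertColor(blur01, from = "sRGB", to = "Lab")
  s <- sqrt((lab_b[, 1] - lab_mu[1])^2 + (lab_b[, 2] - lab_mu[2])^2 +
            (lab_b[, 3] - lab_mu[3])^2)
  s <- matrix(s, h, w)
  rng <- range(s)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, h, w))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Remove small blobs in the image corners
#'
#' Deletes 4-connected components whose bounding box intersects any of
#' the four `corner_window` x `corner_window` corner squares and whose
#' area is at most `max_blob` pixels; everything else is untouched.
#'
#' @param mask Binary matrix (0/1).
#' @param corner_window Corner square side in pixels (default 32).
#' @param max_blob Maximum area (pixels^2) of a deletable blob
#'   (default 200).
#' @return Cleaned binary matrix.
#' @export
remove_corner_noise <- function(mask, corner_window = 32, max_blob = 200) {
  stopifnot(is_binary_mask(mask))
  if (!any(mask > 0)) return(mask)
  lab <- EBImage::bwlabel(mask)
  k <- max(lab)
  if (k == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  rmin <- tapply(idx[, 1], lv, min); rmax <- tapply(idx[, 1], lv, max)
  cmin <- tapply(idx[, 2], lv, min); cmax <- tapply(idx[, 2], lv, max)
  area <- tabulate(lv, k)
  cw <- corner_window
  # bbox intersects a corner square iff it reaches both the row band and
  # the column band of that corner
  top    <- rmin <= cw;     bot   <- rmax >= h - cw + 1
  left   <- cmin <= cw;     right <- cmax >= w - cw + 1
  in_corner <- (top & left) | (top & right) | (bot & left) | (bot & right)
  drop <- which(in_corner & area <= max_blob)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel operator, `sqrt(Gx^2 + Gy^2)`, with reflected borders.
#'
#' @param gray Numeric matrix (single channel).
#' @return Gradient magnitude matrix of the same size.
#' @export
gradient_magnitude <- function(gray) {
  stopifnot(is.matrix(gray))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dcol
  sy <- t(sx)                                           # d/drow
  gx <- conv2_reflect(gray, sx)
  gy <- conv2_reflect(gray, sy)
  sqrt(gx^2 + gy^2)
}

# Grayscale morphological reconstruction by dilation: geodesic dilation of
# `marker` under `mask` iterated to stability (3x3 elementary dilations).
# EBImage grayscale morphology clamps to [0, 1], so both images are mapped
# affinely into [0, 1] for the iteration and mapped back at the end.
reconstruct_dilate <- function(marker, mask, max_iter = 512) {
  stopifnot(all(marker <= mask + 1e-9))
  lo <- min(marker); hi <- max(mask)
  if (hi - lo < 1e-12) return(pmin(marker, mask))
  sc <- function(x) (x - lo) / (hi - lo)
  box <- EBImage::makeBrush(3, "box")
  mk <- pmin(sc(marker), sc(mask))
  msk <- sc(mask)
  tol <- 1e-9 / (hi - lo)
  for (i in seq_len(max_iter)) {
    m2 <- pmin(EBImage::dilate(mk, box), msk)
    if (max(abs(m2 - mk)) < tol) { mk <- m2; break }
    mk <- m2
  }
  mk * (hi - lo) + lo
}

# Regional maxima via h-maxima with h = 1 on the 0..255 scale: pixels
# whose peak survives suppression of maxima shallower than h.
regional_maxima <- function(x, h = 1) {
  rec <- reconstruct_dilate(x - h, x)
  (x - rec) > h / 2
}

#' Segmentation configuration
#'
#' Tunable parameters of the marker and watershed stages, with defaults
#' calibrated at the 512x512 patch scale.
#'
#' @param s_min Saliency gate for foreground markers (default 0.1).
#' @param corner_window,max_blob Corner denoising parameters.
#' @param se_radius Disk radius of the reconstruction structuring element
#'   at 512x512 scale; scaled proportionally for other sizes (default 5).
#' @param h_max Regional-maxima depth on the 0..255 gray scale (default
#'   10): maxima shallower than `h_max` merge with their surroundings,
#'   suppressing noise-induced marker splits.
#' @param prop_lambda Spatial regularization of the gradient flooding
#'   (default 1e-4; larger values weight distance over gradient).
#' @return A named list of parameters.
#' @export
seg_config <- function(s_min = 0.1, corner_window = 32, max_blob = 200,
                       se_radius = 5, h_max = 10, prop_lambda = 1e-4) {
  list(s_min = s_min, corner_window = corner_window, max_blob = max_blob,
       se_radius = se_radius, h_max = h_max, prop_lambda = prop_lambda)
}

#' Compute watershed markers on the foreground image
#'
#' Foreground markers are the regional maxima of the
#' opening-by-reconstruction followed by closing-by-reconstruction of the
#' inverted grayscale foreground (disk radius `se_radius`, scaled to the
#' image size), gated by `saliency >= s_min` and cleaned by
#' [remove_corner_noise()]. Background markers are the ridge lines of the
#' influence zones of the Otsu-binarized nuclei mask (the watershed of its
#' distance transform). The two sets are disjoint by construction.
#'
#' @param fore Stain-separated foreground RGB array.
#' @param saliency Saliency map from [ft_saliency()] (same grid).
#' @param config See [seg_config()].
#' @return An object of class `marker_set`:
#'   `list(foreground_markers, background_markers)` binary matrices.
#' @export
compute_markers <- function(fore, saliency, config = seg_config()) {
  stopifnot(all(dim(fore)[1:2] == dim(saliency)))
  gray <- luminance(fore)
  h <- nrow(gray); w <- ncol(gray)
  inv <- (255 - gray) / 255              # [0,1]: EBImage morphology range

  r_se <- max(1L, round(config$se_radius * min(h, w) / 512))
  brush <- EBImage::makeBrush(2L * r_se + 1L, "disc")
  obr <- reconstruct_dilate(EBImage::erode(inv, brush), inv)
  tmp <- 1 - obr
  cbr <- 1 - reconstruct_dilate(EBImage::erode(tmp, brush), tmp)

  fg <- regional_maxima(cbr, config$h_max / 255) & (saliency >= config$s_min)
  fg <- remove_corner_noise(fg * 1L, config$corner_window, config$max_blob)
  if (!any(fg > 0)) {
    stop("compute_markers: no foreground markers found ",
         "(image may contain no nuclei; saliency gate s_min = ",
         config$s_min, ")")
  }

  th <- EBImage::otsu(clamp(gray / 255, 0, 1))
  nmask <- (gray / 255 < th) * 1L          # nuclei are dark on the foreground
  if (!any(nmask > 0)) nmask <- fg
  d <- EBImage::distmap(1L - nmask)        # distance to the nearest nucleus
  d <- d / max(d, 1)
  zones <- EBImage::propagate(d, EBImage::bwlabel(nmask), lambda = 1e4)
  bg <- ridge_pixels(zones)
  if (!any(bg)) bg <- (d == max(d)) & (d > 0)
  bg <- bg & !(fg > 0) & !(nmask > 0)
  structure(list(foreground_markers = fg,
                 background_markers = bg * 1L),
            class = "marker_set")
}

# Pixels whose 4-neighborhood contains two different positive labels.
ridge_pixels <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  r <- matrix(FALSE, h, w)
  r[-h, ] <- r[-h, ] | (lab[-h, ] != lab[-1, ] & lab[-h, ] > 0 & lab[-1, ] > 0)
  r[-1, ] <- r[-1, ] | (lab[-1, ] != lab[-h, ] & lab[-1, ] > 0 & lab[-h, ] > 0)
  r[, -w] <- r[, -w] | (lab[, -w] != lab[, -1] & lab[, -w] > 0 & lab[, -1] > 0)
  r[, -1] <- r[, -1] | (lab[, -1] != lab[, -w] & lab[, -1] > 0 & lab[, -w] > 0)
  r
}

#' Marker-controlled watershed of a gradient image
#'
#' Floods the gradient landscape from the foreground marker components
#' (seeded geodesic flooding, which realizes minima imposition at the
#' markers) with one extra seed covering the background markers. The
#' number of nucleus labels always equals the number of 4-connected
#' foreground marker components; background-seeded catchment pixels are 0.
#'
#' @param gradient Gradient magnitude matrix.
#' @param markers A `marker_set` from [compute_markers()].
#' @param prop_lambda Spatial regularization (see [seg_config()]).
#' @return Integer label matrix with labels `1..K` and 0 for background.
#' @export
watershed_segment <- function(gradient, markers, prop_lambda = 1e-4) {
  stopifnot(inherits(markers, "marker_set"))
  fgl <- EBImage::bwlabel(markers$foreground_markers)
  k <- max(fgl)
  if (k == 0) stop("watershed_segment: no foreground markers")
  seeds <- fgl
  seeds[markers$background_markers > 0 & fgl == 0] <- k + 1L
  g01 <- gradient / max(gradient, 1e-12)   # propagate expects [0,1]-scale
  lab <- EBImage::propagate(g01, seeds, lambda = prop_lambda)
  lab <- round(lab)
  lab[lab == k + 1L] <- 0L
  storage.mode(lab) <- "integer"
  lab
}

#' Two-stage nuclei segmentation of an H&E image
#'
#' Runs the full chain: stain separation (SNMF), frequency-tuned saliency
#' on the hematoxylin foreground, Sobel gradient, marker extraction and
#' marker-controlled watershed. Deterministic for fixed inputs and seed.
#'
#' @param img RGB array `H x W x 3`.
#' @param stain_cfg Named list passed to [estimate_stains()]
#'   (`lambda`, `I0`, `seed`, ...).
#' @param seg_cfg See [seg_config()].
#' @return `list(labels, nuclei, foreground, background, saliency,
#'   markers)`: `labels` is the nucleus label mask, `nuclei` the
#'   foreground image whitened outside nuclei.
#' @export
segment_nuclei <- function(img, stain_cfg = list(), seg_cfg = seg_config()) {
  I0 <- if (is.null(stain_cfg$I0)) 255 else stain_cfg$I0
  sep <- tryCatch({
    args <- c(list(img = img), stain_cfg)
    do.call(separate_image, args)
  }, error = function(e) stop_stage("stain_separation", e))
  sal <- tryCatch(ft_saliency(sep$foreground),
                  error = function(e) stop_stage("saliency", e))
  grad <- tryCatch(gradient_magnitude(luminance(sep$foreground)),
                   error = function(e) stop_stage("gradient", e))
  markers <- tryCatch(compute_markers(sep$foreground, sal, seg_cfg),
                      error = function(e) stop_stage("markers", e))
  labels <- tryCatch(watershed_segment(grad, markers, seg_cfg$prop_lambda),
                     error = function(e) stop_stage("watershed", e))
  nuclei <- sep$foreground
  outside <- labels == 0L
  for (ch in 1:3) {
    m <- nuclei[, , ch]
    m[outside] <- 255L
    nuclei[, , ch] <- m
  }
  list(labels = labels, nuclei = nuclei, foreground = sep$foreground,
       background = sep$background, saliency = sal, markers = markers,
       model = sep$model)
}
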