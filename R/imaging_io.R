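# Image and mask I/O plus the preprocessing applied to whole-slide crops:
# 0.5x rescaling and random 512x512 patch extraction.
#
# Conventions: an RGB image is an integer array H x W x 3 with values in
# [0, 255], indexed (row, column) = (y, x), 0-based pixel coordinates in
# patch records. Masks are integer matrices (0/1 binary masks, or label
# masks with 0 = background/ridge).

#' Read an RGB image from disk
#'
#' Reads a PNG, TIFF or JPEG image and returns an 8-bit RGB array.
#' Grayscale images are replicated to 3 channels; an alpha channel, if
#' present, is dropped. 16-bit sources are reduced to 8 bits by integer
#' division by 257. No color-profile transforms are applied.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return An integer array `H x W x 3` with values in `[0, 255]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("load_image: file not found: ", path)
  }
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop("load_image: unreadable image file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) {
    d <- array(rep(d, 3L), dim = c(dim(d), 3L))
  } else if (dim(d)[3] > 3L) {
    d <- d[, , 1:3, drop = FALSE]
  } else if (dim(d)[3] < 3L) {
    d <- array(rep(d[, , 1], 3L), dim = c(dim(d)[1:2], 3L))
  }
  if (any(!is.finite(d)) || any(dim(d)[1:2] < 1L)) {
    stop("load_image: corrupt image data in ", path)
  }
  # EBImage normalizes to [0,1]; recover the integer code and reduce a
  # 16-bit code to 8 bits by %/% 257 (exact identity for 8-bit sources).
  v16 <- round(clamp(d, 0, 1) * 65535)
  out <- aperm(v16 %/% 257, c(2, 1, 3))
  storage.mode(out) <- "integer"
  out
}

#' Write an RGB image to disk
#'
#' @param img Integer array `H x W x 3`, values in `[0, 255]`.
#' @param path Output path; format chosen from the extension
#'   (png/tif/tiff/jpg/jpeg).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  x <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(x, path, quality = 100)
  invisible(path)
}

#' Downscale an image by a factor of two
#'
#' Bilinear 0.5x rescaling, realized exactly as the mean of each 2x2 pixel
#' block (the bilinear kernel at half resolution with pixel-center
#' alignment), rounded half up. Odd trailing rows/columns are dropped.
#'
#' @param img Integer array `H x W x 3`.
#' @return Integer array `floor(H/2) x floor(W/2) x 3`.
#' @export
rescale_half <- function(img) {
  stopifnot(length(dim(img)) == 3L)
  h2 <- dim(img)[1] %/% 2L
  w2 <- dim(img)[2] %/% 2L
  stopifnot(h2 >= 1L, w2 >= 1L)
  ro <- seq_len(h2) * 2L - 1L
  co <- seq_len(w2) * 2L - 1L
  out <- array(0L, dim = c(h2, w2, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    s <- (m[ro, co, drop = FALSE] + m[ro + 1L, co, drop = FALSE] +
          m[ro, co + 1L, drop = FALSE] + m[ro + 1L, co + 1L, drop = FALSE])
    out[, , ch] <- as.integer(floor(s / 4 + 0.5))
  }
  out
}

#' Randomly crop patches from an image
#'
#' Draws `n` top-left corners uniformly (with replacement) over the valid
#' range and returns verbatim sub-arrays. Bit-reproducible for a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param img Integer array `H x W x 3`.
#' @param n Number of patches (default 20).
#' @param size Patch side length in pixels (default 512).
#' @param seed Integer RNG seed (required).
#' @param parent_id Identifier recorded in each patch record.
#' @param label Class label inherited by every patch
#'   (`"carcinoma"`, `"non-carcinoma"` or `NA`).
#' @return A list of `n` patch records: `patch` (array `size x size x 3`),
#'   `parent_id`, `patch_index` (0-based), `label`, and the 0-based corner
#'   `(y0, x0)`.
#' @export
random_patches <- function(img, n = 20, size = 512, seed,
                           parent_id = "image", label = NA_character_) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < size || w < size) {
    stop("random_patches: image ", h, "x", w,
         " is smaller than patch size ", size)
  }
  corners <- with_seed(seed, {
    y0 <- sample.int(h - size + 1L, n, replace = TRUE) - 1L
    x0 <- sample.int(w - size + 1L, n, replace = TRUE) - 1L
    cbind(y0, x0)
  })
  lapply(seq_len(n), function(i) {
    y0 <- corners[i, 1]; x0 <- corners[i, 2]
    list(patch = img[(y0 + 1):(y0 + size), (x0 + 1):(x0 + size), , drop = FALSE],
         parent_id = parent_id, patch_index = i - 1L,
         label = label, y0 = y0, x0 = x0)
  })
}

#' Write a binary or label mask losslessly
#'
#' Masks with values up to 255 are written as 8-bit PNG; masks with up to
#' 65535 labels as 16-bit TIFF (the available PNG writer is 8-bit only).
#' The round trip through [read_mask()] is exact.
#'
#' @param mask Integer matrix of non-negative labels (0 = background).
#' @param path Output path: `.png` for 8-bit masks, `.tif`/`.tiff` for
#'   16-bit label masks.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || any(mask != floor(mask)) || any(mask < 0)) {
    stop("write_mask: mask must be a matrix of non-negative integers")
  }
  mx <- max(mask, 0)
  if (mx > 65535) stop("write_mask: more than 65535 labels cannot be stored")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (mx > 255) {
      stop("write_mask: >255 labels need a 16-bit container; use .tif")
    }
    png::writePNG(mask / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else {
    stop("write_mask: unsupported extension '", ext, "' (use png or tif)")
  }
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path Path to a PNG (8-bit) or TIFF (16-bit) mask.
#' @return Integer matrix of labels.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("read_mask: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    out <- round(v * 255)
  } else if (ext %in% c("tif", "tiff")) {
    v <- tiff::readTIFF(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    out <- round(v * 65535)
  } else {
    stop("read_mask: unsupported extension '", ext, "'")
  }
  storage.mode(out) <- "integer"
  out
}

#' Read or write a dataset manifest
#'
#' The manifest is a CSV with columns `image_path`,
#' `label` (carcinoma | non-carcinoma) and `split` (train | test).
#'
#' @param path CSV path.
#' @return A data frame with the three manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "label", "split")
  if (!all(need %in% names(m))) {
    stop("read_manifest: manifest must have columns ",
         paste(need, collapse = ", "))
  }
  m
}

#' @rdname read_manifest
#' @param manifest Data frame with columns `image_path`, `label`, `split`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
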