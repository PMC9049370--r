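# Completed local binary pattern (CLBP) texture descriptors and color
# auto-correlograms, fused into the 246-dimensional patch feature.
#
# CLBP decomposes the local differences around each pixel into a sign
# code (S), a magnitude code (M) and a center bit (C):
#   S = sum_p s(g_p - g_c) 2^p,   M = sum_p s(D_p - D_c) 2^p,
#   C = s(g_c - g_N),   s(x) = 1 if x >= 0 else 0,
# with D_p = |g_p - g_c|, D_c a magnitude threshold (per-pixel mean of
# D_p by default, image-wide mean optionally) and g_N the mean center
# gray. With P = 8, R = 1 the uniform-pattern (u2) histograms of S and M
# have 59 bins each, giving the 118-dimensional texture block.

#' CLBP configuration
#'
#' @param P Sampling points on the circle (default 8).
#' @param R Circle radius in pixels (default 1).
#' @param magnitude_threshold_mode `"local"` (per-pixel mean of the
#'   neighbor magnitudes, the default) or `"global"` (image-wide mean,
#'   the classic convention).
#' @return A named list.
#' @export
clbp_config <- function(P = 8, R = 1,
                        magnitude_threshold_mode = c("local", "global")) {
  stopifnot(P >= 4, R >= 1)
  list(P = as.integer(P), R = R,
       magnitude_threshold_mode = match.arg(magnitude_threshold_mode))
}

# Circle sampling offsets (row, col) for p = 0..P-1; near-integer offsets
# snapped so axis-aligned neighbors are sampled exactly.
clbp_offsets <- function(P, R) {
  p <- 0:(P - 1)
  ang <- 2 * pi * p / P
  dc <- R * cos(ang)
  dr <- -R * sin(ang)
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  cbind(dr = snap(dr), dc = snap(dc))
}

# Bilinearly sample `gray` at (centers + offset) for all valid centers at
# once. `rows`, `cols` index the valid center block.
sample_neighbors <- function(gray, rows, cols, dr, dc) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0;   fc <- dc - c0
  r1 <- if (fr > 0) r0 + 1 else r0   # keep indices in range for integral
  c1 <- if (fc > 0) c0 + 1 else c0   # offsets (their weight is zero)
  blk <- function(ar, ac) gray[rows + ar, cols + ac, drop = FALSE]
  (1 - fr) * (1 - fc) * blk(r0, c0) +
  (1 - fr) * fc       * blk(r0, c1) +
  fr       * (1 - fc) * blk(r1, c0) +
  fr       * fc       * blk(r1, c1)
}

#' Per-pixel CLBP code maps
#'
#' Computes the S, M and C components for every interior pixel (centers
#' at distance >= `ceiling(R)` from the border). Neighbors are sampled on
#' the circle of radius `R` at angles `2*pi*p/P` with bilinear
#' interpolation.
#'
#' @param gray Numeric matrix of gray values.
#' @param cfg See [clbp_config()].
#' @return `list(S, M, C, P, valid_offset)`: `S` and `M` are integer
#'   matrices of codes in `[0, 2^P - 1]` over the valid region, `C` a 0/1
#'   matrix, `valid_offset` the border width excluded on each side.
#' @export
clbp_codes <- function(gray, cfg = clbp_config()) {
  stopifnot(is.matrix(gray))
  P <- cfg$P; R <- cfg$R
  b <- as.integer(ceiling(R))
  h <- nrow(gray); w <- ncol(gray)
  if (h - 2L * b < 1L || w - 2L * b < 1L) {
    stop("clbp_codes: image too small for radius ", R)
  }
  rows <- (b + 1L):(h - b)
  cols <- (b + 1L):(w - b)
  gc <- gray[rows, cols, drop = FALSE]
  off <- clbp_offsets(P, R)

  D <- vector("list", P)
  S <- matrix(0L, nrow(gc), ncol(gc))
  for (p in seq_len(P)) {
    gp <- sample_neighbors(gray, rows, cols, off[p, 1], off[p, 2])
    diffp <- gp - gc
    diffp[abs(diffp) < 1e-9] <- 0   # exact ties despite interpolation noise
    S <- S + as.integer(diffp >= 0) * 2L^(p - 1L)
    D[[p]] <- abs(diffp)
  }
  Dc <- if (cfg$magnitude_threshold_mode == "local") {
    Reduce(`+`, D) / P
  } else {
    mean(vapply(D, mean, 0))
  }
  M <- matrix(0L, nrow(gc), ncol(gc))
  for (p in seq_len(P)) {
    M <- M + as.integer(D[[p]] - Dc >= 0) * 2L^(p - 1L)
  }
  gN <- mean(gc)
  C <- (gc - gN >= 0) * 1L
  list(S = S, M = M, C = C, P = P, valid_offset = b)
}

.stainseg_env <- new.env(parent = emptyenv())

#' Uniform-pattern (u2) code-to-bin mapping
#'
#' Codes with at most two circular 0/1 transitions each get their own bin
#' (in increasing code order); all remaining codes share one final bin.
#' For `P = 8` this yields 58 + 1 = 59 bins.
#'
#' @param P Number of bits (<= 16).
#' @return Integer vector of length `2^P` mapping code -> 0-based bin,
#'   with attribute `n_bins`.
#' @export
uniform_mapping <- function(P) {
  stopifnot(P <= 16)
  key <- paste0("u2_", P)
  if (!is.null(.stainseg_env[[key]])) return(.stainseg_env[[key]])
  codes <- 0:(2^P - 1)
  bits <- sapply(0:(P - 1), function(b) bitwAnd(codes, bitwShiftL(1L, b)) > 0)
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  uniform <- which(trans <= 2)
  map <- integer(2^P)
  map[] <- length(uniform)            # shared non-uniform bin (0-based index)
  map[uniform] <- seq_along(uniform) - 1L
  attr(map, "n_bins") <- length(uniform) + 1L
  .stainseg_env[[key]] <- map
  map
}

#' CLBP texture descriptor
#'
#' Default layout: concatenation of the u2 histogram of the S codes and
#' the u2 histogram of the M codes, each L1-normalized, 59 + 59 = 118
#' dimensions for `P = 8` (the C bit is computed but not separately
#' histogrammed). The alternative layout (`joint_mc = TRUE`) is the joint
#' 59 x 2 histogram of (M bin, C bit), the same total length.
#'
#' @param codes Output of [clbp_codes()].
#' @param cfg See [clbp_config()].
#' @param joint_mc Use the joint M/C 59 x 2 histogram instead of the
#'   S + M concatenation (default `FALSE`).
#' @return Numeric vector of length `2 * (#u2 bins)` (118 for `P = 8`).
#' @export
clbp_descriptor <- function(codes, cfg = clbp_config(), joint_mc = FALSE) {
  map <- uniform_mapping(codes$P)
  nb <- attr(map, "n_bins")
  hist_of <- function(bins, n) {
    hh <- tabulate(bins, n)
    tot <- sum(hh)
    if (tot > 0) hh / tot else rep(0, n)
  }
  if (joint_mc) {
    bins <- map[codes$M + 1L] + 1L + nb * codes$C
    return(hist_of(bins, 2L * nb))
  }
  hS <- hist_of(map[codes$S + 1L] + 1L, nb)
  hM <- hist_of(map[codes$M + 1L] + 1L, nb)
  c(hS, hM)
}

#' CLBP descriptor of a gray image (convenience)
#'
#' @inheritParams clbp_codes
#' @inheritParams clbp_descriptor
#' @return Numeric vector (length 118 for the default configuration).
#' @export
clbp_features <- function(gray, cfg = clbp_config(), joint_mc = FALSE) {
  clbp_descriptor(clbp_codes(gray, cfg), cfg, joint_mc)
}

#' Quantize an RGB image to 64 colors
#'
#' Four uniform levels per channel:
#' `index = 16 * floor(R/64) + 4 * floor(G/64) + floor(B/64)`.
#'
#' @param img RGB array in `[0, 255]`.
#' @return Integer matrix of color indices in `[0, 63]` with attribute
#'   `palette_size = 64`.
#' @export
color_quantize <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  idx <- 16L * (img[, , 1] %/% 64L) + 4L * (img[, , 2] %/% 64L) +
    (img[, , 3] %/% 64L)
  storage.mode(idx) <- "integer"
  attr(idx, "palette_size") <- 64L
  idx
}

#' Color auto-correlogram
#'
#' For each color `c` and distance `k`, the probability that a pixel at
#' chessboard (L-infinity) distance exactly `k` from a pixel of color `c`
#' also has color `c`, estimated over all ordered pixel pairs. Border
#' pairs are normalized by the per-distance valid neighbor counts; colors
#' absent from the image contribute 0. The output is ordered color-major,
#' then distance: 64 colors x {1, 3} = 128 dimensions by default.
#'
#' @param indexed Color index matrix from [color_quantize()].
#' @param distances Set of chessboard distances (default `c(1, 3)`).
#' @return Numeric vector of length `palette_size * length(distances)`,
#'   entries in `[0, 1]`.
#' @export
auto_correlogram <- function(indexed, distances = c(1, 3)) {
  if (length(distances) == 0) {
    stop("auto_correlogram: empty distance set")
  }
  pal <- attr(indexed, "palette_size")
  if (is.null(pal)) pal <- 64L
  h <- nrow(indexed); w <- ncol(indexed)
  if (h < 1 || w < 1) stop("auto_correlogram: empty image")
  out <- matrix(0, pal, length(distances))
  for (di in seq_along(distances)) {
    k <- distances[di]
    same <- numeric(pal)
    tot <- numeric(pal)
    for (dr in -k:k) {
      dcs <- if (abs(dr) == k) -k:k else c(-k, k)
      for (dc in dcs) {
        ov <- shift_overlap(h, w, dr, dc)
        if (is.null(ov)) next
        a <- indexed[ov$rows, ov$cols, drop = FALSE]
        b <- indexed[ov$rows_shift, ov$cols_shift, drop = FALSE]
        tot <- tot + tabulate(a + 1L, pal)
        eq <- a == b
        if (any(eq)) same <- same + tabulate(a[eq] + 1L, pal)
      }
    }
    out[, di] <- ifelse(tot > 0, same / tot, 0)
  }
  v <- as.numeric(t(out))   # color-major, distance within color
  names(v) <- paste0("c", rep(0:(pal - 1), each = length(distances)),
                     "_k", rep(distances, pal))
  v
}

#' Fuse the texture and color blocks
#'
#' Concatenates the CLBP texture block and the auto-correlogram color
#' block in that order (118 + 128 = 246 by default).
#'
#' @param texture Numeric vector (CLBP block).
#' @param color Numeric vector (correlogram block).
#' @param texture_len,color_len Expected block lengths.
#' @return Numeric vector of length `texture_len + color_len`.
#' @export
fuse_features <- function(texture, color, texture_len = 118,
                          color_len = 128) {
  if (length(texture) != texture_len) {
    stop("fuse_features: texture block has length ", length(texture),
         ", expected ", texture_len)
  }
  if (length(color) != color_len) {
    stop("fuse_features: color block has length ", length(color),
         ", expected ", color_len)
  }
  c(texture, color)
}

#' Fused feature vector of one patch
#'
#' CLBP texture on the grayscale nuclei-segmented image (white background
#' pixels included in the valid region) fused with the color
#' auto-correlogram of the stain-separated foreground patch.
#'
#' @param nuclei_patch RGB array: foreground image whitened outside
#'   nuclei.
#' @param fore_patch RGB array: stain-separated foreground.
#' @param cfg CLBP configuration.
#' @param distances Correlogram distance set.
#' @return Numeric vector of length 246 (defaults).
#' @export
patch_features <- function(nuclei_patch, fore_patch, cfg = clbp_config(),
                           distances = c(1, 3)) {
  tex <- clbp_features(luminance(nuclei_patch), cfg)
  col <- auto_correlogram(color_quantize(fore_patch), distances)
  fuse_features(tex, col, length(tex), length(col))
}
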