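# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (report convention; base round() is half-even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ITU-R 601 luminance of an 8-bit RGB array; returns an H x W double matrix
# on the 0..255 scale.
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Reflect-pad a matrix by k pixels on every side (border handling for
# convolution kernels).
pad_reflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h > k, w > k)
  ri <- c((k + 1):2, 1:h, (h - 1):(h - k))
  ci <- c((k + 1):2, 1:w, (w - 1):(w - k))
  m[ri, ci]
}

# 2-D convolution (correlation) with a small odd-sized kernel, reflected
# borders. Kernel dims must be odd and equal.
conv2_reflect <- function(m, kernel) {
  kh <- nrow(kernel)
  stopifnot(kh == ncol(kernel), kh %% 2 == 1)
  k <- (kh - 1L) %/% 2L
  p <- pad_reflect(m, k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kh)) {
      if (kernel[a, b] != 0) {
        out <- out + kernel[a, b] * p[a:(a + h - 1L), b:(b + w - 1L)]
      }
    }
  }
  out
}

# Separable Gaussian blur with reflected borders (used for nucleus edge
# feathering in the synthetic generator).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  kern_r <- matrix(0, 2 * k + 1, 2 * k + 1); kern_r[, k + 1] <- g
  kern_c <- matrix(0, 2 * k + 1, 2 * k + 1); kern_c[k + 1, ] <- g
  conv2_reflect(conv2_reflect(m, kern_r), kern_c)
}

# Shift a matrix by (dr, dc), exposing only the valid overlap; returns the
# index ranges so callers can align the un-shifted matrix.
shift_overlap <- function(h, w, dr, dc) {
  r1 <- max(1L, 1L - dr); r2 <- min(h, h - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(w, w - dc)
  if (r1 > r2 || c1 > c2) return(NULL)
  list(rows = r1:r2, cols = c1:c2,
       rows_shift = (r1 + dr):(r2 + dr), cols_shift = (c1 + dc):(c2 + dc))
}

stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}
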