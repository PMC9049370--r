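# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementations.

# Literal per-pixel CLBP: loops over centers and sampling points,
# bilinear interpolation written out longhand.
clbp_oracle <- function(gray, P = 8, R = 1, mode = "local") {
  h <- nrow(gray); w <- ncol(gray); b <- ceiling(R)
  nr <- h - 2 * b; nc <- w - 2 * b
  S <- matrix(0L, nr, nc); M <- matrix(0L, nr, nc)
  Dstore <- array(0, c(nr, nc, P))
  sample_at <- function(yy, xx) {
    if (abs(yy - round(yy)) < 1e-9) yy <- round(yy)
    if (abs(xx - round(xx)) < 1e-9) xx <- round(xx)
    y0 <- floor(yy); x0 <- floor(xx)
    fy <- yy - y0; fx <- xx - x0
    y1 <- if (fy > 0) y0 + 1 else y0
    x1 <- if (fx > 0) x0 + 1 else x0
    (1 - fy) * (1 - fx) * gray[y0, x0] + (1 - fy) * fx * gray[y0, x1] +
      fy * (1 - fx) * gray[y1, x0] + fy * fx * gray[y1, x1]
  }
  for (yi in (b + 1):(h - b)) {
    for (xi in (b + 1):(w - b)) {
      gc <- gray[yi, xi]
      for (p in 0:(P - 1)) {
        ang <- 2 * pi * p / P
        gp <- sample_at(yi - R * sin(ang), xi + R * cos(ang))
        dp <- gp - gc
        if (abs(dp) < 1e-9) dp <- 0   # same tie convention as the package
        if (dp >= 0) S[yi - b, xi - b] <- S[yi - b, xi - b] + 2L^p
        Dstore[yi - b, xi - b, p + 1] <- abs(dp)
      }
    }
  }
  for (yi in seq_len(nr)) {
    for (xi in seq_len(nc)) {
      Dc <- if (mode == "local") mean(Dstore[yi, xi, ]) else mean(Dstore)
      for (p in 0:(P - 1)) {
        if (Dstore[yi, xi, p + 1] - Dc >= 0) {
          M[yi, xi] <- M[yi, xi] + 2L^p
        }
      }
    }
  }
  gN <- mean(gray[(b + 1):(h - b), (b + 1):(w - b)])
  C <- (gray[(b + 1):(h - b), (b + 1):(w - b), drop = FALSE] - gN >= 0) * 1L
  list(S = S, M = M, C = C)
}

# Exhaustive ordered-pair auto-correlogram on tiny images.
correlogram_oracle <- function(idx, distances, pal = 64) {
  h <- nrow(idx); w <- ncol(idx)
  coords <- expand.grid(r = seq_len(h), c = seq_len(w))
  out <- matrix(0, pal, length(distances))
  for (di in seq_along(distances)) {
    k <- distances[di]
    for (color in 0:(pal - 1)) {
      same <- 0; tot <- 0
      p1s <- which(idx == color)
      for (p1 in p1s) {
        r1 <- coords$r[p1]; c1 <- coords$c[p1]
        for (p2 in seq_len(h * w)) {
          d <- max(abs(coords$r[p2] - r1), abs(coords$c[p2] - c1))
          if (d == k) {
            tot <- tot + 1
            if (idx[p2] == color) same <- same + 1
          }
        }
      }
      out[color + 1, di] <- if (tot > 0) same / tot else 0
    }
  }
  as.numeric(t(out))
}

# Closed-form non-negative soft threshold for orthonormal designs.
soft_threshold_oracle <- function(v, W, lambda) {
  pmax(0, as.numeric(crossprod(W, v)) - lambda)
}

# Pairwise-comparison AUC estimator.
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == "carcinoma"]
  sn <- scores[labels != "carcinoma"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force Hausdorff on coordinate sets.
hausdorff_oracle <- function(X, Y) {
  px <- which(X > 0, arr.ind = TRUE)
  py <- which(Y > 0, arr.ind = TRUE)
  dmat <- sqrt(outer(px[, 1], py[, 1], "-")^2 + outer(px[, 2], py[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Tiny flat-field H&E render used by several suites.
tiny_scene <- function(seed, size = 128, n = 8, overlap = 0, noise = 0.01,
                       radius = c(8, 14)) {
  make_scene(scene_spec(image_size = c(size, size), n_nuclei = n,
                        radius_range = radius, overlap_fraction = overlap,
                        noise_sd = noise, seed = seed))
}

random_gray <- function(seed, h = 8, w = 8) {
  stainseg:::with_seed(seed, matrix(sample(0:255, h * w, TRUE), h, w))
}
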