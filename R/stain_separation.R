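# Stage 1: stain separation by sparse non-negative matrix factorization
# (SNMF) of the optical-density image.
#
# The Beer-Lambert model ties the observed RGB intensities I to the stain
# concentrations: V = log(I0 / I) = W H, where W (3 x r) holds the unit-norm
# OD color vector of each stain and H (r x n) the per-pixel concentrations.
# W and H are estimated by alternating non-negative LASSO coding of H and a
# multiplicative update of W under the objective
#   1/2 ||V - W H||_F^2 + lambda * sum_j ||H(j,)||_1,   ||W(,j)||_2 = 1.
# The natural logarithm is used; any consistent base only rescales W H.

#' Convert an RGB image to optical density
#'
#' `V[c, p] = ln(I0 / max(I[c, p], 1))`. Intensities are clamped to at
#' least 1 so the OD stays finite.
#'
#' @param img Integer array `H x W x 3` in `[0, 255]`.
#' @param I0 Reference (illuminating) intensity, default 255.
#' @return A `3 x n` matrix of optical densities with attributes
#'   `dim_hw` (image height/width) and `I0`.
#' @export
rgb_to_od <- function(img, I0 = 255) {
  stopifnot(I0 > 0, length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  V <- rbind(c(img[, , 1]), c(img[, , 2]), c(img[, , 3]))
  V <- log(I0 / pmax(V, 1))
  V <- pmax(V, 0)
  attr(V, "dim_hw") <- c(h, w)
  attr(V, "I0") <- I0
  V
}

#' Convert optical densities back to an RGB image
#'
#' `I = round(I0 * exp(-V))` clipped to `[0, 255]`. Composed with
#' [rgb_to_od()] this is the identity up to +-1 quantization.
#'
#' @param V `3 x n` non-negative OD matrix.
#' @param I0 Reference intensity.
#' @param dim_hw Image height and width (taken from `attr(V, "dim_hw")`
#'   when omitted).
#' @return Integer array `H x W x 3`.
#' @export
od_to_rgb <- function(V, I0 = 255, dim_hw = attr(V, "dim_hw")) {
  stopifnot(nrow(V) == 3L, !is.null(dim_hw))
  I <- clamp(round(I0 * exp(-V)), 0, 255)
  out <- array(0L, dim = c(dim_hw[1], dim_hw[2], 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(I[ch, ])
  out
}

#' Construct a stain color appearance model
#'
#' @param W `3 x r` non-negative matrix; columns are normalized to unit
#'   Euclidean norm.
#' @param stain_order Character names of the columns, default
#'   `c("hematoxylin", "eosin")` truncated to `r`.
#' @return An object of class `stain_model` with elements `W` and
#'   `stain_order`.
#' @export
stain_model <- function(W, stain_order = c("hematoxylin", "eosin")) {
  W <- as.matrix(W)
  dimnames(W) <- NULL
  stopifnot(nrow(W) == 3L, all(W >= 0))
  nrm <- sqrt(colSums(W^2))
  if (any(nrm == 0)) stop("stain_model: zero column in W")
  W <- sweep(W, 2, nrm, "/")
  structure(list(W = W, stain_order = stain_order[seq_len(ncol(W))]),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain color appearance model (", ncol(x$W), " stains)\n", sep = "")
  m <- round(x$W, 4)
  colnames(m) <- x$stain_order
  rownames(m) <- c("R", "G", "B")
  print(m)
  invisible(x)
}

#' SNMF objective value
#'
#' `1/2 ||V - W H||_F^2 + lambda * sum(H)` for non-negative `H`.
#'
#' @param V OD matrix, `W` stain matrix (3 x r), `H` density maps (r x n).
#' @param W Stain color appearance matrix.
#' @param H Density maps.
#' @param lambda Sparsity weight.
#' @return Scalar objective value.
#' @export
snmf_objective <- function(V, W, H, lambda) {
  0.5 * sum((V - W %*% H)^2) + lambda * sum(H)
}

#' Non-negative sparse coding of stain densities
#'
#' Solves, independently per pixel, the non-negative LASSO
#' `min_h 1/2 ||v - W h||_2^2 + lambda ||h||_1, h >= 0` by cyclic
#' coordinate descent with non-negative soft thresholding (the unique
#' optimum of this convex problem, identical to the LARS-LASSO solution).
#' All pixels are updated simultaneously as matrix operations.
#'
#' @param V `3 x n` OD matrix.
#' @param model A `stain_model` (columns must be unit norm) or a `3 x r`
#'   matrix.
#' @param lambda Sparsity penalty (>= 0).
#' @param max_sweeps Maximum coordinate sweeps (default 200).
#' @param tol Convergence tolerance on the largest coefficient change
#'   (default 1e-6).
#' @param warm Optional `r x n` warm-start matrix.
#' @return `r x n` non-negative density matrix `H`.
#' @export
sparse_code <- function(V, model, lambda, max_sweeps = 200, tol = 1e-6,
                        warm = NULL) {
  W <- if (inherits(model, "stain_model")) model$W else as.matrix(model)
  if (any(!is.finite(V)) || any(!is.finite(W))) {
    stop("sparse_code: non-finite inputs")
  }
  r <- ncol(W); n <- ncol(V)
  G <- crossprod(W)                 # r x r gram; diag ~ 1 for unit columns
  B <- crossprod(W, V)              # r x n
  H <- if (is.null(warm)) matrix(0, r, n) else warm
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(r)) {
      resid <- B[j, ]
      if (r > 1L) {
        resid <- resid - G[j, -j, drop = FALSE] %*% H[-j, , drop = FALSE]
      }
      hj <- pmax(0, (as.numeric(resid) - lambda) / G[j, j])
      delta <- max(delta, max(abs(hj - H[j, ]), 0))
      H[j, ] <- hj
    }
    if (delta < tol) break
  }
  H
}

#' Order stain columns as (hematoxylin, eosin)
#'
#' Hematoxylin absorbs strongly in the red channel while eosin barely
#' does, so the column with the larger red-channel OD component is taken
#' as hematoxylin. Deterministic and idempotent; only `r = 2` models are
#' supported.
#'
#' @param model A `stain_model` with 2 columns.
#' @param maps Optional `r x n` density matrix whose rows are permuted
#'   consistently.
#' @return The reordered `stain_model`, or `list(model, maps)` when
#'   `maps` is supplied.
#' @export
order_stains <- function(model, maps = NULL) {
  stopifnot(inherits(model, "stain_model"))
  if (ncol(model$W) != 2L) {
    stop("order_stains: only two-stain models are supported")
  }
  perm <- if (model$W[1, 1] >= model$W[1, 2]) 1:2 else 2:1
  out <- stain_model(model$W[, perm, drop = FALSE],
                     c("hematoxylin", "eosin"))
  if (is.null(maps)) return(out)
  list(model = out, maps = maps[perm, , drop = FALSE])
}

#' Estimate the stain model and density maps by sparse NMF
#'
#' Alternating optimization: non-negative LASSO coding of `H` given `W`
#' ([sparse_code()]), then a multiplicative update of `W` with column
#' renormalization to unit L2 norm (compensated in `H` so the product is
#' unchanged). Iterations that would increase the objective are rejected
#' and terminate the loop, so the objective is non-increasing across
#' accepted iterations. Near-white pixels (all channels below `od_floor`)
#' carry no stain signal and are excluded from the fit; the dictionary is
#' fit on a random subsample of at most `n_fit_pixels` informative pixels
#' and the final `H` is then coded for every pixel.
#'
#' `W` is initialized from the data: the masked pixels at the 1st and
#' 99th percentile of the (OD red - OD blue) statistic, which point
#' towards eosin-like and hematoxylin-like colors respectively.
#'
#' @param V `3 x n` OD matrix (from [rgb_to_od()]).
#' @param r Number of stains (default 2).
#' @param lambda Sparsity weight (default 0.2).
#' @param max_iter Maximum alternating iterations (default 50).
#' @param tol Relative Frobenius change in `W` below which the loop stops
#'   (default 1e-4).
#' @param seed RNG seed for the fitting subsample.
#' @param od_floor Informative-pixel threshold in OD units (default 0.15).
#' @param n_fit_pixels Subsample size for the dictionary fit
#'   (default 20000).
#' @return `list(model = stain_model, maps = r x n density matrix)`, with
#'   stains ordered (hematoxylin, eosin) when `r = 2`.
#' @export
estimate_stains <- function(V, r = 2, lambda = 0.2, max_iter = 50,
                            tol = 1e-4, seed = 1, od_floor = 0.15,
                            n_fit_pixels = 20000) {
  stopifnot(nrow(V) == 3L, r >= 1L)
  keep <- which(apply(V, 2, max) >= od_floor)
  if (length(keep) < r) {
    stop("estimate_stains: fewer informative pixels (", length(keep),
         ") than stains (", r, ")")
  }
  fit_idx <- if (length(keep) > n_fit_pixels) {
    with_seed(seed, sort(sample(keep, n_fit_pixels)))
  } else keep
  Vf <- V[, fit_idx, drop = FALSE]

  # data-driven init: extreme pixels of the red-minus-blue OD statistic
  stat <- Vf[1, ] - Vf[3, ]
  o <- order(stat)
  lo <- Vf[, o[max(1L, ceiling(0.01 * length(o)))]]
  hi <- Vf[, o[min(length(o), floor(0.99 * length(o)) + 1L)]]
  W <- cbind(hi, lo)
  if (r != 2L) {
    W <- Vf[, o[round(seq(1, length(o), length.out = r))], drop = FALSE]
  }
  nrm <- sqrt(colSums(W^2))
  bad <- nrm < 1e-8
  if (any(bad)) {
    W[, bad] <- make_stain_matrix()$W[, seq_len(sum(bad)), drop = FALSE]
    nrm[bad] <- 1
  }
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")

  H <- NULL
  obj <- Inf
  for (it in seq_len(max_iter)) {
    H <- sparse_code(Vf, W, lambda, warm = H)
    num <- Vf %*% t(H)
    den <- W %*% (H %*% t(H))
    W_new <- W * num / pmax(den, 1e-12)
    W_new <- pmax(W_new, 0)
    nrm <- sqrt(colSums(W_new^2))
    if (any(nrm < 1e-12)) break          # collapsed column: keep previous W
    W_new <- sweep(W_new, 2, nrm, "/")
    H_comp <- H * nrm                    # keeps W_new %*% H_comp == W %*% H'
    obj_new <- snmf_objective(Vf, W_new, H_comp, lambda)
    if (obj_new > obj + 1e-12) break     # reject increase, stop
    dW <- sqrt(sum((W_new - W)^2)) / sqrt(sum(W^2))
    W <- W_new
    H <- H_comp
    obj <- obj_new
    if (dW < tol) break
  }

  model <- stain_model(W, if (r == 2L) c("hematoxylin", "eosin")
                       else paste0("stain", seq_len(r)))
  H_full <- sparse_code(V, model, lambda)
  if (r == 2L) {
    os <- order_stains(model, H_full)
    model <- os$model
    H_full <- os$maps
  }
  attr(H_full, "lambda") <- lambda
  list(model = model, maps = H_full)
}

#' Reconstruct the stain-separated foreground and background images
#'
#' The foreground is the hematoxylin channel rendered alone
#' (`od_to_rgb(W[,1] H[1,])`) and shows nuclei on white; the background is
#' the eosin channel (`od_to_rgb(W[,2] H[2,])`).
#'
#' @param img Source RGB array (supplies the pixel grid dimensions).
#' @param model A `stain_model` ordered (hematoxylin, eosin).
#' @param maps `2 x n` density matrix aligned with `img`.
#' @param I0 Reference intensity.
#' @return `list(foreground, background)` of RGB arrays.
#' @export
separate <- function(img, model, maps, I0 = 255) {
  stopifnot(inherits(model, "stain_model"))
  h <- dim(img)[1]; w <- dim(img)[2]
  if (ncol(maps) != h * w) {
    stop("separate: density maps (", ncol(maps),
         " pixels) do not match image (", h * w, " pixels)")
  }
  dim_hw <- c(h, w)
  fore <- od_to_rgb(model$W[, 1, drop = FALSE] %*% maps[1, , drop = FALSE],
                    I0, dim_hw)
  back <- od_to_rgb(model$W[, 2, drop = FALSE] %*% maps[2, , drop = FALSE],
                    I0, dim_hw)
  list(foreground = fore, background = back)
}

#' One-call stain separation of an RGB image
#'
#' Convenience wrapper: OD conversion, SNMF fit and channel
#' reconstruction.
#'
#' @inheritParams estimate_stains
#' @param img RGB array.
#' @param I0 Reference intensity.
#' @return `list(model, maps, foreground, background)`.
#' @export
separate_image <- function(img, lambda = 0.2, I0 = 255, seed = 1, ...) {
  V <- rgb_to_od(img, I0)
  fit <- estimate_stains(V, lambda = lambda, seed = seed, ...)
  c(fit, separate(img, fit$model, fit$maps, I0))
}
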