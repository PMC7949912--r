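#' Training-time augmentation configuration
#'
#' Defaults follow the common recipe for slice-wise neuroimaging regressors:
#' elastic deformation with scaling `alpha` in `[28, 30]`, field smoothing
#' `sigma` in `[3.5, 4]` pixels and application probability 0.3; random
#' affine with rotations up to 4.6 degrees, isotropic scale in
#' `[0.98, 1.02]` and translation up to 0.03 of the extent; and an additive
#' per-channel intensity shift in `[-0.1, 0.1]`. Affine and channel shift are
#' always applied; only the elastic step is probabilistic.
#'
#' @param elastic_alpha_range Deformation scaling range (pixels).
#' @param elastic_sigma_range Gaussian smoothing range of the displacement
#'   field (pixels).
#' @param elastic_p Probability of applying the elastic step.
#' @param affine_degrees Maximum absolute rotation (degrees).
#' @param affine_scale_range Isotropic scale range.
#' @param affine_translate Maximum translation as a fraction of the extent.
#' @param shift_range Additive per-channel shift range.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(elastic_alpha_range = c(28, 30),
                           elastic_sigma_range = c(3.5, 4.0),
                           elastic_p = 0.3,
                           affine_degrees = 4.6,
                           affine_scale_range = c(0.98, 1.02),
                           affine_translate = 0.03,
                           shift_range = c(-0.1, 0.1)) {
  stopifnot(
    elastic_alpha_range[1] <= elastic_alpha_range[2],
    elastic_sigma_range[1] <= elastic_sigma_range[2],
    elastic_p >= 0, elastic_p <= 1,
    affine_scale_range[1] <= affine_scale_range[2],
    shift_range[1] <= shift_range[2]
  )
  structure(
    list(
      elastic_alpha_range = elastic_alpha_range,
      elastic_sigma_range = elastic_sigma_range,
      elastic_p = elastic_p,
      affine_degrees = affine_degrees,
      affine_scale_range = affine_scale_range,
      affine_translate = affine_translate,
      shift_range = shift_range
    ),
    class = "augment_config"
  )
}

# banded 1D Gaussian convolution matrix with truncated kernels renormalized
# at the boundary (preserves constants exactly)
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  d <- outer(seq_len(n), seq_len(n), `-`)
  M <- exp(-d^2 / (2 * sigma^2))
  M[abs(d) > r] <- 0
  M / rowSums(M)
}

gaussian_blur2d <- function(m, sigma) {
  gauss_band(nrow(m), sigma) %*% m %*% t(gauss_band(ncol(m), sigma))
}

as_hwc <- function(slice) {
  if (is.matrix(slice)) array(slice, c(dim(slice), 1)) else slice
}

restore_shape <- function(out, slice) {
  if (is.matrix(slice)) out[, , 1] else out
}

# bilinear sampling of (H, W) image at fractional (row, col) coordinate
# matrices; outside the image the fill is 0. Linear-index gathers on a
# clamped grid with a validity mask keep this fast enough for per-slice
# training-time use.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img)
  W <- ncol(img)
  r0 <- floor(rows)
  c0 <- floor(cols)
  fr <- rows - r0
  fc <- cols - c0
  r0c <- pmin.int(pmax.int(r0, 1), H)
  r1c <- pmin.int(pmax.int(r0 + 1, 1), H)
  c0c <- pmin.int(pmax.int(c0, 1), W)
  c1c <- pmin.int(pmax.int(c0 + 1, 1), W)
  ok_r0 <- (r0 >= 1) & (r0 <= H)
  ok_r1 <- (r0 + 1 >= 1) & (r0 + 1 <= H)
  ok_c0 <- (c0 >= 1) & (c0 <= W)
  ok_c1 <- (c0 + 1 >= 1) & (c0 + 1 <= W)
  v00 <- img[r0c + (c0c - 1) * H] * (ok_r0 & ok_c0)
  v01 <- img[r0c + (c1c - 1) * H] * (ok_r0 & ok_c1)
  v10 <- img[r1c + (c0c - 1) * H] * (ok_r1 & ok_c0)
  v11 <- img[r1c + (c1c - 1) * H] * (ok_r1 & ok_c1)
  out <- v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
  matrix(out, H, W)
}

#' Elastic deformation of a slice
#'
#' Per-pixel uniform(-1, 1) displacements are smoothed with a Gaussian of
#' width `sigma`, scaled by `alpha`, and applied with bilinear interpolation
#' (zero fill outside the image). The same displacement field is applied to
#' every channel so GM and WM stay anatomically aligned.
#'
#' @param slice A (H, W) matrix or (H, W, C) array.
#' @param alpha Displacement scaling (pixels); 0 gives the identity.
#' @param sigma Gaussian width of the field smoothing (pixels).
#' @return The deformed slice, same shape as the input.
#' @export
elastic_transform <- function(slice, alpha, sigma) {
  if (!all(is.finite(slice))) abort("non-finite values in slice.")
  stopifnot(alpha >= 0, sigma > 0)
  x <- as_hwc(slice)
  d <- dim(x)
  if (alpha == 0) return(slice)
  dr <- gaussian_blur2d(matrix(runif(d[1] * d[2], -1, 1), d[1], d[2]), sigma) * alpha
  dc <- gaussian_blur2d(matrix(runif(d[1] * d[2], -1, 1), d[1], d[2]), sigma) * alpha
  base_r <- matrix(seq_len(d[1]), d[1], d[2])
  base_c <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  out <- x
  for (ci in seq_len(d[3])) {
    out[, , ci] <- bilinear_sample(x[, , ci], base_r + dr, base_c + dc)
  }
  restore_shape(out, slice)
}

#' Random affine transform of a slice
#'
#' Rotation sampled uniformly within `[-degrees, degrees]` about the slice
#' center, isotropic scale within `scale_range`, and translation up to
#' `translate` of each axis extent, applied by inverse mapping with bilinear
#' resampling and zero fill. The same transform is applied to all channels.
#'
#' @param slice A (H, W) matrix or (H, W, C) array.
#' @param config An [augment_config()] (fields `affine_degrees`,
#'   `affine_scale_range`, `affine_translate`).
#' @return The transformed slice.
#' @export
random_affine <- function(slice, config = augment_config()) {
  x <- as_hwc(slice)
  d <- dim(x)
  theta <- runif(1, -config$affine_degrees, config$affine_degrees) * pi / 180
  sc <- runif(1, config$affine_scale_range[1], config$affine_scale_range[2])
  tr <- runif(1, -config$affine_translate, config$affine_translate) * d[1]
  tc <- runif(1, -config$affine_translate, config$affine_translate) * d[2]
  if (theta == 0 && sc == 1 && tr == 0 && tc == 0) return(slice)
  cr <- (d[1] + 1) / 2
  cc <- (d[2] + 1) / 2
  base_r <- matrix(seq_len(d[1]), d[1], d[2]) - cr
  base_c <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cc
  # inverse map: undo translation, then inverse rotation/scale
  pr <- base_r - tr
  pc <- base_c - tc
  inv <- 1 / sc
  rows <- (cos(theta) * pr + sin(theta) * pc) * inv + cr
  cols <- (-sin(theta) * pr + cos(theta) * pc) * inv + cc
  out <- x
  for (ci in seq_len(d[3])) {
    out[, , ci] <- bilinear_sample(x[, , ci], rows, cols)
  }
  restore_shape(out, slice)
}

#' Random per-channel intensity shift
#'
#' Adds a scalar drawn uniformly from `shift_range`, independently per
#' channel.
#'
#' @param slice A (H, W) matrix or (H, W, C) array.
#' @param shift_range Two-element numeric range.
#' @return The shifted slice.
#' @export
channel_shift <- function(slice, shift_range = c(-0.1, 0.1)) {
  x <- as_hwc(slice)
  d <- dim(x)
  shifts <- runif(d[3], shift_range[1], shift_range[2])
  for (ci in seq_len(d[3])) x[, , ci] <- x[, , ci] + shifts[ci]
  restore_shape(x, slice)
}

#' Full augmentation pipeline for one slice
#'
#' Applies the elastic step with probability `elastic_p`, then the affine
#' transform, then the channel shift. Deterministic given the R RNG state.
#'
#' @param slice A (H, W) matrix or (H, W, C) array.
#' @param config An [augment_config()].
#' @return The augmented slice.
#' @export
augment_pipeline <- function(slice, config = augment_config()) {
  if (config$elastic_p > 0 && runif(1) < config$elastic_p) {
    alpha <- runif(1, config$elastic_alpha_range[1], config$elastic_alpha_range[2])
    sigma <- runif(1, config$elastic_sigma_range[1], config$elastic_sigma_range[2])
    slice <- elastic_transform(slice, alpha, sigma)
  }
  slice <- random_affine(slice, config)
  channel_shift(slice, config$shift_range)
}
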