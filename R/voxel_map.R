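#' Stitch per-slice predictions into a voxel-level brain-age map
#'
#' Each voxel's age is the mean of the three slice predictions that
#' intersect it: for voxel (i, j, k), the mean of the i-th sagittal, j-th
#' coronal and k-th axial slice prediction (axis convention: axis 1
#' sagittal, axis 2 coronal, axis 3 axial).
#'
#' @param axial_preds,coronal_preds,sagittal_preds Numeric vectors of
#'   per-slice predicted ages whose lengths match the corresponding axis
#'   extents of `shape`.
#' @param shape Integer vector of 3: the cropped volume shape.
#' @param participant_id Identifier stored with the map.
#' @return An object of class `brain_age_map` with fields `grid` (3D
#'   array, years), `sigma` (0), `participant_id`.
#' @export
stitch_voxel_map <- function(axial_preds, coronal_preds, sagittal_preds,
                             shape, participant_id = "subject") {
  shape <- as.integer(shape)
  if (length(sagittal_preds) != shape[1] ||
    length(coronal_preds) != shape[2] ||
    length(axial_preds) != shape[3]) {
    abort(sprintf(
      "prediction lengths (sagittal %d, coronal %d, axial %d) do not match shape (%s)",
      length(sagittal_preds), length(coronal_preds), length(axial_preds),
      paste(shape, collapse = ", ")
    ))
  }
  grid <- (outer(outer(sagittal_preds, coronal_preds, `+`), axial_preds, `+`)) / 3
  structure(
    list(
      participant_id = participant_id, grid = grid, sigma = 0,
      display_range = c(20, 60)
    ),
    class = "brain_age_map"
  )
}

#' @export
print.brain_age_map <- function(x, ...) {
  cat("<brain_age_map> ", x$participant_id, " (",
    paste(dim(x$grid), collapse = "x"), "), sigma = ", x$sigma,
    ", mean age ", format(mean(x$grid), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

# separable 3D Gaussian filter; truncated kernels renormalized at the
# boundary so constants (and hence the global mean, approximately) are
# preserved
gaussian_smooth3d <- function(a, sigma) {
  if (sigma == 0) return(a)
  d <- dim(a)
  B1 <- gauss_band(d[1], sigma)
  B2 <- gauss_band(d[2], sigma)
  B3 <- gauss_band(d[3], sigma)
  m <- matrix(a, d[1])
  a <- array(B1 %*% m, d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(B2 %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(B3 %*% matrix(a, d[3]), c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}

#' Gaussian smoothing of a brain-age map
#'
#' Stitching slice predictions produces high-frequency voxel-to-voxel
#' jumps; spatial smoothing suppresses them. `sigma = 0` is the identity.
#'
#' @param map A `brain_age_map`.
#' @param sigma Gaussian width in voxels (>= 0).
#' @return The smoothed map with `sigma` recorded.
#' @export
smooth_map <- function(map, sigma) {
  stopifnot(inherits(map, "brain_age_map"))
  if (sigma < 0) abort("`sigma` must be >= 0.")
  map$grid <- gaussian_smooth3d(map$grid, sigma)
  map$sigma <- sigma
  map
}

#' Roughness of a brain-age map
#'
#' Mean absolute difference between axis-adjacent voxels (years), pooled
#' over the three axes — a scalar measure of the voxel-to-voxel prediction
#' instability that stitching introduces.
#'
#' @param map A `brain_age_map` (or bare 3D array).
#' @return Non-negative scalar (years).
#' @export
map_roughness <- function(map) {
  g <- if (inherits(map, "brain_age_map")) map$grid else map
  d <- dim(g)
  s <- 0
  n <- 0
  if (d[1] > 1) {
    s <- s + sum(abs(g[-1, , ] - g[-d[1], , ]))
    n <- n + (d[1] - 1) * d[2] * d[3]
  }
  if (d[2] > 1) {
    s <- s + sum(abs(g[, -1, ] - g[, -d[2], ]))
    n <- n + d[1] * (d[2] - 1) * d[3]
  }
  if (d[3] > 1) {
    s <- s + sum(abs(g[, , -1] - g[, , -d[3]]))
    n <- n + d[1] * d[2] * (d[3] - 1)
  }
  s / n
}

#' Write a brain-age map as NIfTI
#'
#' @param map A `brain_age_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$grid), path)
  invisible(path)
}
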