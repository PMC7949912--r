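#' Construct a segmented volume
#'
#' Container for one subject's tissue maps: gray matter in the first channel,
#' white matter in the second. The WM channel may be `NULL` for single-tissue
#' work.
#'
#' @param participant_id Subject identifier.
#' @param gm 3D numeric array of gray-matter intensities.
#' @param wm 3D numeric array of white-matter intensities, or `NULL`.
#' @return An object of class `segmented_volume`.
#' @export
segmented_volume <- function(participant_id, gm, wm = NULL) {
  if (length(dim(gm)) != 3) abort("`gm` must be a 3D array.")
  if (!is.null(wm)) {
    if (!identical(dim(gm), dim(wm))) {
      abort(sprintf(
        "GM and WM shapes differ: (%s) vs (%s)",
        paste(dim(gm), collapse = ", "), paste(dim(wm), collapse = ", ")
      ))
    }
  }
  if (!all(is.finite(gm)) || (!is.null(wm) && !all(is.finite(wm)))) {
    abort("volume contains non-finite values.")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      gm = gm, wm = wm, shape = dim(gm)
    ),
    class = "segmented_volume"
  )
}

#' @export
print.segmented_volume <- function(x, ...) {
  cat("<segmented_volume> ", x$participant_id, " (",
    paste(x$shape, collapse = "x"), "), channels: gm",
    if (!is.null(x$wm)) " + wm", "\n",
    sep = ""
  )
  invisible(x)
}

#' Load a segmented volume from NIfTI files
#'
#' @param gm_path Path to the gray-matter NIfTI.
#' @param wm_path Path to the white-matter NIfTI, or `NULL` for GM-only use.
#' @param participant_id Subject identifier.
#' @return A [segmented_volume()]. Grids are returned as read, no resampling.
#' @export
load_volume <- function(gm_path, wm_path = NULL, participant_id = NULL) {
  if (!file.exists(gm_path)) abort(paste0("file not found: ", gm_path))
  gm <- array(as.numeric(RNifti::readNifti(gm_path)), dim = dim(RNifti::readNifti(gm_path)))
  wm <- NULL
  if (!is.null(wm_path)) {
    if (!file.exists(wm_path)) abort(paste0("file not found: ", wm_path))
    wmimg <- RNifti::readNifti(wm_path)
    wm <- array(as.numeric(wmimg), dim = dim(wmimg))
  }
  if (is.null(participant_id)) {
    participant_id <- sub("_gm.*$", "", basename(gm_path))
  }
  segmented_volume(participant_id, gm, wm)
}

#' Min-max scale each tissue channel to [0, 1]
#'
#' Each channel is scaled independently; a constant channel maps to all
#' zeros so empty volumes survive preprocessing rather than erroring.
#'
#' @param volume A [segmented_volume()].
#' @return The volume with scaled channels.
#' @export
scale_intensities <- function(volume) {
  stopifnot(inherits(volume, "segmented_volume"))
  sc <- function(x) {
    if (anyNA(x)) abort("NaN/NA present in volume.")
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) return(array(0, dim(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  volume$gm <- sc(volume$gm)
  if (!is.null(volume$wm)) volume$wm <- sc(volume$wm)
  volume
}

#' Per-axis crop offsets reproducing the canonical corner crop
#'
#' For the canonical segmented-brain shape (121, 145, 121) the crop removes
#' fixed margins of (25, 24), (28, 29), (25, 24) voxels, giving (72, 88, 72).
#' For other shapes the low margin is `floor(0.2 d)` and the kept extent is
#' `d - round(0.4 d)`, so roughly 40% of each axis is removed from the
#' corners.
#'
#' @param shape Integer vector of 3 axis lengths.
#' @return A 3x2 integer matrix of (low, high) margins per axis.
#' @export
default_crop_offsets <- function(shape) {
  shape <- as.integer(shape)
  if (identical(shape, c(121L, 145L, 121L))) {
    return(matrix(c(25L, 24L, 28L, 29L, 25L, 24L),
      ncol = 2, byrow = TRUE,
      dimnames = list(NULL, c("low", "high"))
    ))
  }
  low <- as.integer(floor(0.2 * shape))
  kept <- shape - as.integer(round(0.4 * shape))
  high <- shape - low - kept
  matrix(c(rbind(low, high)),
    ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("low", "high"))
  )
}

#' Crop corner margins from a volume
#'
#' Removes a low-side and high-side margin per axis (about 40% of each
#' extent in total), identically for both channels. With the default offsets
#' a (121, 145, 121) volume crops to exactly (72, 88, 72).
#'
#' @param volume A [segmented_volume()].
#' @param offsets 3x2 matrix of (low, high) voxel margins, or `NULL` for
#'   [default_crop_offsets()]. Use all zeros for the identity.
#' @return The cropped volume.
#' @export
crop_volume <- function(volume, offsets = NULL) {
  stopifnot(inherits(volume, "segmented_volume"))
  shp <- volume$shape
  if (is.null(offsets)) {
    if (any(shp < 8)) abort("each axis must have length >= 8 to crop.")
    offsets <- default_crop_offsets(shp)
  }
  offsets <- matrix(as.integer(offsets), ncol = 2)
  kept <- shp - offsets[, 1] - offsets[, 2]
  if (any(kept < 4) && any(offsets != 0L)) {
    abort(sprintf(
      "crop leaves fewer than 4 voxels on an axis (kept: %s)",
      paste(kept, collapse = ", ")
    ))
  }
  ix <- lapply(1:3, function(d) seq.int(offsets[d, 1] + 1L, shp[d] - offsets[d, 2]))
  volume$gm <- volume$gm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  if (!is.null(volume$wm)) {
    volume$wm <- volume$wm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
  volume$shape <- dim(volume$gm)
  attr(volume, "crop_offsets") <- offsets
  volume
}

#' Scale and crop a volume in one step
#'
#' @param volume A [segmented_volume()].
#' @param offsets Crop offsets as in [crop_volume()].
#' @return The preprocessed volume.
#' @export
preprocess_volume <- function(volume, offsets = NULL) {
  crop_volume(scale_intensities(volume), offsets)
}

orientation_axis <- function(orientation) {
  switch(orientation,
    sagittal = 1L, coronal = 2L, axial = 3L,
    abort(paste0("unknown orientation: ", orientation))
  )
}

# zero-pad a (H, w) matrix to (H, W) splitting the margin evenly
# (extra column on the high side when odd)
pad_cols <- function(m, W) {
  w <- ncol(m)
  if (w == W) return(m)
  if (w > W) abort("slice wider than target; cannot pad.")
  lo <- (W - w) %/% 2
  hi <- W - w - lo
  cbind(
    matrix(0, nrow(m), lo), m, matrix(0, nrow(m), hi)
  )
}

#' Extract standardized 2D slices along one orientation
#'
#' Under the default axis convention, axis 1 is sagittal, axis 2 coronal,
#' axis 3 axial. Every slice is standardized to a common height x width equal
#' to (axis-1 extent, axis-2 extent) of the cropped volume: sagittal slices
#' are transposed, coronal slices are zero-padded along the width — for the
#' canonical (72, 88, 72) crop the (72, 72) coronal slice becomes (72, 88).
#'
#' @param volume A preprocessed (scaled, cropped) [segmented_volume()].
#' @param orientation One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param tissue One of `"both"`, `"gm"`, `"wm"`; channel count is 2 only for
#'   `"both"`.
#' @return A `slice_stack`: list with `data` (array height x width x
#'   channels x n_slices), `orientation`, `participant_id`, `slice_index`
#'   (1-based along the orientation axis).
#' @export
extract_slices <- function(volume, orientation = c("axial", "coronal", "sagittal"),
                           tissue = c("both", "gm", "wm")) {
  orientation <- match.arg(orientation)
  tissue <- match.arg(tissue)
  axis <- orientation_axis(orientation)
  shp <- volume$shape
  H <- shp[1]
  W <- shp[2]
  chans <- switch(tissue,
    both = {
      if (is.null(volume$wm)) abort("tissue = 'both' but volume has no WM channel.")
      list(volume$gm, volume$wm)
    },
    gm = list(volume$gm),
    wm = {
      if (is.null(volume$wm)) abort("tissue = 'wm' but volume has no WM channel.")
      list(volume$wm)
    }
  )
  S <- shp[axis]
  out <- array(0, c(H, W, length(chans), S))
  for (ci in seq_along(chans)) {
    v <- chans[[ci]]
    for (s in seq_len(S)) {
      sl <- switch(axis,
        t(v[s, , , drop = TRUE]), # sagittal: (d2, d3) -> (d3, d2)
        v[, s, , drop = TRUE], # coronal: (d1, d3)
        v[, , s, drop = TRUE] # axial: (d1, d2)
      )
      if (nrow(sl) != H) {
        abort("sagittal slice height does not match axis-1 extent; non-cubic sagittal/axial axes are unsupported.")
      }
      out[, , ci, s] <- pad_cols(sl, W)
    }
  }
  structure(
    list(
      data = out, orientation = orientation,
      participant_id = volume$participant_id,
      slice_index = seq_len(S)
    ),
    class = "slice_stack"
  )
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<slice_stack> ", x$participant_id, ", ", x$orientation, ": ",
    d[4], " slices of (", d[3], ", ", d[1], ", ", d[2], ")\n",
    sep = ""
  )
  invisible(x)
}

# Concatenate slice stacks from several subjects into one training array.
# Returns list(data = (H, W, C, N) array, age = length-N vector,
# participant_id, slice_index).
bind_stacks <- function(stacks, ages) {
  d <- dim(stacks[[1]]$data)
  S <- d[4]
  N <- S * length(stacks)
  data <- array(0, c(d[1], d[2], d[3], N))
  age <- numeric(N)
  pid <- character(N)
  sidx <- integer(N)
  for (i in seq_along(stacks)) {
    span <- ((i - 1) * S + 1):(i * S)
    data[, , , span] <- stacks[[i]]$data
    age[span] <- ages[i]
    pid[span] <- stacks[[i]]$participant_id
    sidx[span] <- stacks[[i]]$slice_index
  }
  list(data = data, age = age, participant_id = pid, slice_index = sidx)
}
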