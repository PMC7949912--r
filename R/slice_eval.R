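#' Build a per-slice prediction table for one orientation
#'
#' Runs a trained slice regressor over every slice of every subject and
#' returns the long table of per-(subject, slice) predicted ages — one row
#' per individual per slice, the raw material for error profiles, the
#' per-view linear combiner, and voxel maps.
#'
#' @param model A trained `orientation_regressor`.
#' @param volumes List of preprocessed (scaled, cropped)
#'   [segmented_volume()]s.
#' @param records Participants tibble with `participant_id` and `age`; every
#'   volume's id must be present.
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @param tissue `"both"`, `"gm"` or `"wm"`, matching the model's channels.
#' @return A tibble of class `slice_prediction_table` with columns
#'   `participant_id`, `age`, `orientation`, `slice_index`, `predicted_age`.
#' @export
build_prediction_table <- function(model, volumes, records,
                                   orientation = c("axial", "coronal", "sagittal"),
                                   tissue = c("both", "gm", "wm")) {
  orientation <- match.arg(orientation)
  tissue <- match.arg(tissue)
  ids <- vapply(volumes, function(v) v$participant_id, character(1))
  missing <- setdiff(ids, records$participant_id)
  if (length(missing)) {
    abort(paste0(
      "subjects missing from records: ", paste(missing, collapse = ", ")
    ))
  }
  age_of <- setNames(records$age, records$participant_id)
  rows <- lapply(volumes, function(v) {
    st <- extract_slices(v, orientation, tissue)
    tibble::tibble(
      participant_id = v$participant_id,
      age = unname(age_of[v$participant_id]),
      orientation = orientation,
      slice_index = st$slice_index,
      predicted_age = predict_slices(model, st)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slice_prediction_table", class(out))
  out
}

#' Wide subjects-by-slices matrix of a prediction table
#'
#' @param table A `slice_prediction_table` (long tibble).
#' @return Numeric matrix (subjects x slices), row names the participant
#'   ids; the true ages are attached as attribute `"age"` in row order.
#' @export
prediction_matrix <- function(table) {
  wide <- tidyr::pivot_wider(
    dplyr::arrange(table, .data$participant_id, .data$slice_index),
    id_cols = c("participant_id", "age"),
    names_from = "slice_index", values_from = "predicted_age"
  )
  m <- as.matrix(wide[, -(1:2)])
  rownames(m) <- wide$participant_id
  attr(m, "age") <- wide$age
  m
}

#' Per-slice error profile with 0.95 confidence band
#'
#' For each slice index, the MAE over subjects of the slice's prediction
#' and a normal-approximation 95% confidence half-width (1.96 standard
#' errors of the per-subject absolute errors).
#'
#' @param table A `slice_prediction_table`.
#' @param split Label stored with the profile (e.g. `"train"`,
#'   `"validation"`).
#' @return A tibble of class `slice_error_profile` with columns
#'   `orientation`, `slice_index`, `mae`, `ci_halfwidth`, `n`, `split`.
#' @export
slice_error_profile <- function(table, split = "validation") {
  n_sub <- dplyr::n_distinct(table$participant_id)
  if (n_sub < 2) {
    warn("confidence interval undefined for a single subject; returning 0.")
  }
  out <- table |>
    dplyr::mutate(abs_err = abs(.data$predicted_age - .data$age)) |>
    dplyr::group_by(.data$orientation, .data$slice_index) |>
    dplyr::summarise(
      mae = mean(.data$abs_err),
      ci_halfwidth = if (dplyr::n() > 1) {
        1.96 * stats::sd(.data$abs_err) / sqrt(dplyr::n())
      } else {
        0
      },
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(split = split)
  class(out) <- c("slice_error_profile", class(out))
  out
}

#' Summary error metrics for one view
#'
#' The four headline metrics reported per orientation: `average_slice_error`
#' (mean over slices of the per-slice MAE), `average_error` (MAE of the
#' per-subject mean-over-slices prediction), and — when a fitted view
#' combiner is supplied — `regression_error` (MAE of the combiner's
#' prediction) and `r2` (coefficient of determination of combiner
#' predictions against true age).
#'
#' @param table A `slice_prediction_table`.
#' @param combiner Optional fitted [fit_view_combiner()] object.
#' @return A one-row tibble.
#' @export
view_metrics <- function(table, combiner = NULL) {
  prof <- slice_error_profile(table)
  per_subj <- table |>
    dplyr::group_by(.data$participant_id, .data$age) |>
    dplyr::summarise(mean_pred = mean(.data$predicted_age), .groups = "drop")
  out <- tibble::tibble(
    orientation = table$orientation[1],
    average_slice_error = mean(prof$mae),
    average_error = mean(abs(per_subj$mean_pred - per_subj$age)),
    regression_error = NA_real_,
    r2 = NA_real_
  )
  if (!is.null(combiner)) {
    pr <- predict(combiner, table)
    out$regression_error <- mean(abs(pr$predicted - pr$age))
    out$r2 <- 1 - sum((pr$predicted - pr$age)^2) / sum((pr$age - mean(pr$age))^2)
  }
  out
}

#' Compare gray-matter and white-matter error profiles
#'
#' Per-slice MAE difference between two single-tissue error profiles of the
#' same orientation, plus the fraction of slices where the WM error exceeds
#' the GM error (ties count 0.5).
#'
#' @param profile_gm,profile_wm [slice_error_profile()] tibbles sharing
#'   orientation and slice count.
#' @return A tibble with columns `slice_index`, `mae_gm`, `mae_wm`,
#'   `mae_diff` (WM minus GM) and attribute `fraction_wm_higher`.
#' @export
compare_tissue_profiles <- function(profile_gm, profile_wm) {
  if (nrow(profile_gm) != nrow(profile_wm)) {
    abort("profiles have different slice counts.")
  }
  if (!identical(profile_gm$orientation[1], profile_wm$orientation[1])) {
    abort("profiles are from different orientations.")
  }
  out <- tibble::tibble(
    orientation = profile_gm$orientation,
    slice_index = profile_gm$slice_index,
    mae_gm = profile_gm$mae,
    mae_wm = profile_wm$mae,
    mae_diff = profile_wm$mae - profile_gm$mae
  )
  frac <- mean((out$mae_diff > 0) + 0.5 * (out$mae_diff == 0))
  attr(out, "fraction_wm_higher") <- frac
  class(out) <- c("tissue_comparison", class(out))
  out
}
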