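#' Split a cohort into training and validation subjects
#'
#' Random subject-level split, reproducible from `seed`.
#'
#' @param records Participants tibble.
#' @param val_frac Fraction of subjects in the validation split.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `val`.
#' @export
split_cohort <- function(records, val_frac = 0.2, seed = 1L) {
  n <- nrow(records)
  n_val <- max(1L, round(val_frac * n))
  with_seed(seed, {
    val <- sort(sample(records$participant_id, n_val))
  })
  list(train = setdiff(records$participant_id, val), val = val)
}

#' Preprocess every volume of a cohort
#'
#' @param volumes List of [segmented_volume()]s.
#' @param offsets Crop offsets as in [crop_volume()].
#' @return List of scaled, cropped volumes.
#' @export
preprocess_cohort <- function(volumes, offsets = NULL) {
  lapply(volumes, preprocess_volume, offsets = offsets)
}

stacks_for <- function(volumes, records, ids, orientation, tissue) {
  keep <- volumes[vapply(volumes, function(v) v$participant_id %in% ids, logical(1))]
  ages <- setNames(records$age, records$participant_id)[
    vapply(keep, function(v) v$participant_id, character(1))
  ]
  bind_stacks(lapply(keep, extract_slices, orientation = orientation, tissue = tissue), ages)
}

#' Train slice regressors and view combiners end to end
#'
#' The complete training driver: for each requested view it extracts the
#' training/validation slices, trains a slice regressor, builds the
#' per-slice prediction tables, and fits the view combiner on the training
#' table (its `e_x` comes from the validation table). The returned object
#' feeds [run_full_pipeline()] directly.
#'
#' @param volumes List of preprocessed [segmented_volume()]s.
#' @param records Participants tibble.
#' @param views Character subset of `c("axial", "coronal", "sagittal")`.
#' @param tissue `"both"`, `"gm"` or `"wm"`.
#' @param config A [train_config()]; its seed is fanned out per view.
#' @param augment An [augment_config()] or `NULL`.
#' @param split A [split_cohort()] list, or `NULL` to split here.
#' @param val_frac Validation fraction when splitting here.
#' @param preset Backbone preset for [build_backbone()].
#' @return An object of class `brainage_pipeline`: named lists `models` and
#'   `combiners`, the `split`, and per-view prediction `tables`
#'   (train and validation).
#' @export
fit_brainage_pipeline <- function(volumes, records,
                                  views = c("axial", "coronal", "sagittal"),
                                  tissue = "both",
                                  config = train_config(),
                                  augment = augment_config(),
                                  split = NULL, val_frac = 0.2,
                                  preset = "small_cnn") {
  views <- match.arg(views, several.ok = TRUE)
  if (is.null(split)) {
    split <- split_cohort(records, val_frac, stage_seed(config$seed, "split"))
  }
  in_ch <- if (tissue == "both") 2L else 1L
  models <- list()
  combiners <- list()
  tables <- list()
  vol_train <- volumes[vapply(volumes, function(v) v$participant_id %in% split$train, logical(1))]
  vol_val <- volumes[vapply(volumes, function(v) v$participant_id %in% split$val, logical(1))]
  for (v in views) {
    cfg <- config
    cfg$orientation <- v
    cfg$seed <- stage_seed(config$seed, paste0("train_", v))
    tr <- stacks_for(volumes, records, split$train, v, tissue)
    va <- stacks_for(volumes, records, split$val, v, tissue)
    model <- build_backbone(preset, in_ch, seed = cfg$seed)
    model <- train_regressor(model, tr, va, cfg, augment)
    tab_tr <- build_prediction_table(model, vol_train, records, v, tissue)
    tab_va <- build_prediction_table(model, vol_val, records, v, tissue)
    comb <- fit_view_combiner(tab_tr, tab_va)
    models[[v]] <- model
    combiners[[v]] <- comb
    tables[[v]] <- list(train = tab_tr, validation = tab_va)
  }
  structure(
    list(
      models = models, combiners = combiners, tables = tables,
      split = split, tissue = tissue, views = views
    ),
    class = "brainage_pipeline"
  )
}

#' @export
print.brainage_pipeline <- function(x, ...) {
  cat("<brainage_pipeline> views: ", paste(x$views, collapse = ", "),
    "; tissue: ", x$tissue, "; ",
    length(x$split$train), " train / ", length(x$split$val), " val subjects\n",
    sep = ""
  )
  for (v in x$views) {
    cat("  ", v, ": e_x = ", format(x$combiners[[v]]$e_x, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.brainage_pipeline <- function(x, ...) {
  purrr::map_dfr(x$views, function(v) {
    dplyr::bind_cols(
      view_metrics(x$tables[[v]]$validation, x$combiners[[v]])
    )
  })
}
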