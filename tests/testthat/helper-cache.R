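# Expensive fixtures (trained models, cohorts) are built once per test run
# and shared across test files through this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# small cohort for unit tests of preprocessing / evaluation plumbing
tiny_cohort <- function() {
  cached("tiny_cohort", {
    spec <- phantom_spec(n_subjects = 10, volume_shape = c(41, 49, 41), seed = 3)
    c(generate_cohort(spec), list(spec = spec))
  })
}

# The full-scale parameter-recovery run on the default phantom cohort:
# n = 240, shape (61, 73, 61), seed 7, small_cnn backbone, axial view,
# 15 epochs (3 rampup). Shared by the acceptance-style checks.
recovery_run <- function() {
  cached("recovery_run", {
    spec <- phantom_spec()
    cohort <- generate_cohort(spec)
    vols <- preprocess_cohort(cohort$volumes)
    split <- split_cohort(cohort$records, 0.2, sliceage:::stage_seed(spec$seed, "split"))
    cfg <- train_config(
      total_epochs = 15, rampup_epochs = 3,
      seed = sliceage:::stage_seed(spec$seed, "train_axial"),
      orientation = "axial"
    )
    tr <- sliceage:::stacks_for(vols, cohort$records, split$train, "axial", "both")
    va <- sliceage:::stacks_for(vols, cohort$records, split$val, "axial", "both")
    model <- build_backbone("small_cnn", 2L, seed = cfg$seed)
    # no augmentation for phantom recovery: the affine scale jitter acts as
    # label noise on a purely geometric age signal (see methods vignette)
    model <- train_regressor(model, tr, va, cfg, augment = NULL)
    vol_val <- vols[vapply(vols, function(v) v$participant_id %in% split$val, logical(1))]
    val_table <- build_prediction_table(model, vol_val, cohort$records, "axial", "both")
    # keep only what the tests read; the raw volumes are large
    list(
      spec = spec, records = cohort$records, split = split, model = model,
      val_stack = va, val_table = val_table,
      val_sd = sd(va$age[!duplicated(va$participant_id)])
    )
  })
}

# a reduced-scale three-view pipeline for the fusion end-to-end checks
small_pipeline <- function() {
  cached("small_pipeline", {
    spec <- phantom_spec(n_subjects = 60, volume_shape = c(41, 49, 41), seed = 11)
    cohort <- generate_cohort(spec)
    vols <- preprocess_cohort(cohort$volumes)
    cfg <- train_config(total_epochs = 8, rampup_epochs = 2, seed = 11)
    pl <- fit_brainage_pipeline(
      vols, cohort$records,
      views = c("axial", "coronal", "sagittal"),
      config = cfg, augment = NULL, val_frac = 0.25
    )
    vol_val <- vols[vapply(vols, function(v) v$participant_id %in% pl$split$val, logical(1))]
    res <- run_full_pipeline(vol_val, cohort$records, pl$models, pl$combiners)
    list(spec = spec, cohort = cohort, pipeline = pl, result = res)
  })
}
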