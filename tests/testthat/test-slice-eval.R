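# build a synthetic prediction table directly (no network needed)
make_table <- function(pred_matrix, ages, orientation = "axial",
                       ids = sprintf("s%02d", seq_len(nrow(pred_matrix)))) {
  out <- tidyr::expand_grid(
    i = seq_len(nrow(pred_matrix)), slice_index = seq_len(ncol(pred_matrix))
  ) |>
    dplyr::mutate(
      participant_id = ids[.data$i],
      age = ages[.data$i],
      orientation = orientation,
      predicted_age = pred_matrix[cbind(.data$i, .data$slice_index)]
    ) |>
    dplyr::select("participant_id", "age", "orientation", "slice_index", "predicted_age")
  class(out) <- c("slice_prediction_table", class(out))
  out
}

test_that("prediction tables have one row per subject per slice", {
  co <- tiny_cohort()
  vols <- preprocess_cohort(co$volumes[1:5])
  cfg <- train_config(total_epochs = 2, rampup_epochs = 1, seed = 4)
  tr <- sliceage:::stacks_for(
    vols, co$records,
    co$records$participant_id[1:5], "axial", "both"
  )
  m <- train_regressor(build_backbone("small_cnn", 2L, seed = 4), tr, NULL, cfg, augment = NULL)

  tab <- build_prediction_table(m, vols, co$records, "axial", "both")
  S <- vols[[1]]$shape[3]
  expect_equal(nrow(tab), 5 * S)
  expect_identical(dim(prediction_matrix(tab)), c(5L, as.integer(S)))

  # invariant to subject ordering
  tab_rev <- build_prediction_table(m, rev(vols), co$records, "axial", "both")
  expect_equal(
    dplyr::arrange(tab, .data$participant_id, .data$slice_index),
    dplyr::arrange(tab_rev, .data$participant_id, .data$slice_index)
  )

  # rerun identical
  expect_equal(tab, build_prediction_table(m, vols, co$records, "axial", "both"))

  expect_error(
    build_prediction_table(m, vols, co$records[-1, ], "axial", "both"),
    "missing from records"
  )
})

test_that("slice error profile computes MAE and 0.95 CI per slice", {
  ages <- c(30, 40, 50)
  exact <- make_table(matrix(ages, 3, 4), ages)
  prof <- slice_error_profile(exact)
  expect_true(all(prof$mae == 0))
  expect_true(all(prof$ci_halfwidth == 0))
  expect_equal(nrow(prof), 4)

  offset <- make_table(matrix(ages + 2, 3, 4), ages)
  expect_true(all(slice_error_profile(offset)$mae == 2))

  # two subjects, one slice, absolute errors 1 and 3:
  # MAE 2, SE = sd(c(1,3))/sqrt(2) = 1, half-width 1.96
  two <- make_table(matrix(c(31, 43), 2, 1), c(30, 40))
  p2 <- slice_error_profile(two)
  expect_equal(p2$mae, 2)
  expect_equal(p2$ci_halfwidth, 1.96, tolerance = 1e-12)

  one <- make_table(matrix(35, 1, 3), 30)
  expect_warning(p1 <- slice_error_profile(one), "single subject")
  expect_true(all(p1$ci_halfwidth == 0))
})

test_that("view metrics match hand arithmetic and the Jensen property", {
  ages <- c(30, 40)
  tab <- make_table(matrix(c(30, 40, 34, 44), 2, 2), ages)
  vm <- view_metrics(tab)
  expect_equal(vm$average_slice_error, 2)
  expect_equal(vm$average_error, 2)

  ages4 <- c(30, 40, 50, 60)
  exact <- make_table(matrix(ages4, 4, 3), ages4)
  cb <- fit_view_combiner(exact, exact)
  vm0 <- view_metrics(exact, cb)
  expect_equal(vm0$average_slice_error, 0)
  expect_equal(vm0$average_error, 0)
  expect_equal(vm0$regression_error, 0, tolerance = 1e-8)
  expect_equal(vm0$r2, 1, tolerance = 1e-8)

  # average_error <= average_slice_error on random tables
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    S <- sample(2:6, 1)
    a <- runif(n, 20, 80)
    tb <- make_table(matrix(a + rnorm(n * S, 0, 5), n, S), a)
    v <- view_metrics(tb)
    expect_lte(v$average_error, v$average_slice_error + 1e-12)
  }
})

test_that("metrics are invariant to subject permutation", {
  set.seed(13)
  a <- runif(6, 20, 80)
  m <- matrix(a + rnorm(6 * 5, 0, 3), 6, 5)
  t1 <- make_table(m, a)
  perm <- sample(6)
  t2 <- make_table(m[perm, ], a[perm], ids = sprintf("s%02d", seq_len(6))[perm])
  expect_equal(view_metrics(t1), view_metrics(t2))
  expect_equal(slice_error_profile(t1)$mae, slice_error_profile(t2)$mae)
})

test_that("tissue comparison reports per-slice differences and WM fraction", {
  ages <- c(30, 40, 50)
  base <- slice_error_profile(make_table(matrix(ages + 2, 3, 6), ages))
  worse <- base
  worse$mae <- worse$mae + 1

  same <- compare_tissue_profiles(base, base)
  expect_true(all(same$mae_diff == 0))
  expect_equal(attr(same, "fraction_wm_higher"), 0.5) # tie convention

  cmp <- compare_tissue_profiles(base, worse)
  expect_equal(attr(cmp, "fraction_wm_higher"), 1)
  expect_true(all(cmp$mae_diff == 1))

  expect_error(compare_tissue_profiles(base, worse[-1, ]), "slice counts")
})

test_that("white-matter channels with weaker age signal score worse per slice", {
  # hybrid phantoms: GM rendered at the true age, WM at the fixed reference
  # age (the limiting case of a weaker WM age signal), so a WM-only
  # regressor has nothing to learn while a GM-only one does
  spec <- phantom_spec(n_subjects = 120, seed = 17)
  co <- generate_cohort(spec)
  a_ref <- mean(spec$age_range)
  hybrids <- lapply(seq_along(co$volumes), function(i) {
    wm_vol <- sliceage:::with_seed(1000 + i, phantom_volume(spec, a_ref))
    segmented_volume(
      co$volumes[[i]]$participant_id,
      co$volumes[[i]]$gm, wm_vol$wm
    )
  })
  vols <- preprocess_cohort(hybrids)
  sp <- split_cohort(co$records, 0.25, 2)
  cfg <- train_config(total_epochs = 15, rampup_epochs = 3, seed = 2)
  vol_val <- vols[vapply(vols, function(v) v$participant_id %in% sp$val, logical(1))]

  profiles <- lapply(c("gm", "wm"), function(tis) {
    trs <- sliceage:::stacks_for(vols, co$records, sp$train, "axial", tis)
    m <- train_regressor(
      build_backbone("small_cnn", 1L, seed = 2), trs, NULL, cfg,
      augment = NULL
    )
    tab <- build_prediction_table(m, vol_val, co$records, "axial", tis)
    slice_error_profile(tab)
  })
  cmp <- compare_tissue_profiles(profiles[[1]], profiles[[2]])
  expect_gt(attr(cmp, "fraction_wm_higher"), 0.5)
  # and the pooled error ordering agrees
  expect_lt(mean(profiles[[1]]$mae), mean(profiles[[2]]$mae))
})
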