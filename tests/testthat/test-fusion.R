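make_table <- function(pred_matrix, ages, orientation = "axial",
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

test_that("view combiner: perfect predictors give zero train residual", {
  set.seed(1)
  ages_tr <- runif(20, 20, 80)
  ages_va <- runif(8, 20, 80)
  train_tab <- make_table(matrix(ages_tr, 20, 3), ages_tr)
  val_tab <- make_table(
    matrix(ages_va + rnorm(8 * 3, 0, 1), 8, 3), ages_va,
    ids = sprintf("v%02d", 1:8)
  )
  cb <- fit_view_combiner(train_tab, val_tab)
  pr_tr <- predict(cb, train_tab)
  expect_equal(pr_tr$predicted, pr_tr$age, tolerance = 1e-8)
  # e_x reflects the validation table's own consistency error
  pr_va <- predict(cb, val_tab)
  expect_equal(cb$e_x, mean(abs(pr_va$predicted - pr_va$age)), tolerance = 1e-12)
  expect_gt(cb$e_x, 0)
})

test_that("constant-age cohorts produce an intercept-only prediction", {
  set.seed(2)
  tab <- make_table(matrix(runif(12 * 3, 30, 50), 12, 3), rep(42, 12))
  cb <- fit_view_combiner(tab, tab)
  pr <- predict(cb, tab)
  expect_equal(pr$predicted, rep(42, 12), tolerance = 1e-8)
})

test_that("singular designs fall back to ridge and are flagged", {
  set.seed(3)
  ages <- runif(4, 20, 80)
  # more slices than training subjects -> singular OLS design
  tab <- make_table(matrix(ages + rnorm(4 * 6, 0, 2), 4, 6), ages)
  cb <- fit_view_combiner(tab, tab)
  expect_identical(cb$method, "ridge")
  expect_length(cb$coefficients, 6)
  expect_true(is.finite(cb$e_x))
})

test_that("combiner beats the unweighted slice mean on noisy tables", {
  set.seed(4)
  n <- 200
  S <- 8
  ages <- runif(n, 20, 80)
  noise_sd <- seq(1, 15, length.out = S) # slice-specific noise levels
  preds <- sapply(seq_len(S), function(s) ages + rnorm(n, 0, noise_sd[s]))
  tr_idx <- 1:120
  tr <- make_table(preds[tr_idx, ], ages[tr_idx])
  va <- make_table(preds[-tr_idx, ], ages[-tr_idx], ids = sprintf("v%03d", 1:80))
  cb <- fit_view_combiner(tr, va)
  mean_pred_mae <- mean(abs(rowMeans(preds[-tr_idx, ]) - ages[-tr_idx]))
  expect_lte(cb$e_x, mean_pred_mae)
})

test_that("inverse-error ensemble matches direct arithmetic", {
  # equal errors reduce to the arithmetic mean
  expect_equal(as.vector(ensemble_age(c(30, 36, 42), c(3, 3, 3))), 36)
  # consensus is invariant to the errors
  expect_equal(as.vector(ensemble_age(c(40, 40, 40), c(1, 9, 2))), 40)
  # errors (2, 4, 4) give weights (0.5, 0.25, 0.25)
  out <- ensemble_age(c(30, 36, 42), c(2, 4, 4))
  expect_equal(as.vector(out), 34.5)
  expect_equal(unname(attr(out, "weights")), c(0.5, 0.25, 0.25))

  expect_error(ensemble_age(c(30, 40), c(1, -1)), "positive")
  expect_error(ensemble_age(c(30, 40), c(1, 0)), "positive")
  expect_error(ensemble_age(numeric(0), numeric(0)), "at least one view")
  # subsets of views are allowed and renormalize
  expect_equal(as.vector(ensemble_age(c(30, 50), c(1, 1))), 40)
})

test_that("ensemble output stays in the convex hull and is shift-equivariant", {
  set.seed(6)
  for (i in 1:200) {
    ages <- runif(3, 15, 95)
    errs <- runif(3, 0.2, 10)
    y <- as.vector(ensemble_age(ages, errs))
    expect_gte(y, min(ages) - 1e-12)
    expect_lte(y, max(ages) + 1e-12)
    expect_equal(as.vector(ensemble_age(ages + 5, errs)), y + 5, tolerance = 1e-10)
    expect_equal(sum(attr(ensemble_age(ages, errs), "weights")), 1, tolerance = 1e-12)
  }
})

test_that("full pipeline: three-view ensemble at least matches the worst view", {
  sp <- small_pipeline()
  res <- sp$result
  expect_true(all(c("age_axial", "age_coronal", "age_sagittal", "age_combined") %in% names(res)))
  # combined age within per-view min/max for every subject
  per_view <- as.matrix(res[, c("age_axial", "age_coronal", "age_sagittal")])
  expect_true(all(res$age_combined >= apply(per_view, 1, min) - 1e-9))
  expect_true(all(res$age_combined <= apply(per_view, 1, max) + 1e-9))

  view_mae <- apply(abs(per_view - res$age), 2, mean)
  combined_mae <- mean(abs(res$age_combined - res$age))
  expect_lte(combined_mae, max(view_mae))

  g <- glance(res)
  expect_true(all(c("mae", "r2", "spearman_gap_age") %in% names(g)))
  expect_equal(g$mae, combined_mae)
})

test_that("pipeline errors on mismatched views", {
  sp <- small_pipeline()
  vols <- preprocess_cohort(sp$cohort$volumes[1:3])
  expect_error(
    run_full_pipeline(
      vols, sp$cohort$records,
      sp$pipeline$models["axial"], sp$pipeline$combiners["coronal"]
    ),
    "same views"
  )
})

test_that("combiners persist to JSON and back", {
  set.seed(9)
  ages <- runif(15, 20, 80)
  tab <- make_table(matrix(ages + rnorm(45, 0, 2), 15, 3), ages)
  cb <- fit_view_combiner(tab, tab)
  path <- withr::local_tempfile(fileext = ".json")
  save_combiner(cb, path)
  cb2 <- load_combiner(path)
  expect_equal(cb2$coefficients, cb$coefficients, tolerance = 1e-12)
  expect_equal(cb2$e_x, cb$e_x, tolerance = 1e-12)
  expect_equal(predict(cb2, tab)$predicted, predict(cb, tab)$predicted, tolerance = 1e-10)
})
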