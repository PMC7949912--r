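#' Fit a per-view linear combiner of slice predictions
#'
#' Ordinary least squares from a subject's vector of per-slice predicted
#' ages to the true age, fitted on the training table (not the validation
#' table, to avoid circular analysis). The combiner's validation error `e_x`
#' — the weight source for the inverse-error ensemble — is the MAE of the
#' fitted combiner on the validation table. If the design is singular
#' (slices >= training subjects, or collinear slice predictions) the fit
#' falls back to ridge regression with a documented penalty and is flagged
#' in the metadata.
#'
#' @param train_table `slice_prediction_table` used to fit the coefficients.
#' @param val_table `slice_prediction_table` used to estimate `e_x`.
#' @param ridge_penalty Ridge penalty used only on singular designs.
#' @return An object of class `view_combiner` with fields `orientation`,
#'   `coefficients` (length `S_x`), `intercept`, `e_x`, `method`.
#' @export
fit_view_combiner <- function(train_table, val_table, ridge_penalty = 1e-2) {
  Xtr <- prediction_matrix(train_table)
  ytr <- attr(Xtr, "age")
  S <- ncol(Xtr)
  n <- nrow(Xtr)
  design <- cbind(1, unclass(Xtr))
  method <- "ols"
  coefs <- NULL
  if (n > S) {
    fit <- lm.fit(design, ytr)
    coefs <- fit$coefficients
    # pivoted-out (collinear) columns get zero weight; the fit is still the
    # least-squares interpolant
    coefs[is.na(coefs)] <- 0
  } else {
    method <- "ridge"
    # penalize slice coefficients but not the intercept
    pen <- diag(c(0, rep(ridge_penalty, S)))
    coefs <- solve(crossprod(design) + pen, crossprod(design, ytr))[, 1]
  }
  out <- structure(
    list(
      orientation = train_table$orientation[1],
      coefficients = unname(coefs[-1]),
      intercept = unname(coefs[1]),
      n_slices = S, n_train = n, method = method,
      fit_split = "train", e_x = NA_real_
    ),
    class = "view_combiner"
  )
  val_pred <- predict(out, val_table)
  out$e_x <- mean(abs(val_pred$predicted - val_pred$age))
  out
}

#' @export
predict.view_combiner <- function(object, table, ...) {
  X <- prediction_matrix(table)
  if (ncol(X) != object$n_slices) {
    abort(sprintf(
      "table has %d slices but combiner was fitted on %d", ncol(X), object$n_slices
    ))
  }
  tibble::tibble(
    participant_id = rownames(X),
    age = attr(X, "age"),
    predicted = as.vector(unclass(X) %*% object$coefficients + object$intercept)
  )
}

#' @export
print.view_combiner <- function(x, ...) {
  cat("<view_combiner> ", x$orientation, ": ", x$n_slices,
    " slice coefficients (", x$method, "), validation MAE e_x = ",
    format(x$e_x, digits = 4), " years\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.view_combiner <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("slice_", seq_len(x$n_slices))),
    estimate = c(x$intercept, x$coefficients)
  )
}

#' @export
glance.view_combiner <- function(x, ...) {
  tibble::tibble(
    orientation = x$orientation, n_slices = x$n_slices,
    n_train = x$n_train, method = x$method, e_x = x$e_x
  )
}

#' Inverse-validation-error weighted ensemble of per-view ages
#'
#' The final age is the weighted average of the per-view combined ages with
#' weights proportional to `1 / e_x`, the reciprocal of each view's
#' validation error, normalized to sum to one:
#' `age = sum(L_x / e_x) / sum(1 / e_x)`. Any non-empty subset of views is
#' allowed; weights renormalize over the views supplied.
#'
#' @param view_ages Numeric vector (one subject, one age per view) or an
#'   n-subjects x n-views matrix/data frame of per-view combined ages.
#' @param view_errors Positive numeric vector of validation errors `e_x`,
#'   one per view.
#' @return Numeric vector of combined ages with the normalized weights
#'   attached as attribute `"weights"`.
#' @export
ensemble_age <- function(view_ages, view_errors) {
  if (length(view_errors) < 1) abort("at least one view is required.")
  if (any(!is.finite(view_errors)) || any(view_errors <= 0)) {
    abort("all view errors e_x must be positive and finite.")
  }
  A <- if (is.matrix(view_ages) || is.data.frame(view_ages)) {
    as.matrix(view_ages)
  } else {
    matrix(view_ages, nrow = 1)
  }
  if (ncol(A) != length(view_errors)) {
    abort("number of views in `view_ages` and `view_errors` differ.")
  }
  w <- (1 / view_errors) / sum(1 / view_errors)
  out <- as.vector(A %*% w)
  attr(out, "weights") <- setNames(w, colnames(A))
  out
}

#' Run the full slice-to-ensemble prediction pipeline
#'
#' For each configured view: build the per-slice prediction table, apply the
#' view combiner, then merge the per-view ages with the inverse-error
#' weighted ensemble. Returns the per-subject table plus cohort summary
#' metrics (MAE, R-squared, and the Spearman correlation between the brain
#' age gap — predicted minus true — and true age).
#'
#' @param volumes List of preprocessed [segmented_volume()]s.
#' @param records Participants tibble.
#' @param models Named list of trained `orientation_regressor`s (names among
#'   `"axial"`, `"coronal"`, `"sagittal"`).
#' @param combiners Named list of fitted [fit_view_combiner()]s with the
#'   same names.
#' @param tissue Tissue configuration passed to slice extraction.
#' @return A tibble of class `ensemble_result` with columns
#'   `participant_id`, `age`, one `age_<view>` column per view, and
#'   `age_combined`; summary metrics are available via [glance()].
#' @export
run_full_pipeline <- function(volumes, records, models, combiners,
                              tissue = "both") {
  views <- names(models)
  if (is.null(views) || !length(views)) abort("`models` must be a named list.")
  if (!setequal(views, names(combiners))) {
    abort("`models` and `combiners` must cover the same views.")
  }
  per_view <- lapply(views, function(v) {
    tab <- build_prediction_table(models[[v]], volumes, records, v, tissue)
    predict(combiners[[v]], tab)
  })
  base <- per_view[[1]][, c("participant_id", "age")]
  A <- vapply(per_view, function(p) p$predicted, numeric(nrow(base)))
  colnames(A) <- views
  e <- vapply(views, function(v) combiners[[v]]$e_x, numeric(1))
  combined <- ensemble_age(A, e)
  out <- base
  for (v in views) out[[paste0("age_", v)]] <- A[, v]
  out$age_combined <- as.vector(combined)
  gap <- out$age_combined - out$age
  attr(out, "weights") <- attr(combined, "weights")
  attr(out, "summary") <- tibble::tibble(
    mae = mean(abs(gap)),
    r2 = 1 - sum(gap^2) / sum((out$age - mean(out$age))^2),
    spearman_gap_age = stats::cor(gap, out$age, method = "spearman")
  )
  class(out) <- c("ensemble_result", class(out))
  out
}

#' @export
glance.ensemble_result <- function(x, ...) {
  attr(x, "summary")
}
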