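effect_row <- function(grouping, view, type, t, df, p, alpha, note = NA_character_) {
  tibble::tibble(
    grouping = as.character(grouping), view = as.character(view),
    test_type = type, t = t, df = df, p = p,
    significant = !is.na(p) & p < alpha, note = note
  )
}

#' Two-tailed dependent (paired) t-test
#'
#' Classical paired t on the differences, with the two-sided p-value from
#' the t distribution with n - 1 degrees of freedom. Zero-variance
#' differences raise an error rather than returning an infinite statistic.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @param alpha Significance threshold used for the `significant` flag.
#' @param grouping,view Labels carried into the result row.
#' @return A one-row tibble: `grouping`, `view`, `test_type` (`"dependent"`),
#'   `t`, `df`, `p`, `significant`.
#' @export
paired_t <- function(x, y, alpha = 0.03, grouping = NA, view = NA) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need n >= 2 pairs.")
  if (sd(x - y) == 0) {
    abort("zero-variance differences: paired t statistic undefined.")
  }
  ht <- t.test(x, y, paired = TRUE)
  effect_row(
    grouping, view, "dependent",
    unname(ht$statistic), unname(ht$parameter), ht$p.value, alpha
  )
}

#' Two-tailed independent (unpaired) t-test
#'
#' Pooled-variance two-sample t by default; set `welch = TRUE` for the
#' Welch unequal-variance form.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param alpha Significance threshold for the flag.
#' @param welch Use the Welch test instead of pooled variance.
#' @param grouping,view Labels carried into the result row.
#' @return A one-row tibble as in [paired_t()], `test_type`
#'   `"independent"`.
#' @export
unpaired_t <- function(x, y, alpha = 0.03, welch = FALSE,
                       grouping = NA, view = NA) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs n >= 2.")
  ht <- t.test(x, y, var.equal = !welch)
  effect_row(
    grouping, view, "independent",
    unname(ht$statistic), unname(ht$parameter), ht$p.value, alpha
  )
}

#' Site-effect report: paired t-tests of age vs. predicted age per site
#'
#' For every (site, view) cell, a two-tailed dependent t-test comparing
#' chronological age with predicted age, flagged at `alpha` (default 0.03,
#' the conventional bolding threshold in multi-site brain-age reports; no
#' multiple-testing correction is applied by default, use
#' `adjust = "BH"` for a Benjamini-Hochberg variant). Sites whose
#' predictions equal age exactly are reported as "no effect" rows; singleton
#' sites are skipped with a warning and listed with NA statistics.
#'
#' @param predictions Tibble with `participant_id`, `view`, `predicted_age`
#'   (one row per subject per view).
#' @param records Participants tibble with `participant_id`, `age`, `site`.
#' @param alpha Significance threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per (site, view).
#' @export
site_effect_report <- function(predictions, records, alpha = 0.03,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!all(predictions$participant_id %in% records$participant_id)) {
    abort("predictions contain subjects absent from records.")
  }
  df <- dplyr::inner_join(
    predictions, records[, c("participant_id", "age", "site")],
    by = "participant_id"
  )
  rows <- df |>
    dplyr::group_by(.data$site, .data$view) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 2) {
        warn(sprintf("site %s has a single subject; skipped.", key$site))
        return(effect_row(key$site, key$view, "dependent",
          NA_real_, NA_real_, NA_real_, alpha,
          note = "singleton site, skipped"
        ))
      }
      if (sd(g$age - g$predicted_age) == 0) {
        return(effect_row(key$site, key$view, "dependent",
          0, nrow(g) - 1, 1, alpha,
          note = "zero-variance differences: no effect"
        ))
      }
      paired_t(g$age, g$predicted_age, alpha, grouping = key$site, view = key$view)
    }) |>
    dplyr::bind_rows()
  if (adjust == "BH") {
    rows$p_adjusted <- stats::p.adjust(rows$p, method = "BH")
    rows$significant <- !is.na(rows$p_adjusted) & rows$p_adjusted < alpha
  }
  rows
}

#' Sex-effect report: the four standard tests
#'
#' Exactly four rows: an independent (unpaired) male-vs-female test on
#' chronological age, the same on predicted age, and dependent (paired)
#' age-vs-prediction tests within males and within females — test types
#' I, I, D, D.
#'
#' @param predictions Tibble with `participant_id`, `predicted_age` (one
#'   row per subject for the view under test).
#' @param records Participants tibble with `participant_id`, `age`, `sex`
#'   (`"F"`/`"M"`).
#' @param alpha Significance threshold.
#' @return A four-row tibble.
#' @export
sex_effect_report <- function(predictions, records, alpha = 0.03) {
  df <- dplyr::inner_join(
    predictions, records[, c("participant_id", "age", "sex")],
    by = "participant_id"
  )
  if (anyNA(df$sex)) abort("missing sex label.")
  if (!all(c("F", "M") %in% df$sex)) abort("both sexes must be present.")
  m <- df[df$sex == "M", ]
  f <- df[df$sex == "F", ]
  zero_safe_paired <- function(x, y, grouping) {
    if (sd(x - y) == 0) {
      effect_row(grouping, NA, "dependent", 0, length(x) - 1, 1, alpha,
        note = "zero-variance differences: no effect"
      )
    } else {
      paired_t(x, y, alpha, grouping = grouping)
    }
  }
  dplyr::bind_rows(
    unpaired_t(m$age, f$age, alpha, grouping = "M vs F: age"),
    unpaired_t(m$predicted_age, f$predicted_age, alpha, grouping = "M vs F: prediction"),
    zero_safe_paired(m$age, m$predicted_age, "M: age vs prediction"),
    zero_safe_paired(f$age, f$predicted_age, "F: age vs prediction")
  )
}

#' Fit the brain-age-gap vs. age regression line
#'
#' Least-squares line of the gap (predicted minus true age) against true
#' age. Slice-level regressors systematically overestimate ages below the
#' cohort mean and underestimate above it, which shows up here as a
#' negative slope (regression to the mean).
#'
#' @param predictions Numeric vector of predicted ages.
#' @param ages Numeric vector of true ages (n >= 3, non-constant).
#' @return An object of class `age_bias_fit` with `slope`, `intercept`,
#'   `mean_age`, and the underlying data.
#' @export
age_bias_fit <- function(predictions, ages) {
  if (length(predictions) != length(ages)) abort("length mismatch.")
  if (length(ages) < 3) abort("need n >= 3.")
  if (sd(ages) == 0) abort("constant ages: slope undefined.")
  gap <- predictions - ages
  fit <- lm.fit(cbind(1, ages), gap)
  structure(
    list(
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      mean_age = mean(ages),
      data = tibble::tibble(age = ages, gap = gap)
    ),
    class = "age_bias_fit"
  )
}

#' @export
print.age_bias_fit <- function(x, ...) {
  cat("<age_bias_fit> gap = ", format(x$intercept, digits = 4), " + ",
    format(x$slope, digits = 4), " * age  (cohort mean age ",
    format(x$mean_age, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.age_bias_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "age"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.age_bias_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    mean_age = x$mean_age, n = nrow(x$data)
  )
}
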