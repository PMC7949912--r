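#' Plot a per-slice error profile
#'
#' MAE against slice index with the 0.95 confidence band; multiple splits
#' (train/validation) can be overlaid by row-binding profiles first.
#'
#' @param object A [slice_error_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slice_error_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$slice_index, y = .data$mae,
    colour = .data$split, fill = .data$split
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mae - .data$ci_halfwidth,
        ymax = .data$mae + .data$ci_halfwidth
      ),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "slice index", y = "MAE (years)",
      title = paste0("Per-slice error profile (", object$orientation[1], ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs. true age for an ensemble result
#'
#' @param object An [run_full_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$age_combined)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (years)", y = "predicted age (years)") +
    ggplot2::theme_minimal()
}

#' Plot the brain-age gap against age with the bias regression line
#'
#' The vertical reference marks the cohort mean age, the horizontal marks
#' zero gap; the fitted line visualizes over-estimation below the mean and
#' under-estimation above it.
#'
#' @param object An [age_bias_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_bias_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$gap)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$mean_age, linetype = "dashed", colour = "red") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "blue"
    ) +
    ggplot2::labs(x = "chronological age (years)", y = "brain age gap (years)") +
    ggplot2::theme_minimal()
}

#' Lightbox plot of a brain-age map
#'
#' Axial slices of the voxel-level age map on a fixed display range
#' (default 20-60 years).
#'
#' @param object A `brain_age_map`.
#' @param n_slices Number of axial slices to show.
#' @param range Display range in years.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brain_age_map <- function(object, n_slices = 12,
                                   range = object$display_range, ...) {
  d <- dim(object$grid)
  ks <- unique(round(seq(1, d[3], length.out = min(n_slices, d[3]))))
  df <- purrr::map_dfr(ks, function(k) {
    tibble::tibble(
      slice = k,
      row = rep(seq_len(d[1]), times = d[2]),
      col = rep(seq_len(d[2]), each = d[1]),
      age = as.vector(object$grid[, , k])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$age)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient(
      low = "red", high = "yellow", limits = range, oob = scales_squish
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "age (years)") +
    ggplot2::theme_void()
}

# minimal squish to avoid a scales dependency
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}
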