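#' Plot an area ranking
#'
#' Dot plot of the per-area median hold-out MAE, with the age-only baseline
#' (dashed) and the across-area two-sigma relevance threshold (dotted).
#'
#' @param object An `area_ranking_set` from [rank_areas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.area_ranking_set <- function(object, ...) {
  d <- object$summary
  thr <- mean(d$median_mae) - 2 * stats::sd(d$median_mae)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(factor(.data$roi_label), .data$median_mae),
      y = .data$median_mae
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(
      yintercept = object$baseline_mae, linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted") +
    ggplot2::labs(
      x = "brain area (ROI label)",
      y = "median hold-out MAE (normalized score)",
      title = paste0(
        "Area ranking (", object$test,
        "); dashed = age-only baseline, dotted = two-sigma threshold"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a feature-family importance breakdown
#'
#' Stacked bar of the relative Gini-importance share of each feature family
#' (age, volume, shape, intensity, texture), rescaled to 100%.
#'
#' @param object An `importance_breakdown` from [family_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_breakdown <- function(object, ...) {
  d <- dplyr::mutate(object$family,
    area = if (is.null(object$roi_label)) {
      "area"
    } else {
      paste0("ROI ", object$roi_label)
    }
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$area, y = .data$share_pct, fill = .data$family)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "relative importance (%)", fill = "family") +
    ggplot2::theme_minimal()
}

#' Family-importance comparison across several areas
#'
#' Stacked bars of family shares for a list of breakdowns (one bar per
#' area), the usual way to compare which families drive the selected areas.
#'
#' @param breakdowns Named list of `importance_breakdown` objects (names =
#'   area labels, e.g. the `importance` element per test of a
#'   [run_pipeline()] result).
#' @return A ggplot object.
#' @export
plot_family_importance <- function(breakdowns) {
  stopifnot(length(breakdowns) > 0)
  d <- dplyr::bind_rows(lapply(names(breakdowns), function(nm) {
    dplyr::mutate(breakdowns[[nm]]$family, area = nm)
  }))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$area, y = .data$share_pct, fill = .data$family)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = "brain area", y = "relative importance (%)",
      fill = "family"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the randomization-test noise distribution
#'
#' Histogram of replicate median MAEs with the fitted normal mean (solid)
#' and the two-sigma significance threshold (dashed).
#'
#' @param object A `noise_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.noise_distribution <- function(object, ...) {
  d <- tibble::tibble(mae = object$replicate_mae)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mae)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mu) +
    ggplot2::geom_vline(
      xintercept = object$mu - 2 * object$sigma, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "median MAE of random-feature models",
      y = "replicates"
    ) +
    ggplot2::theme_minimal()
}
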