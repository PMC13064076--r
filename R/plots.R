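#' Plot a threshold-by-feature frequency histogram
#'
#' Color-coded 2D frequency distribution of one event feature across the
#' Ca2+ threshold ladder (thresholds on the y axis, log-spaced feature bins
#' on the x axis, per-cell event frequency as fill).
#'
#' @param object A [accumulate_histograms()] result.
#' @param feature Feature to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_histogram <- function(object, feature = "max_size_um2", ...) {
  h <- dplyr::filter(object, .data$feature == !!feature)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid,
                                  y = factor(.data$threshold),
                                  fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(name = "events/cell/600 s") +
    ggplot2::labs(x = feature, y = expression(paste(Delta, "F/F"[R], " threshold"))) +
    ggplot2::theme_minimal()
}

#' Plot cumulative feature curves
#'
#' @param object A [cumulative_distribution()] result (or several row-bound
#'   together with a `condition` column for overlays).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cumulative_curve <- function(object, ...) {
  aes <- if ("condition" %in% names(object)) {
    ggplot2::aes(x = .data$x, y = .data$cdf, colour = .data$condition)
  } else {
    ggplot2::aes(x = .data$x, y = .data$cdf)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(object$feature), y = "cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Plot condition-wise mean NMF component weights
#'
#' @param object An `mted_nmf` fit with labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mted_nmf <- function(object, ...) {
  mw <- mean_component_weights(object)
  ggplot2::ggplot(mw, ggplot2::aes(x = .data$condition, y = .data$mean_weight,
                                   fill = factor(.data$component))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_weight - .data$sd_weight,
                   ymax = .data$mean_weight + .data$sd_weight),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = NULL, y = "mean component weight", fill = "component") +
    ggplot2::theme_minimal()
}

#' Plot an LDA projection
#'
#' Recordings on the first two discriminant axes (or a strip plot when only
#' one axis exists), colored by condition, with class centroids marked.
#'
#' @param object An `mted_lda` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mted_lda <- function(object, ...) {
  co <- object$coordinates
  if ("LD2" %in% names(co)) {
    cen <- tibble::as_tibble(object$centroids)
    cen$condition <- rownames(object$centroids)
    ggplot2::ggplot(co, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                     colour = .data$condition)) +
      ggplot2::geom_point() +
      ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 2) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(co, ggplot2::aes(x = .data$LD1, y = .data$condition,
                                     colour = .data$condition)) +
      ggplot2::geom_jitter(height = 0.1) +
      ggplot2::theme_minimal()
  }
}
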