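#' Default log-spaced bin edges for the four event features
#'
#' Event features are heavy-tailed, so bins are log-spaced. Ranges:
#' max size 1–1e4 um^2, duration 0.2–600 s, distance 0.1–100 um,
#' max slope 1e-3–1e2 s^-1; 32 bins each. All configurable.
#'
#' @param n_bins Bins per feature.
#' @return Named list of numeric edge vectors, one per feature column name.
#' @export
feature_bins <- function(n_bins = 32) {
  ranges <- list(
    max_size_um2 = c(1, 1e4),
    duration_s = c(0.2, 600),
    distance_um = c(0.1, 100),
    max_slope_per_s = c(1e-3, 1e2)
  )
  lapply(ranges, function(r) {
    exp(seq(log(r[1]), log(r[2]), length.out = n_bins + 1))
  })
}

# Histogram of one feature at one level for one recording, per-cell scaled
# and rescaled to a common 600 s recording equivalent. Out-of-range values
# are clamped to the edge bins; the clamp count is returned as an attribute.
bin_events <- function(values, edges, n_cells, duration_s, equiv_s = 600) {
  clamped <- sum(values < edges[1] | values > edges[length(edges)])
  v <- pmin(pmax(values, edges[1]), edges[length(edges)])
  counts <- as.numeric(table(cut(v, edges, include.lowest = TRUE)))
  freq <- counts / n_cells * equiv_s / duration_s
  attr(freq, "clamped") <- clamped
  freq
}

#' Accumulate per-cell-scaled feature histograms across recordings
#'
#' For every feature and threshold level, event counts are binned, divided by
#' the recording's cell count, rescaled to a common 600-second recording
#' equivalent, and then averaged across recordings with equal weight (the
#' recording is the statistical unit). The result is the 2D
#' threshold-by-feature frequency distribution used for the color-coded
#' histogram displays.
#'
#' @param tables List of `mted_events` tibbles (one per recording) sharing
#'   the same ladder, or a single table.
#' @param bins Bin edges from [feature_bins()].
#' @param features Feature columns to histogram.
#' @return A tibble of class `feature_histogram`: columns `feature`,
#'   `threshold`, `bin` (index), `bin_lo`, `bin_hi`, `bin_mid`, `freq`
#'   (events per cell per 600 s, averaged over recordings). The number of
#'   range-clamped events is stored in `attr(, "clamped")`.
#' @export
accumulate_histograms <- function(tables, bins = feature_bins(),
                                  features = names(bins)) {
  if (inherits(tables, "mted_events")) tables <- list(tables)
  if (!length(tables)) stop("no event tables supplied", call. = FALSE)
  ladders <- lapply(tables, attr, "ladder")
  ladder <- ladders[[1]]
  if (!all(vapply(ladders, identical, logical(1), ladder))) {
    stop("all recordings must share the same threshold ladder", call. = FALSE)
  }

  clamped_total <- 0L
  per_rec <- lapply(tables, function(tb) {
    n_cells <- if (nrow(tb)) tb$n_cells[1] else 1L
    dur <- if (nrow(tb)) tb$duration_recorded_s[1] else 600
    purrr::map_dfr(features, function(feat) {
      edges <- bins[[feat]]
      purrr::map_dfr(ladder, function(level) {
        vals <- tb[[feat]][tb$threshold == level]
        freq <- bin_events(vals, edges, n_cells, dur)
        clamped_total <<- clamped_total + attr(freq, "clamped")
        nb <- length(edges) - 1
        tibble::tibble(
          feature = feat, threshold = level, bin = seq_len(nb),
          bin_lo = edges[-length(edges)], bin_hi = edges[-1],
          bin_mid = sqrt(edges[-length(edges)] * edges[-1]),
          freq = as.numeric(freq)
        )
      })
    })
  })

  out <- dplyr::bind_rows(per_rec, .id = ".rec") |>
    dplyr::group_by(.data$feature, .data$threshold, .data$bin,
                    .data$bin_lo, .data$bin_hi, .data$bin_mid) |>
    dplyr::summarise(freq = mean(.data$freq), .groups = "drop") |>
    dplyr::arrange(.data$feature, .data$threshold, .data$bin)
  if (clamped_total > 0) {
    message("accumulate_histograms: ", clamped_total,
            " events clamped to edge bins")
  }
  attr(out, "ladder") <- ladder
  attr(out, "n_recordings") <- length(tables)
  attr(out, "clamped") <- clamped_total
  class(out) <- c("feature_histogram", class(out))
  out
}

#' Cumulative distribution of a feature at one threshold level
#'
#' Normalized running sum of the histogram mass over the feature bins at the
#' chosen level. A level without events yields a flat curve flagged
#' degenerate.
#'
#' @param hist A [accumulate_histograms()] result.
#' @param feature Feature name.
#' @param level Threshold level (must be on the ladder).
#' @return A tibble of class `cumulative_curve`: `x` (bin upper edges),
#'   `cdf`; attribute `degenerate` when the level holds no events.
#' @export
cumulative_distribution <- function(hist, feature = "max_size_um2", level = 2) {
  stopifnot(inherits(hist, "feature_histogram"))
  ladder <- attr(hist, "ladder")
  if (!level %in% ladder) stop("level ", level, " is not on the ladder", call. = FALSE)
  h <- dplyr::filter(hist, .data$feature == !!feature, .data$threshold == level)
  total <- sum(h$freq)
  degenerate <- total <= 0
  cdf <- if (degenerate) rep(0, nrow(h)) else cumsum(h$freq) / total
  out <- tibble::tibble(feature = feature, threshold = level,
                        x = h$bin_hi, cdf = cdf)
  attr(out, "degenerate") <- degenerate
  if (degenerate) {
    warning("no events at level ", level, "; flat curve", call. = FALSE)
  }
  class(out) <- c("cumulative_curve", class(out))
  out
}

#' Marker-positive cell fraction in percent
#'
#' Simple proportion summary used for culture-purity counts (e.g. cells with
#' microglial marker immunofluorescence among all counted cells), reported to
#' two decimals as a percentage.
#'
#' @param n_positive,n_total Non-negative counts, `n_positive <= n_total`,
#'   `n_total > 0`.
#' @return Percentage rounded to two decimals.
#' @examples
#' marker_positive_fraction(9, 4051) # 0.22
#' marker_positive_fraction(2, 1961) # 0.10
#' @export
marker_positive_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  stopifnot(all(n_positive >= 0), all(n_positive <= n_total))
  round(100 * n_positive / n_total, 2)
}
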