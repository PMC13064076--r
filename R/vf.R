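#' Per-pixel volume fraction from the reference channel
#'
#' The Ca2+-insensitive reference brightness is proportional to indicator
#' expression, which scales with the cell volume inside the optical voxel.
#' Within each cell the reference is normalized to a robust per-cell maximum
#' (99th percentile of that cell's pixels) and expressed in percent, capped
#' at 100. Per-cell (rather than global) normalization makes the measure a
#' within-cell morphological quantity, independent of expression differences
#' between cells.
#'
#' @param reference A [reference_map()].
#' @param cell_labels Integer matrix of cell ids (0 = background), e.g. the
#'   simulator's label map or a manual segmentation.
#' @param anchor_quantile Per-cell quantile anchoring 100%.
#' @return Numeric matrix of volume fractions in percent (`NA` outside
#'   cells).
#' @export
compute_vf <- function(reference, cell_labels, anchor_quantile = 0.99) {
  stopifnot(inherits(reference, "reference_map"), is.matrix(cell_labels),
            identical(dim(cell_labels), dim(reference$fr)))
  if (!any(cell_labels > 0)) stop("cell_labels holds no cells", call. = FALSE)
  vf <- matrix(NA_real_, nrow(cell_labels), ncol(cell_labels))
  for (ci in sort(unique(cell_labels[cell_labels > 0]))) {
    px <- cell_labels == ci
    vals <- reference$fr[px]
    anchor <- stats::quantile(vals, anchor_quantile, names = FALSE)
    if (anchor <= 0 || stats::sd(vals) == 0) {
      warning("cell ", ci, " has a degenerate (uniform) reference; vf set to 100",
              call. = FALSE)
      vf[px] <- 100
    } else {
      vf[px] <- pmin(100 * vals / anchor, 100)
    }
  }
  vf
}

#' Relative basal Ca2+ in the low-volume-fraction periphery
#'
#' Compares the green-channel baseline F0 against the zero-Ca2+ reference
#' F_R in thin peripheral regions (volume fraction at most `vf_max`,
#' default 12.5%). The per-cell `basal_ratio = mean(F0_green / F_R)` is 1
#' for a cell at zero Ca2+ and grows with resting Ca2+; inverting the Hill
#' model maps it back to a concentration estimate,
#' `basal_ca_est = hill_inverse((basal_ratio - 1) / (dyn_range - 1))`.
#' The dimensionless ratio is the primary readout (it does not depend on the
#' assumed sensor dynamic range); the nM estimate is reported alongside.
#'
#' Pixels whose implied saturation falls outside `[0, 1)` (possible under
#' noise) are excluded from the concentration estimate and counted in the
#' `n_flagged` column.
#'
#' @param f0_green `baseline_map` of the unmixed green channel.
#' @param reference A [reference_map()] (calibrate `scale_k` on control
#'   recordings and reuse it, so ratios are comparable across recordings).
#' @param vf_map Volume-fraction matrix from [compute_vf()].
#' @param cell_labels Integer matrix of cell ids.
#' @param vf_max Peripheral band upper limit in percent.
#' @param hill [hill_params()] used for the inversion.
#' @return A tibble of class `vf_profile`, one row per cell: `cell_id`,
#'   `n_pixels`, `basal_ratio`, `basal_ca_est`, `n_flagged`.
#' @export
basal_level <- function(f0_green, reference, vf_map, cell_labels,
                        vf_max = 12.5, hill = hill_params(dyn_range = 6)) {
  stopifnot(inherits(f0_green, "baseline_map"), inherits(reference, "reference_map"))
  band <- !is.na(vf_map) & vf_map <= vf_max & cell_labels > 0
  if (!any(band)) {
    stop("no pixels with volume fraction <= ", vf_max, "%", call. = FALSE)
  }
  rows <- lapply(sort(unique(cell_labels[band])), function(ci) {
    px <- band & cell_labels == ci
    ratio <- f0_green$f0[px] / reference$fr[px]
    basal_ratio <- mean(ratio)
    theta <- (ratio - 1) / (hill$dyn_range - 1)
    ok <- theta >= 0 & theta < 1
    mean_theta <- (basal_ratio - 1) / (hill$dyn_range - 1)
    est <- if (mean_theta >= 0 && mean_theta < 1) {
      hill_inverse(mean_theta, hill)
    } else if (mean_theta < 0) 0 else NA_real_
    tibble::tibble(cell_id = ci, n_pixels = sum(px),
                   basal_ratio = basal_ratio, basal_ca_est = est,
                   n_flagged = sum(!ok))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "vf_max") <- vf_max
  class(out) <- c("vf_profile", class(out))
  out
}
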