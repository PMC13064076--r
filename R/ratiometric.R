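#' Spectral unmixing of a two-channel movie
#'
#' Applies the inverse of the 2x2 mixing matrix to every pixel pair to undo
#' spectral overlap between the green and red fluorophores. Negative values
#' produced by noisy inputs are clipped to zero (the clip count is reported
#' as a message).
#'
#' @param movie A [two_channel_movie()].
#' @param mixing 2x2 mixing matrix: `detected = mixing %*% pure`. Must be
#'   invertible; should be diagonally dominant (each fluorophore lands mostly
#'   in its own channel).
#' @return A [two_channel_movie()] with unmixed channels.
#' @export
unmix <- function(movie, mixing) {
  stopifnot(inherits(movie, "two_channel_movie"))
  mixing <- as.matrix(mixing)
  if (!identical(dim(mixing), c(2L, 2L))) {
    stop("mixing must be a 2x2 matrix", call. = FALSE)
  }
  if (abs(det(mixing)) < 1e-12 * max(abs(mixing), 1)^2) {
    stop("mixing matrix is singular and cannot be inverted", call. = FALSE)
  }
  inv <- solve(mixing)
  g <- inv[1, 1] * movie$green + inv[1, 2] * movie$red
  r <- inv[2, 1] * movie$green + inv[2, 2] * movie$red
  n_clip <- sum(g < 0) + sum(r < 0)
  if (n_clip > 0) {
    message("unmix: clipped ", n_clip, " negative intensities to 0")
    g <- pmax(g, 0)
    r <- pmax(r, 0)
  }
  two_channel_movie(g, r, movie$pixel_size, movie$frame_interval)
}

#' Per-pixel baseline (F0) estimation
#'
#' Approximates the minimal fluorescence of every pixel over a recording —
#' the sensor brightness at resting Ca2+. The estimator is a sliding-window
#' low-percentile filter: within each window (advancing by half a window) the
#' per-pixel `percentile` order statistic is taken; the resulting envelope is
#' smoothed with a short moving average and its temporal minimum is the
#' baseline. A constant trace maps to itself, and sparse transients shorter
#' than the window are ignored by construction.
#'
#' @param stack 3D array (y, x, frame).
#' @param window Window length in frames (>= 1, <= recording length).
#' @param percentile Percentile level in (0, 50].
#' @param smooth Moving-average length over window positions.
#' @return A `baseline_map`: list with `f0` (matrix), `window`, `percentile`.
#' @export
estimate_f0 <- function(stack, window = 100, percentile = 8, smooth = 3) {
  stopifnot(is.array(stack), length(dim(stack)) == 3,
            window >= 1, percentile > 0, percentile <= 50)
  d <- dim(stack)
  nt <- d[3]
  if (window > nt) {
    stop("window (", window, ") exceeds the recording length (", nt, " frames)",
         call. = FALSE)
  }
  m <- matrix(stack, nrow = d[1] * d[2], ncol = nt)
  stride <- max(1L, floor(window / 2))
  starts <- seq(1L, nt - window + 1L, by = stride)
  if (starts[length(starts)] + window - 1L < nt) {
    starts <- c(starts, nt - window + 1L)
  }
  env <- vapply(starts, function(s) {
    row_quantile(m[, s:(s + window - 1L), drop = FALSE], percentile / 100)
  }, numeric(nrow(m)))
  env <- matrix(env, nrow = nrow(m))
  if (length(starts) > 1 && smooth > 1) {
    env <- t(apply(env, 1L, moving_average, k = smooth))
  }
  f0 <- matrix(apply(env, 1L, min), d[1], d[2])
  structure(list(f0 = f0, window = window, percentile = percentile),
            class = "baseline_map")
}

#' Global reference scaling factor
#'
#' The scaled reference F_R must equal the green-channel fluorescence at zero
#' Ca2+. Because the baseline F0 reflects green brightness at *resting* (not
#' zero) Ca2+, the raw green/red baseline ratio is divided by the Hill-model
#' resting brightness `1 + (dyn_range - 1) * theta(basal_ca)`:
#'
#' `scale_k = median(F0_green / F0_red over cell pixels) / resting_brightness`
#'
#' One scaling factor is computed from designated control recordings and
#' reused for all measurements of a dataset; see [reference_map()].
#'
#' @param f0_green,f0_red `baseline_map`s of the unmixed channels.
#' @param hill [hill_params()]; `basal_ca` and `dyn_range` set the divisor.
#' @param cell_mask Logical matrix selecting cell pixels.
#' @return Scalar `scale_k`.
#' @export
compute_scale_factor <- function(f0_green, f0_red, hill, cell_mask) {
  stopifnot(inherits(f0_green, "baseline_map"), inherits(f0_red, "baseline_map"),
            is.matrix(cell_mask))
  if (!any(cell_mask)) stop("cell_mask is empty", call. = FALSE)
  red_vals <- f0_red$f0[cell_mask]
  if (any(red_vals <= 0)) {
    stop("non-positive red baseline inside the cell mask", call. = FALSE)
  }
  ratio <- stats::median(f0_green$f0[cell_mask] / red_vals)
  ratio / hill_brightness(hill$basal_ca, hill)
}

#' Scaled reference map F_R
#'
#' `fr = scale_k * F0_red` pixelwise. The reference is static over the
#' recording (the red fluorophore is Ca2+-insensitive and photostable on the
#' 10-minute timescale).
#'
#' @param f0_red `baseline_map` of the unmixed red channel.
#' @param scale_k Scaling factor from [compute_scale_factor()].
#' @return A `reference_map`: list with `fr` (matrix) and `scale_k`.
#' @export
reference_map <- function(f0_red, scale_k) {
  stopifnot(inherits(f0_red, "baseline_map"), scale_k > 0)
  structure(list(fr = scale_k * f0_red$f0, scale_k = scale_k),
            class = "reference_map")
}

#' Ratiometric activity signal dF/F_R
#'
#' `dff = (F - F_R) / F_R` per pixel and frame, defined on the analysis mask.
#' Pixels whose reference falls below `fr_floor` are excluded (near-zero
#' references make the ratio unstable); a default floor of 0 keeps every
#' positive-reference pixel. Excluded or non-positive-reference pixels are
#' `NA` in the output, and the number of pixels dropped from a supplied mask
#' is reported.
#'
#' @param green_stack 3D array of the (unmixed) green channel.
#' @param reference A [reference_map()].
#' @param mask Optional logical matrix restricting the analysis; defaults to
#'   `fr > fr_floor`.
#' @param fr_floor Minimum usable reference intensity (a.u.).
#' @param pixel_size,frame_interval Calibration carried into the result.
#' @return A [dff_movie()].
#' @export
compute_dff <- function(green_stack, reference, mask = NULL, fr_floor = 0,
                        pixel_size = 1, frame_interval = 0.2) {
  stopifnot(is.array(green_stack), length(dim(green_stack)) == 3,
            inherits(reference, "reference_map"))
  fr <- reference$fr
  stopifnot(identical(dim(fr), dim(green_stack)[1:2]))
  usable <- fr > fr_floor
  if (is.null(mask)) {
    mask <- usable
  } else {
    dropped <- sum(mask & !usable)
    if (dropped > 0) {
      warning("compute_dff: ", dropped,
              " masked pixels have unusable reference and were excluded",
              call. = FALSE)
    }
    mask <- mask & usable
  }
  d <- dim(green_stack)
  dff <- array(NA_real_, d)
  idx <- which(mask)
  if (length(idx)) {
    g <- matrix(green_stack, d[1] * d[2], d[3])[idx, , drop = FALSE]
    dff_m <- (g - fr[idx]) / fr[idx]
    full <- matrix(NA_real_, d[1] * d[2], d[3])
    full[idx, ] <- dff_m
    dff <- array(full, d)
  }
  dff_movie(dff, mask, pixel_size, frame_interval)
}

#' Full ratiometric normalization of a two-channel movie
#'
#' Convenience wrapper chaining [unmix()], [estimate_f0()] on both channels,
#' [compute_scale_factor()] (unless a precomputed `scale_k` from control
#' recordings is supplied), [reference_map()] and [compute_dff()].
#'
#' @param movie A [two_channel_movie()].
#' @param hill [hill_params()].
#' @param mixing 2x2 mixing matrix (identity = no unmixing).
#' @param scale_k Optional precomputed scaling factor; when `NULL` it is
#'   calibrated from this movie.
#' @param cell_mask Logical matrix of cell pixels; default: pixels whose red
#'   baseline exceeds `mask_quantile` of its positive values.
#' @param window,percentile Baseline estimator settings.
#' @param fr_floor Reference floor for the analysis mask.
#' @param mask_quantile Quantile of positive red baselines used for the
#'   default cell mask.
#' @return List: `dff` ([dff_movie()]), `f0_green`, `f0_red`, `reference`,
#'   `scale_k`, `cell_mask`.
#' @export
normalize_movie <- function(movie, hill = hill_params(dyn_range = 6),
                            mixing = diag(2), scale_k = NULL,
                            cell_mask = NULL, window = 100, percentile = 8,
                            fr_floor = 0, mask_quantile = 0.05) {
  um <- unmix(movie, mixing)
  f0g <- estimate_f0(um$green, window = window, percentile = percentile)
  f0r <- estimate_f0(um$red, window = window, percentile = percentile)
  if (is.null(cell_mask)) {
    pos <- f0r$f0[f0r$f0 > 0]
    if (!length(pos)) stop("no positive red baseline pixels", call. = FALSE)
    cell_mask <- f0r$f0 > stats::quantile(pos, mask_quantile) / 2
  }
  if (is.null(scale_k)) {
    scale_k <- compute_scale_factor(f0g, f0r, hill, cell_mask)
  }
  ref <- reference_map(f0r, scale_k)
  dff <- compute_dff(um$green, ref, mask = cell_mask, fr_floor = fr_floor,
                     pixel_size = movie$pixel_size,
                     frame_interval = movie$frame_interval)
  list(dff = dff, f0_green = f0g, f0_red = f0r, reference = ref,
       scale_k = scale_k, cell_mask = cell_mask)
}
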