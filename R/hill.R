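#' GCaMP6s Hill calibration parameters
#'
#' Bundle of the Hill-model parameters that map free Ca2+ concentration to
#' relative GCaMP6s brightness. Defaults are the published GCaMP6s constants
#' (Kd = 144 nM, Hill coefficient 2.45) and a resting astrocyte Ca2+
#' concentration of 50 nM. The sensor dynamic range (brightness at saturating
#' Ca2+ relative to zero Ca2+) is not pinned down by the sensor literature at
#' the precision needed here, so it is an explicit free parameter; every
#' computation in the package is written to be valid for any `dyn_range > 1`.
#'
#' @param kd Dissociation constant in nM. Must be positive.
#' @param hill_n Hill coefficient (dimensionless, positive).
#' @param dyn_range Ratio of fluorescence at saturating vs zero Ca2+ (> 1).
#' @param basal_ca Assumed resting Ca2+ concentration in nM (>= 0).
#'
#' @return An object of class `hill_params` (a named list).
#' @examples
#' hp <- hill_params()
#' hill_saturation(hp$kd, hp) # 0.5 by definition of Kd
#' @export
hill_params <- function(kd = 144, hill_n = 2.45, dyn_range = 50, basal_ca = 50) {
  stopifnot(kd > 0, hill_n > 0, dyn_range > 1, basal_ca >= 0)
  structure(
    list(kd = kd, hill_n = hill_n, dyn_range = dyn_range, basal_ca = basal_ca),
    class = "hill_params"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "<hill_params> Kd = %g nM, n = %g, dynamic range = %g, basal Ca2+ = %g nM\n",
    x$kd, x$hill_n, x$dyn_range, x$basal_ca
  ))
  invisible(x)
}

#' Hill saturation of a Ca2+ sensor
#'
#' Fractional occupancy theta = ca^n / (kd^n + ca^n). The sensor brightness per
#' unit indicator is then `1 + (dyn_range - 1) * theta` relative to the
#' zero-Ca2+ brightness.
#'
#' @param ca Ca2+ concentration(s) in nM, >= 0. Vectorized.
#' @param hill A [hill_params()] object.
#' @return Saturation fraction(s) in \[0, 1).
#' @export
hill_saturation <- function(ca, hill = hill_params()) {
  stopifnot(all(ca >= 0))
  # work on the log scale so ca^n cannot overflow for large ca
  r <- exp(hill$hill_n * (log(ca) - log(hill$kd)))
  theta <- r / (1 + r)
  theta[ca == 0] <- 0
  theta
}

#' Invert the Hill saturation back to a concentration
#'
#' Exact analytic inverse of [hill_saturation()]:
#' `ca = kd * (theta / (1 - theta))^(1/n)`. theta = 1 corresponds to a
#' saturated sensor, where the concentration is unidentifiable; that input is
#' an error rather than `Inf` so callers must handle saturation explicitly.
#'
#' @param theta Saturation fraction(s) in \[0, 1). Vectorized.
#' @inheritParams hill_saturation
#' @return Ca2+ concentration(s) in nM.
#' @export
hill_inverse <- function(theta, hill = hill_params()) {
  if (any(theta < 0) || any(theta >= 1)) {
    stop("theta must lie in [0, 1); theta = 1 means a saturated sensor", call. = FALSE)
  }
  hill$kd * (theta / (1 - theta))^(1 / hill$hill_n)
}

#' Relative sensor brightness at a given Ca2+ concentration
#'
#' Brightness per unit indicator, normalized so that zero Ca2+ gives 1:
#' `1 + (dyn_range - 1) * theta(ca)`.
#'
#' @inheritParams hill_saturation
#' @return Relative brightness (>= 1).
#' @keywords internal
hill_brightness <- function(ca, hill = hill_params()) {
  1 + (hill$dyn_range - 1) * hill_saturation(ca, hill)
}
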