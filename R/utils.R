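#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the session stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Row-wise quantile of a pixels-by-frames matrix
#'
#' Type-7 (linear interpolation) order statistic per row, using partial
#' sorting. Used by the baseline estimator where `apply(..., quantile)` is
#' too slow for full-frame stacks.
#' @noRd
row_quantile <- function(m, prob) {
  w <- ncol(m)
  h <- (w - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  g <- h - lo
  apply(m, 1L, function(r) {
    s <- sort.int(r, partial = unique(c(lo, hi)))
    if (lo == hi) s[lo] else (1 - g) * s[lo] + g * s[hi]
  })
}

#' Centered moving average with shrinking edge windows
#' @noRd
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 1) return(x)
  half <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(x[j])
  }, numeric(1))
}

#' Frobenius norm
#' @noRd
fnorm <- function(m) sqrt(sum(m^2))

#' Cosine similarity between two vectors
#' @noRd
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
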