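#' Tidy an NMF fit
#'
#' One row per (component, feature column) of H, joined with the feature /
#' threshold / bin annotation when available; with `matrix = "W"`, one row
#' per (recording, component) weight.
#'
#' @param x An `mted_nmf` object.
#' @param matrix `"H"` (components) or `"W"` (weights).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mted_nmf <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    ids <- x$recording_ids %||% as.character(seq_len(nrow(x$W)))
    out <- tibble::tibble(
      recording_id = rep(ids, x$k),
      component = rep(seq_len(x$k), each = nrow(x$W)),
      weight = as.vector(x$W)
    )
    if (!is.null(x$labels)) {
      out$condition <- rep(as.character(x$labels), x$k)
    }
    return(out)
  }
  out <- tibble::tibble(
    component = rep(seq_len(x$k), times = ncol(x$H)),
    column = rep(seq_len(ncol(x$H)), each = x$k),
    loading = as.vector(x$H)
  )
  if (!is.null(x$column_info)) {
    info <- dplyr::mutate(x$column_info, column = dplyr::row_number())
    out <- dplyr::left_join(out, info, by = "column")
  }
  out
}

#' Glance at an NMF fit
#'
#' @param x An `mted_nmf` object.
#' @param ... Unused.
#' @return One-row tibble with `k`, `reconstruction_error`,
#'   `relative_error`, `iterations`, `restarts`, `seed`.
#' @export
glance.mted_nmf <- function(x, ...) {
  tibble::tibble(
    k = x$k, reconstruction_error = x$reconstruction_error,
    relative_error = x$relative_error, iterations = x$iterations,
    restarts = x$restarts, seed = x$seed
  )
}

#' Tidy an LDA projection
#'
#' @param x An `mted_lda` object.
#' @param ... Unused.
#' @return The per-recording discriminant coordinates as a tibble.
#' @export
tidy.mted_lda <- function(x, ...) {
  x$coordinates
}

#' Glance at an LDA projection
#'
#' @param x An `mted_lda` object.
#' @param ... Unused.
#' @return One-row tibble: class count, axis count, separation statistic.
#' @export
glance.mted_lda <- function(x, ...) {
  tibble::tibble(
    n_recordings = nrow(x$coordinates),
    n_classes = nlevels(x$labels),
    n_axes = sum(grepl("^LD", names(x$coordinates))),
    separation = lda_separation(x),
    shrinkage = x$shrinkage
  )
}
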