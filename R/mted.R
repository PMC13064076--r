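#' Default Ca2+ threshold ladder
#'
#' Strictly increasing dF/F_R levels at which events are segmented. The
#' default spans 0.5 to 20 and includes the levels most analyses single out
#' (2, 5, 10).
#'
#' @param levels Numeric vector of dF/F_R thresholds.
#' @return The validated ladder (numeric vector).
#' @export
threshold_ladder <- function(levels = c(0.5, 1, 2, 3, 4, 5, 7, 10, 15, 20)) {
  stopifnot(is.numeric(levels), length(levels) >= 1,
            all(diff(levels) > 0), levels[1] >= 0)
  levels
}

# Neighborhood offsets (dy, dx, dt) on the "positive" side of the voxel, so
# each unordered voxel pair is visited once.
conn_offsets <- function(connectivity) {
  all26 <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dt = -1:1))
  all26 <- all26[rowSums(abs(all26)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(all26)) == 1,
    "18" = rowSums(abs(all26)) <= 2,
    "26" = rep(TRUE, nrow(all26)),
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  )
  offs <- all26[keep, , drop = FALSE]
  # positive half: first nonzero of (dt, dx, dy) is positive
  pos <- offs[, 3] > 0 |
    (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs[pos, , drop = FALSE]
}

# Connected-component labeling of a voxel set given as sorted linear indices
# into an array of dimension `dims`. Adjacency edges are built per offset and
# the components come from igraph. Returns the per-voxel component id.
label_voxel_components <- function(idx, dims, connectivity = 26) {
  nv <- length(idx)
  if (nv == 0) return(integer(0))
  co <- arrayInd(idx, dims)
  ny <- dims[1]; nx <- dims[2]; nt <- dims[3]
  offs <- conn_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    y2 <- co[, 1] + offs[r, 1]
    x2 <- co[, 2] + offs[r, 2]
    t2 <- co[, 3] + offs[r, 3]
    ok <- y2 >= 1 & y2 <= ny & x2 >= 1 & x2 <= nx & t2 >= 1 & t2 <= nt
    if (!any(ok)) next
    nidx <- y2[ok] + (x2[ok] - 1) * ny + (t2[ok] - 1) * ny * nx
    hit <- match(nidx, idx)
    found <- !is.na(hit)
    if (any(found)) {
      from <- c(from, which(ok)[found])
      to <- c(to, hit[found])
    }
  }
  if (!length(from)) return(seq_len(nv))
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Feature extraction for one component. `co` holds (y, x, t) voxel rows, `w`
# the dF/F_R values, `dff_full` the full stack for the pre-onset baseline
# frame used by the slope at event onset.
component_features <- function(co, w, dff_full, pixel_size, frame_interval) {
  frames <- sort(unique(co[, 3]))
  first <- frames[1]; last <- frames[length(frames)]

  area <- tapply(rep(1L, nrow(co)), co[, 3], sum)
  max_size <- max(area) * pixel_size^2
  duration <- (last - first + 1) * frame_interval

  # intensity-weighted centroid per frame, distance vs the first frame
  sw <- tapply(w, co[, 3], sum)
  cy <- tapply(w * co[, 1], co[, 3], sum) / sw
  cx <- tapply(w * co[, 2], co[, 3], sum) / sw
  disp <- sqrt((cy - cy[1])^2 + (cx - cx[1])^2) * pixel_size
  distance <- max(disp)

  n_frames <- length(frames)
  if (n_frames < 2) {
    max_slope <- 0
    slope_defined <- FALSE
  } else {
    mean_dff <- as.numeric(sw / area)
    # onset slope: compare the first suprathreshold frame against the same
    # pixels one frame earlier, so the rise from baseline is part of the event
    if (first > 1) {
      fp <- co[co[, 3] == first, , drop = FALSE]
      pre <- mean(dff_full[cbind(fp[, 1], fp[, 2], first - 1L)])
      if (!is.na(pre)) mean_dff <- c(pre, mean_dff)
    }
    max_slope <- max(diff(mean_dff)) / frame_interval
    slope_defined <- TRUE
  }

  list(first_frame = first, last_frame = last, n_voxels = nrow(co),
       max_size_um2 = max_size, duration_s = duration,
       distance_um = distance, max_slope_per_s = max_slope,
       slope_defined = slope_defined)
}

#' Multi-threshold event detection (MTED)
#'
#' Segments Ca2+ events independently at every level of a dF/F_R threshold
#' ladder: the stack is binarized at `dff >= level`, spatiotemporal connected
#' components are labeled under the chosen neighborhood, small/short
#' components are discarded, and four features are extracted per event:
#'
#' * `max_size_um2` — peak instantaneous suprathreshold area;
#' * `duration_s` — frames spanned times the frame interval;
#' * `distance_um` — maximal displacement of the intensity-weighted event
#'   center from its position in the first event frame;
#' * `max_slope_per_s` — maximal frame-to-frame increase of the
#'   footprint-mean dF/F_R (the onset frame is compared against the same
#'   pixels one frame before the event, so the rise from baseline counts;
#'   single-frame events report 0 with `slope_defined = FALSE`).
#'
#' @param dff A [dff_movie()].
#' @param ladder Threshold ladder from [threshold_ladder()].
#' @param min_area Discard components never reaching this many pixels in any
#'   single frame.
#' @param min_frames Discard components spanning fewer frames.
#' @param connectivity 6, 18 or 26 (voxel neighborhood in x, y, t).
#' @param recording_id,condition,n_cells,duration_recorded_s Recording
#'   metadata carried into the table; `duration_recorded_s` defaults to the
#'   movie length. `n_cells` is supplied metadata (known in simulations,
#'   counted manually for real recordings).
#' @return A tibble of class `mted_events`, one row per event, with the
#'   ladder, connectivity and filters stored as attributes. Zero-event levels
#'   simply have no rows.
#' @export
detect_events <- function(dff, ladder = threshold_ladder(), min_area = 4,
                          min_frames = 2, connectivity = 26,
                          recording_id = "rec1", condition = NA_character_,
                          n_cells = 1, duration_recorded_s = NULL) {
  stopifnot(inherits(dff, "dff_movie"), n_cells >= 1)
  ladder <- threshold_ladder(ladder)
  d <- dim(dff$dff)
  if (is.null(duration_recorded_s)) {
    duration_recorded_s <- d[3] * dff$frame_interval
  }
  if (!any(dff$mask)) {
    warning("detect_events: empty analysis mask, returning no events",
            call. = FALSE)
  }

  rows <- list()
  for (level in ladder) {
    hot <- which(!is.na(dff$dff) & dff$dff >= level)
    if (!length(hot)) next
    membership <- label_voxel_components(hot, d, connectivity)
    co_all <- arrayInd(hot, d)
    w_all <- dff$dff[hot]
    eid <- 0L
    for (comp in split(seq_along(hot), membership)) {
      co <- co_all[comp, , drop = FALSE]
      frames_spanned <- max(co[, 3]) - min(co[, 3]) + 1L
      if (frames_spanned < min_frames) next
      if (max(tabulate(factor(co[, 3]))) < min_area) next
      feats <- component_features(co, w_all[comp], dff$dff,
                                  dff$pixel_size, dff$frame_interval)
      eid <- eid + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        recording_id = recording_id, condition = condition,
        n_cells = as.integer(n_cells),
        duration_recorded_s = duration_recorded_s,
        threshold = level, event_id = eid, !!!feats
      )
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    recording_id = character(), condition = character(), n_cells = integer(),
    duration_recorded_s = numeric(), threshold = numeric(), event_id = integer(),
    first_frame = integer(), last_frame = integer(), n_voxels = integer(),
    max_size_um2 = numeric(), duration_s = numeric(), distance_um = numeric(),
    max_slope_per_s = numeric(), slope_defined = logical()
  )
  attr(out, "ladder") <- ladder
  attr(out, "connectivity") <- connectivity
  attr(out, "min_area") <- min_area
  attr(out, "min_frames") <- min_frames
  class(out) <- c("mted_events", class(out))
  out
}

#' Per-threshold event counts and feature summaries
#'
#' Event frequency per cell (and per 600-second recording equivalent) at
#' every ladder level, plus quartile summaries of the four event features.
#' Levels without events appear with zero counts.
#'
#' @param table An `mted_events` tibble from [detect_events()].
#' @return A tibble with one row per threshold level.
#' @export
threshold_profile <- function(table) {
  stopifnot(inherits(table, "mted_events"))
  ladder <- attr(table, "ladder")
  n_cells <- if (nrow(table)) table$n_cells[1] else 1L
  dur <- if (nrow(table)) table$duration_recorded_s[1] else NA_real_
  qs <- function(x, p) if (length(x)) unname(stats::quantile(x, p)) else NA_real_
  purrr::map_dfr(ladder, function(level) {
    ev <- dplyr::filter(table, .data$threshold == level)
    n <- nrow(ev)
    tibble::tibble(
      threshold = level, n_events = n,
      events_per_cell = n / n_cells,
      events_per_cell_600s = if (is.na(dur)) NA_real_ else n / n_cells * 600 / dur,
      median_size_um2 = qs(ev$max_size_um2, 0.5),
      q25_size_um2 = qs(ev$max_size_um2, 0.25),
      q75_size_um2 = qs(ev$max_size_um2, 0.75),
      median_duration_s = qs(ev$duration_s, 0.5),
      median_distance_um = qs(ev$distance_um, 0.5),
      median_slope_per_s = qs(ev$max_slope_per_s, 0.5)
    )
  })
}
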