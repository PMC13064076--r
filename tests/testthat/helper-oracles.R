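# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately share no code with the
# package internals.

# Recursive-free flood fill over a logical 3D array: repeatedly grow a
# component from an unvisited TRUE voxel by scanning all its neighbors.
oracle_flood_fill <- function(mask3, connectivity = 26) {
  d <- dim(mask3)
  labels <- array(0L, d)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dt = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  nxt <- 0L
  todo <- which(mask3)
  for (start in todo) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        y <- co[1] + offs[r, 1]; x <- co[2] + offs[r, 2]; t <- co[3] + offs[r, 3]
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || t < 1 || t > d[3]) next
        if (!mask3[y, x, t] || labels[y, x, t] != 0L) next
        labels[y, x, t] <- nxt
        queue <- c(queue, y + (x - 1) * d[1] + (t - 1) * d[1] * d[2])
      }
    }
  }
  labels
}

# Canonical signature of a labeling: sorted list of sorted voxel-index sets,
# so two labelings can be compared up to label permutation.
labeling_signature <- function(labels_by_voxel, idx) {
  comps <- split(idx, labels_by_voxel)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, min, numeric(1)))])
}

# Naive per-pixel sliding-percentile baseline on a single trace: every
# window position, full quantile() call, then min of the smoothed envelope.
oracle_f0_trace <- function(trace, window, percentile, stride = NULL,
                            smooth = 3) {
  nt <- length(trace)
  if (is.null(stride)) stride <- max(1, floor(window / 2))
  starts <- seq(1, nt - window + 1, by = stride)
  if (starts[length(starts)] + window - 1 < nt) starts <- c(starts, nt - window + 1)
  env <- vapply(starts, function(s) {
    unname(quantile(trace[s:(s + window - 1)], percentile / 100, type = 7))
  }, numeric(1))
  if (length(env) > 1 && smooth > 1) {
    half <- floor(smooth / 2)
    env <- vapply(seq_along(env), function(i) {
      mean(env[max(1, i - half):min(length(env), i + half)])
    }, numeric(1))
  }
  min(env)
}

# Brute-force intensity-weighted centroid track of a voxel component.
oracle_max_displacement <- function(co, w, pixel_size) {
  frames <- sort(unique(co[, 3]))
  cent <- t(vapply(frames, function(f) {
    i <- co[, 3] == f
    c(sum(co[i, 1] * w[i]) / sum(w[i]), sum(co[i, 2] * w[i]) / sum(w[i]))
  }, numeric(2)))
  max(sqrt((cent[, 1] - cent[1, 1])^2 + (cent[, 2] - cent[1, 2])^2)) * pixel_size
}

# Brute-force per-event features computed directly from a planted
# concentration movie (not from the plant parameters): suprathreshold-free,
# it uses the known footprints and the rendered concentrations.
oracle_features_from_ca <- function(ca, event, basal_ca, pixel_size,
                                    frame_interval, hill) {
  frames <- event$onset_frame:event$offset_frame
  areas <- vapply(event$footprints, nrow, integer(1))
  dffs <- vapply(seq_along(frames), function(k) {
    fp <- event$footprints[[k]]
    vals <- ca[cbind(fp[, 1], fp[, 2], frames[k])]
    mean((hill$dyn_range - 1) * hill_saturation(vals, hill))
  }, numeric(1))
  dff_basal <- (hill$dyn_range - 1) * hill_saturation(basal_ca, hill)
  cents <- t(vapply(event$footprints, colMeans, numeric(2))) * pixel_size
  list(
    max_size_um2 = max(areas) * pixel_size^2,
    duration_s = length(frames) * frame_interval,
    distance_um = max(sqrt((cents[, 1] - cents[1, 1])^2 +
                             (cents[, 2] - cents[1, 2])^2)),
    max_slope_per_s = max(diff(c(dff_basal, dffs))) / frame_interval
  )
}

# Small deterministic dff_movie built directly from a value array.
make_dff <- function(arr, pixel_size = 1, frame_interval = 0.2) {
  dff_movie(arr, mask = matrix(TRUE, dim(arr)[1], dim(arr)[2]),
            pixel_size = pixel_size, frame_interval = frame_interval)
}

# Event table stub for the statistics module: n events of given feature
# values at one threshold, carrying recording metadata.
stub_events <- function(sizes, threshold = 2, n_cells = 1, duration = 600,
                        recording_id = "r1", condition = "Ctrl",
                        ladder = threshold_ladder()) {
  n <- length(sizes)
  tb <- tibble::tibble(
    recording_id = recording_id, condition = condition,
    n_cells = as.integer(n_cells), duration_recorded_s = duration,
    threshold = threshold, event_id = seq_len(n),
    first_frame = 1L, last_frame = 10L, n_voxels = 100L,
    max_size_um2 = sizes, duration_s = 2, distance_um = 1,
    max_slope_per_s = 1, slope_defined = TRUE
  )
  attr(tb, "ladder") <- ladder
  class(tb) <- c("mted_events", class(tb))
  tb
}
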