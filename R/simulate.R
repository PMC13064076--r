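#' Specify a planted Ca2+ event
#'
#' A planted event is a per-frame set of pixels (the footprint trajectory)
#' inside one cell, together with its Ca2+ kinetics: a linear rise at
#' `rise_rate` from the resting concentration to `peak_ca`, followed by an
#' exponential decay (time constant `tau`) back toward rest. The event is
#' truncated at `offset_frame`; afterwards the concentration is exactly the
#' resting level again.
#'
#' @param cell_id Integer label of the carrying cell.
#' @param onset_frame,offset_frame First and last frame (1-based, inclusive).
#' @param footprints Either one two-column matrix `(row, col)` of pixels
#'   (static footprint) or a list of such matrices, one per frame in
#'   `[onset_frame, offset_frame]`.
#' @param peak_ca Peak Ca2+ concentration in nM (> resting level).
#' @param rise_rate Rise speed in nM/s (> 0).
#'
#' @return A `planted_event` object.
#' @export
planted_event <- function(cell_id, onset_frame, offset_frame, footprints,
                          peak_ca, rise_rate) {
  stopifnot(onset_frame >= 1, onset_frame <= offset_frame,
            peak_ca > 0, rise_rate > 0)
  n_frames <- offset_frame - onset_frame + 1
  if (is.matrix(footprints)) {
    footprints <- rep(list(footprints), n_frames)
  }
  stopifnot(length(footprints) == n_frames,
            all(vapply(footprints, nrow, integer(1)) > 0))
  structure(
    list(cell_id = as.integer(cell_id), onset_frame = as.integer(onset_frame),
         offset_frame = as.integer(offset_frame), footprints = footprints,
         peak_ca = peak_ca, rise_rate = rise_rate),
    class = "planted_event"
  )
}

#' Square pixel footprint centered at (row, col)
#'
#' @param center Length-2 numeric `(row, col)`.
#' @param half_width Half edge length in pixels; the footprint is the
#'   `(2 * half_width + 1)^2` square.
#' @return Two-column integer matrix of pixel coordinates.
#' @export
square_footprint <- function(center, half_width) {
  r <- seq(round(center[1]) - half_width, round(center[1]) + half_width)
  c <- seq(round(center[2]) - half_width, round(center[2]) + half_width)
  as.matrix(expand.grid(row = r, col = c))
}

# Ca2+ concentration of one event at the frame times since onset (seconds).
# Linear rise to peak at rise_rate, then exponential decay toward basal.
event_ca_trace <- function(event, basal_ca, frame_interval, tau) {
  n <- event$offset_frame - event$onset_frame + 1
  # the first event frame already carries one frame-interval of rise so a
  # one-frame event is visibly above rest
  ts <- seq_len(n) * frame_interval
  rise_time <- (event$peak_ca - basal_ca) / event$rise_rate
  ca <- ifelse(
    ts <= rise_time,
    basal_ca + event$rise_rate * ts,
    basal_ca + (event$peak_ca - basal_ca) * exp(-(ts - rise_time) / tau)
  )
  pmin(ca, event$peak_ca)
}

#' Simulate a Ca2+ concentration movie with planted events
#'
#' Renders a per-pixel, per-frame free-Ca2+ concentration field: `basal_ca`
#' everywhere except inside planted-event footprints, where the event
#' kinetics apply (overlaps resolve to the pixelwise maximum). Alongside the
#' movie it returns the ground truth: the planted events plus their four
#' analytically computed features (max size, duration, maximal center
#' displacement, maximal dF/F_R slope) evaluated through the same Hill model
#' the renderer uses, so detection output can be compared against it.
#'
#' @param geometry A [make_cell_geometry()] map; every footprint pixel must
#'   carry its event's cell label.
#' @param event_specs List of [planted_event()] objects (may be empty).
#' @param basal_ca Resting Ca2+ in nM.
#' @param n_frames,frame_interval Temporal extent and calibration.
#' @param tau Decay time constant in seconds.
#' @param hill Hill bundle used for the analytic dF/F_R feature values.
#'
#' @return List with `ca` (3D array, nM), `ground_truth` (tibble, one row per
#'   event) and the simulation parameters.
#' @export
simulate_calcium <- function(geometry, event_specs, basal_ca = 50,
                             n_frames = 600, frame_interval = 0.2,
                             tau = 1.5, hill = hill_params(dyn_range = 6)) {
  stopifnot(inherits(geometry, "volume_map"), n_frames >= 1, frame_interval > 0)
  ny <- nrow(geometry$vf); nx <- ncol(geometry$vf)
  ca <- array(basal_ca, dim = c(ny, nx, n_frames))

  for (ev in event_specs) {
    stopifnot(inherits(ev, "planted_event"))
    if (ev$offset_frame > n_frames) {
      stop("event extends past the last frame", call. = FALSE)
    }
    trace <- event_ca_trace(ev, basal_ca, frame_interval, tau)
    for (k in seq_along(ev$footprints)) {
      fp <- ev$footprints[[k]]
      lab <- geometry$cell_labels[cbind(fp[, 1], fp[, 2])]
      if (any(lab != ev$cell_id)) {
        stop("event footprint leaves cell ", ev$cell_id, call. = FALSE)
      }
      f <- ev$onset_frame + k - 1L
      idx <- cbind(fp[, 1], fp[, 2], f)
      ca[idx] <- pmax(ca[idx], trace[k])
    }
  }

  gt <- ground_truth_features(event_specs, basal_ca, frame_interval, tau,
                              geometry$pixel_size, hill)
  list(ca = ca, ground_truth = gt, basal_ca = basal_ca,
       frame_interval = frame_interval, tau = tau, hill = hill)
}

# Analytic ground-truth features for each planted event, derived from the
# plant parameters through the Hill model (not from the rendered movie).
ground_truth_features <- function(event_specs, basal_ca, frame_interval, tau,
                                  pixel_size, hill) {
  if (!length(event_specs)) {
    return(tibble::tibble(
      event_id = integer(), cell_id = integer(), onset_frame = integer(),
      offset_frame = integer(), peak_ca = numeric(), max_size_um2 = numeric(),
      duration_s = numeric(), distance_um = numeric(), max_slope_per_s = numeric()
    ))
  }
  rows <- purrr::imap(event_specs, function(ev, i) {
    areas <- vapply(ev$footprints, nrow, integer(1))
    centers <- t(vapply(ev$footprints, colMeans, numeric(2))) * pixel_size
    disp <- sqrt(rowSums((centers - matrix(centers[1, ], nrow(centers), 2,
                                           byrow = TRUE))^2))
    trace <- event_ca_trace(ev, basal_ca, frame_interval, tau)
    # footprint-mean dF/F_R is spatially uniform within a planted footprint
    dff <- (hill$dyn_range - 1) * hill_saturation(trace, hill)
    dff_basal <- (hill$dyn_range - 1) * hill_saturation(basal_ca, hill)
    slopes <- diff(c(dff_basal, dff)) / frame_interval
    tibble::tibble(
      event_id = i, cell_id = ev$cell_id, onset_frame = ev$onset_frame,
      offset_frame = ev$offset_frame, peak_ca = ev$peak_ca,
      max_size_um2 = max(areas) * pixel_size^2,
      duration_s = (ev$offset_frame - ev$onset_frame + 1) * frame_interval,
      distance_um = max(disp),
      max_slope_per_s = max(slopes)
    )
  })
  dplyr::bind_rows(rows)
}

#' Render a concentration movie into two fluorescence channels
#'
#' The ratiometric sensor couples GCaMP6s and tdTomato 1:1, so both channels
#' scale with local expression, which in turn is proportional to the occupied
#' volume fraction. The red channel is Ca2+-independent:
#' `red = gain * vf * red_coeff`; the green channel carries the Hill-model
#' brightness: `green = gain * vf * (1 + (dyn_range - 1) * theta(ca))`.
#' Channels are then mixed by the 2x2 crosstalk matrix and optionally
#' degraded with Poisson shot noise (on photon-scaled intensities) and
#' Gaussian read noise. Without noise the render is deterministic.
#'
#' @param ca_movie 3D concentration array in nM.
#' @param geometry Matching [make_cell_geometry()] map.
#' @param hill [hill_params()] bundle.
#' @param expression_gain Overall brightness scale (a.u.).
#' @param red_coeff tdTomato brightness per unit expression relative to the
#'   zero-Ca2+ GCaMP6s brightness.
#' @param crosstalk 2x2 mixing matrix (row = detected channel, column =
#'   true fluorophore), applied as `detected = crosstalk %*% pure`.
#' @param noise `NULL` for a noiseless render, or a list with
#'   `photon_scale` (photons per intensity unit, Poisson shot noise) and/or
#'   `read_sigma` (a.u., Gaussian).
#' @param frame_interval Seconds per frame, stored in the result.
#' @param seed Seed for the noise draws.
#'
#' @return A [two_channel_movie()].
#' @export
render_fluorescence <- function(ca_movie, geometry, hill = hill_params(dyn_range = 6),
                                expression_gain = 100, red_coeff = 1,
                                crosstalk = diag(2), noise = NULL,
                                frame_interval = 0.2, seed = 1) {
  stopifnot(identical(dim(ca_movie)[1:2], dim(geometry$vf)))
  crosstalk <- as.matrix(crosstalk)
  if (!identical(dim(crosstalk), c(2L, 2L)) ||
      abs(det(crosstalk)) < 1e-12 * max(abs(crosstalk))^2) {
    stop("crosstalk matrix must be an invertible 2x2 matrix", call. = FALSE)
  }

  nt <- dim(ca_movie)[3]
  vf_rep <- array(geometry$vf, dim = dim(ca_movie))
  green <- expression_gain * vf_rep * (1 + (hill$dyn_range - 1) *
                                         hill_saturation(ca_movie, hill))
  red <- expression_gain * vf_rep * red_coeff

  mixed_g <- crosstalk[1, 1] * green + crosstalk[1, 2] * red
  mixed_r <- crosstalk[2, 1] * green + crosstalk[2, 2] * red

  if (!is.null(noise)) {
    with_seed(seed, {
      if (!is.null(noise$photon_scale)) {
        ps <- noise$photon_scale
        mixed_g[] <- stats::rpois(length(mixed_g), mixed_g * ps) / ps
        mixed_r[] <- stats::rpois(length(mixed_r), mixed_r * ps) / ps
      }
      if (!is.null(noise$read_sigma)) {
        mixed_g <- mixed_g + stats::rnorm(length(mixed_g), 0, noise$read_sigma)
        mixed_r <- mixed_r + stats::rnorm(length(mixed_r), 0, noise$read_sigma)
      }
    })
    mixed_g <- pmax(mixed_g, 0)
    mixed_r <- pmax(mixed_r, 0)
  }

  two_channel_movie(mixed_g, mixed_r, pixel_size = geometry$pixel_size,
                    frame_interval = frame_interval)
}

#' Plant a set of well-separated square events inside cell somata
#'
#' Convenience generator for validation recordings: events are static (or
#' linearly drifting) squares inside soma discs, with onsets spread through
#' the recording so that distinct events never touch in space-time.
#'
#' @param geometry A [make_cell_geometry()] map.
#' @param n_events Number of events to plant.
#' @param n_frames Total recording length in frames.
#' @param seed Integer seed.
#' @param half_width Square half width in pixels.
#' @param duration_frames Event duration in frames (recycled).
#' @param peak_ca Peak concentrations in nM (recycled).
#' @param drift Per-frame (row, col) center shift in pixels; `c(0, 0)` for
#'   stationary events.
#' @return List of [planted_event()] objects.
#' @export
plant_events <- function(geometry, n_events, n_frames, seed = 1,
                         half_width = 4, duration_frames = 15,
                         peak_ca = 1000, drift = c(0, 0)) {
  stopifnot(n_events >= 1)
  duration_frames <- rep_len(duration_frames, n_events)
  peak_ca <- rep_len(peak_ca, n_events)
  gap <- 10L
  need <- sum(duration_frames) + gap * (n_events + 1L)
  if (need > n_frames) {
    stop("recording too short for ", n_events, " separated events", call. = FALSE)
  }
  with_seed(seed, {
    cells <- sample(rep_len(seq_len(geometry$n_cells), n_events))
    onset <- gap + 1L
    lapply(seq_len(n_events), function(i) {
      ctr <- geometry$soma_centers[cells[i], ]
      nfr <- duration_frames[i]
      fps <- lapply(seq_len(nfr), function(k) {
        square_footprint(ctr + (k - 1) * drift, half_width)
      })
      ev <- planted_event(
        cell_id = cells[i], onset_frame = onset,
        offset_frame = onset + nfr - 1L, footprints = fps,
        peak_ca = peak_ca[i], rise_rate = peak_ca[i] / 0.4
      )
      onset <<- onset + nfr + gap
      ev
    })
  })
}

#' One-call synthetic recording with full ground truth
#'
#' Chains geometry, event planting, concentration simulation and rendering
#' into a single validation recording. All stages share the seed, so the
#' result is bit-identical for identical arguments.
#'
#' @inheritParams make_cell_geometry
#' @inheritParams plant_events
#' @param n_frames,frame_interval Temporal extent (default 600 frames at
#'   5 frames/s, i.e. a 2-minute desk-scale recording).
#' @param basal_ca Resting Ca2+ in nM.
#' @param hill Hill bundle; the default dynamic range of 6 keeps the resting
#'   dF/F_R (0.35) below the lowest detection threshold of 0.5, as it must be
#'   for threshold-ladder event detection to be meaningful.
#' @param crosstalk,noise,expression_gain,red_coeff Passed to
#'   [render_fluorescence()].
#' @return List: `movie`, `geometry`, `ca`, `ground_truth`, `hill`,
#'   `basal_ca`, plus render gains.
#' @export
simulate_recording <- function(n_cells = 2, fov = 128, pixel_size = 1,
                               n_frames = 600, frame_interval = 0.2,
                               n_events = 10, seed = 1, basal_ca = 50,
                               hill = hill_params(dyn_range = 6),
                               peak_ca = 1000, half_width = 4,
                               duration_frames = 15, drift = c(0, 0),
                               expression_gain = 100, red_coeff = 1,
                               crosstalk = diag(2), noise = NULL) {
  geometry <- make_cell_geometry(n_cells, fov, pixel_size, seed = seed)
  events <- if (n_events > 0) {
    plant_events(geometry, n_events, n_frames, seed = seed + 1L,
                 half_width = half_width, duration_frames = duration_frames,
                 peak_ca = peak_ca, drift = drift)
  } else list()
  sim <- simulate_calcium(geometry, events, basal_ca = basal_ca,
                          n_frames = n_frames, frame_interval = frame_interval,
                          hill = hill)
  movie <- render_fluorescence(sim$ca, geometry, hill = hill,
                               expression_gain = expression_gain,
                               red_coeff = red_coeff, crosstalk = crosstalk,
                               noise = noise, frame_interval = frame_interval,
                               seed = seed + 2L)
  list(movie = movie, geometry = geometry, ca = sim$ca,
       ground_truth = sim$ground_truth, events = events, hill = hill,
       basal_ca = basal_ca, expression_gain = expression_gain,
       red_coeff = red_coeff)
}
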