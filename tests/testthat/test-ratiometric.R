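test_that("identity unmixing returns the input; singular matrices error", {
  sim <- simulate_recording(n_cells = 1, fov = 32, n_frames = 60, n_events = 1,
                            seed = 5, duration_frames = 10)
  out <- unmix(sim$movie, diag(2))
  expect_equal(out$green, sim$movie$green)
  expect_equal(out$red, sim$movie$red)
  expect_error(unmix(sim$movie, matrix(1, 2, 2)), "singular")
})

test_that("unmixing inverts the render crosstalk to machine precision", {
  M <- rbind(c(1, 0.2), c(0.1, 1))
  pure <- simulate_recording(n_cells = 1, fov = 48, n_frames = 80, n_events = 2,
                             seed = 6, duration_frames = 10)
  mixed <- simulate_recording(n_cells = 1, fov = 48, n_frames = 80, n_events = 2,
                              seed = 6, crosstalk = M, duration_frames = 10)
  rec <- unmix(mixed$movie, M)
  rel <- max(abs(rec$green - pure$movie$green)) / max(pure$movie$green)
  expect_lt(rel, 1e-6)
  rel_r <- max(abs(rec$red - pure$movie$red)) / max(pure$movie$red)
  expect_lt(rel_r, 1e-6)
})

test_that("baseline estimator matches a naive percentile filter", {
  # constant trace returns the constant
  const <- array(100, dim = c(2, 2, 120))
  expect_true(all(estimate_f0(const, window = 50, percentile = 10)$f0 == 100))

  # step trace: 100 for frames 1-100, then 300; low percentile keeps 100
  trace <- c(rep(100, 100), rep(300, 100))
  arr <- array(rep(trace, each = 1), dim = c(1, 1, 200))
  f0 <- estimate_f0(arr, window = 50, percentile = 10)
  expect_equal(as.numeric(f0$f0), 100)
  expect_equal(as.numeric(f0$f0),
               oracle_f0_trace(trace, window = 50, percentile = 10))

  # a noisy trace with transients: package result equals the trace oracle
  set.seed(42)
  tr2 <- 50 + 5 * sin(seq(0, 6 * pi, length.out = 300)) + rnorm(300)
  tr2[100:110] <- tr2[100:110] + 200
  arr2 <- array(tr2, dim = c(1, 1, 300))
  expect_equal(as.numeric(estimate_f0(arr2, window = 100, percentile = 8)$f0),
               oracle_f0_trace(tr2, window = 100, percentile = 8))

  expect_error(estimate_f0(const, window = 500), "window")
})

test_that("green baseline of a noiseless simulation equals the analytic resting brightness", {
  sim <- simulate_recording(n_cells = 1, fov = 64, n_frames = 300, n_events = 2,
                            seed = 8)
  f0g <- estimate_f0(sim$movie$green)
  cells <- sim$geometry$cell_labels > 0
  analytic <- sim$expression_gain * sim$geometry$vf *
    (1 + (sim$hill$dyn_range - 1) * hill_saturation(sim$basal_ca, sim$hill))
  rel <- abs(f0g$f0[cells] - analytic[cells]) / analytic[cells]
  expect_lt(max(rel), 0.01)
})

test_that("scale factor recovers the closed-form render constant", {
  hill <- hill_params(dyn_range = 6)
  sim <- simulate_recording(n_cells = 2, fov = 64, n_frames = 200, n_events = 2,
                            seed = 9, hill = hill, red_coeff = 2)
  f0g <- estimate_f0(sim$movie$green)
  f0r <- estimate_f0(sim$movie$red)
  mask <- sim$geometry$cell_labels > 0
  k <- compute_scale_factor(f0g, f0r, hill, mask)
  # green/red baseline ratio is B(basal)/red_coeff; dividing by B(basal)
  # leaves 1/red_coeff
  expect_equal(k, 1 / 2, tolerance = 1e-6)

  # Ca2+-insensitive limit: dyn_range -> 1 divisor -> 1 (use basal_ca = 0)
  hill0 <- hill_params(dyn_range = 6, basal_ca = 0)
  k0 <- compute_scale_factor(f0g, f0r, hill0, mask)
  expect_equal(k0, median(f0g$f0[mask] / f0r$f0[mask]), tolerance = 1e-12)

  expect_error(compute_scale_factor(f0g, f0r, hill, mask & FALSE), "empty")
})

test_that("dF/F_R arithmetic and masking behave as defined", {
  f0r <- structure(list(f0 = matrix(2, 4, 4), window = 1, percentile = 8),
                   class = "baseline_map")
  ref <- reference_map(f0r, scale_k = 1)
  g <- array(2, dim = c(4, 4, 3))
  d0 <- compute_dff(g, ref)
  expect_true(all(d0$dff == 0))

  g[1, 1, 2] <- 6 # F = 3 fr at one pixel
  d1 <- compute_dff(g, ref)
  expect_equal(d1$dff[1, 1, 2], 2)

  # pixels with unusable reference are dropped from a supplied mask
  f0r$f0[2, 2] <- 0
  ref2 <- reference_map(f0r, scale_k = 1)
  expect_warning(
    d2 <- compute_dff(g, ref2, mask = matrix(TRUE, 4, 4)),
    "unusable"
  )
  expect_true(all(is.na(d2$dff[2, 2, ])))
})

test_that("noiseless peak dF/F_R matches the closed form through the render equations", {
  hill <- hill_params(dyn_range = 6)
  sim <- simulate_recording(n_cells = 1, fov = 64, n_frames = 200, n_events = 2,
                            seed = 10, peak_ca = 800, hill = hill)
  norm <- normalize_movie(sim$movie, hill = hill,
                          cell_mask = sim$geometry$cell_labels > 0)
  analytic_peak <- (hill$dyn_range - 1) * hill_saturation(800, hill)
  measured_peak <- max(norm$dff$dff, na.rm = TRUE)
  expect_equal(measured_peak, analytic_peak, tolerance = 0.01)
})

test_that("full round trip reproduces the analytic dF/F_R field within 1%", {
  hill <- hill_params(dyn_range = 6)
  M <- rbind(c(1, 0.15), c(0.05, 1))
  sim <- simulate_recording(n_cells = 2, fov = 64, n_frames = 300, n_events = 3,
                            seed = 12, hill = hill, crosstalk = M)
  norm <- normalize_movie(sim$movie, hill = hill, mixing = M,
                          cell_mask = sim$geometry$cell_labels > 0)
  analytic <- (hill$dyn_range - 1) * hill_saturation(sim$ca, hill)
  cells <- sim$geometry$cell_labels > 0
  at_peaks <- analytic > 1
  err <- abs(norm$dff$dff[at_peaks] - analytic[at_peaks]) / analytic[at_peaks]
  expect_lt(max(err, na.rm = TRUE), 0.01)
})

test_that("dF/F_R is strictly increasing in the underlying concentration", {
  hill <- hill_params(dyn_range = 6)
  g <- make_cell_geometry(1, 32, seed = 2)
  cas <- c(10, 50, 100, 200, 400, 800)
  ref_movie <- render_fluorescence(array(0, c(32, 32, 1)), g, hill)
  px <- which(g$cell_labels > 0)[1]
  vals <- vapply(cas, function(ca) {
    mv <- render_fluorescence(array(ca, c(32, 32, 1)), g, hill)
    (mv$green[, , 1][px] - ref_movie$green[, , 1][px]) / ref_movie$green[, , 1][px]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("red baseline ranks like the true volume map", {
  sim <- simulate_recording(n_cells = 2, fov = 96, n_frames = 150, n_events = 2,
                            seed = 13)
  f0r <- estimate_f0(sim$movie$red)
  cells <- sim$geometry$cell_labels > 0
  rho <- cor(f0r$f0[cells], sim$geometry$vf[cells], method = "spearman")
  expect_gte(rho, 0.99)
})
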