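# Per-recording histogram stubs with controllable bin mass, for matrix tests.
hist_stub <- function(mass_at, total_bins = 4, seed = NULL) {
  ladder <- c(2, 5)
  feats <- c("max_size_um2", "duration_s", "distance_um", "max_slope_per_s")
  grid <- expand.grid(bin = seq_len(total_bins), threshold = ladder,
                      feature = feats, stringsAsFactors = FALSE)
  grid <- grid[, c("feature", "threshold", "bin")]
  grid <- grid[order(grid$feature, grid$threshold, grid$bin), ]
  h <- tibble::as_tibble(grid)
  h$bin_lo <- h$bin; h$bin_hi <- h$bin + 1; h$bin_mid <- h$bin + 0.5
  h$freq <- mass_at
  attr(h, "ladder") <- ladder
  class(h) <- c("feature_histogram", class(h))
  h
}

test_that("feature matrix has the block structure and pruning contract", {
  nb <- 4; nl <- 2; nf <- 4
  set.seed(1)
  hists <- lapply(1:6, function(i) hist_stub(runif(nb * nl * nf)))
  names(hists) <- paste0("rec", 1:6)
  fm <- build_feature_matrix(hists, normalization = "none")
  expect_equal(dim(fm$X), c(6L, nb * nl * nf))

  # an all-zero recording row is retained and flagged
  hists$rec7 <- hist_stub(rep(0, nb * nl * nf))
  expect_message(fm0 <- build_feature_matrix(hists, normalization = "none"),
                 "all-zero rows")
  expect_equal(fm0$zero_rows, "rec7")
  expect_equal(nrow(fm0$X), 7L)

  # block-max normalization: each feature block tops out at 1
  fmb <- build_feature_matrix(hists[1:6], normalization = "block_max")
  for (feat in unique(fmb$column_info$feature)) {
    expect_equal(max(fmb$X[, fmb$column_info$feature == feat]), 1)
  }

  # inconsistent binning errors
  bad <- hist_stub(runif(2 * nl * nf), total_bins = 2)
  expect_error(build_feature_matrix(c(hists[1:2], list(bad = bad))),
               "inconsistent")
})

test_that("exact low-rank matrices factorize to numerically zero error", {
  set.seed(11)
  W0 <- matrix(rexp(12 * 3), 12, 3)
  H0 <- matrix(rexp(3 * 40), 3, 40)
  X <- W0 %*% H0
  fit <- run_nmf(X, k = 3, seed = 1, restarts = 10)
  expect_lte(fit$relative_error, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))

  # rank-1 case
  X1 <- outer(rexp(8), rexp(20))
  f1 <- run_nmf(X1, k = 1, seed = 1, restarts = 3)
  expect_lt(f1$relative_error, 1e-8)
})

test_that("NMF is deterministic for a fixed seed and validates k", {
  set.seed(2)
  X <- matrix(rexp(10 * 30), 10, 30)
  a <- run_nmf(X, k = 3, seed = 5)
  b <- run_nmf(X, k = 3, seed = 5)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  expect_error(run_nmf(X, k = 11), "k must lie")
  expect_error(run_nmf(-X, k = 2), "non-negative")
})

test_that("reconstruction error is non-increasing in the component count", {
  set.seed(21)
  X <- matrix(rexp(12 * 50), 12, 50) + matrix(rexp(12), 12) %*% t(rep(1, 50))
  sweep <- nmf_k_sweep(X, ks = 2:10, seed = 3, restarts = 10)
  expect_true(all(diff(sweep$reconstruction_error) <= 1e-6))
})

test_that("planted three-component mixtures are recovered up to permutation/scale", {
  set.seed(31)
  p <- 60
  # three distinct nonnegative activity profiles
  H0 <- rbind(
    dgamma(seq(0, 6, length.out = p), shape = 2, rate = 2),
    dgamma(seq(0, 6, length.out = p), shape = 6, rate = 2),
    c(rep(0, p / 2), dgamma(seq(0, 3, length.out = p / 2), shape = 3, rate = 1))
  )
  W0 <- matrix(rexp(30 * 3), 30, 3)
  X <- W0 %*% H0
  fit <- run_nmf(X, k = 3, seed = 7, restarts = 10)
  m <- match_components(fit$H, H0)
  expect_true(all(m$cosine >= 0.95))
  expect_setequal(m$fitted, 1:3)
})

test_that("condition means of the weights reflect planted contrasts", {
  set.seed(41)
  H0 <- matrix(rexp(3 * 30), 3, 30)
  labels <- rep(c("Ctrl", "3h", "24h"), each = 6)
  W0 <- matrix(rexp(18 * 3, rate = 2), 18, 3)
  W0[labels == "3h", 2] <- W0[labels == "3h", 2] + 3 # extra mass on comp 2
  fit <- structure(list(W = W0, H = H0, k = 3, labels = labels,
                        recording_ids = paste0("r", 1:18)),
                   class = "mted_nmf")
  mw <- mean_component_weights(fit)
  top <- dplyr::slice_max(dplyr::filter(mw, component == 2), mean_weight)
  expect_equal(top$condition, "3h")

  # constructed 2x ratio
  labs2 <- rep(c("A", "B"), each = 4)
  W2 <- matrix(1, 8, 2)
  W2[labs2 == "B", 1] <- 2
  fit2 <- structure(list(W = W2, H = matrix(1, 2, 5), k = 2, labels = labs2,
                         recording_ids = paste0("r", 1:8)),
                    class = "mted_nmf")
  mw2 <- mean_component_weights(fit2)
  c1 <- dplyr::filter(mw2, component == 1)
  expect_equal(c1$mean_weight[c1$condition == "B"] /
                 c1$mean_weight[c1$condition == "A"], 2)
})

test_that("LDA separates separable groups and collapses under permutation", {
  set.seed(51)
  p <- 40
  centers <- matrix(rnorm(3 * p, sd = 6), 3, p)
  X <- do.call(rbind, lapply(1:3, function(g) {
    matrix(rnorm(10 * p, mean = rep(centers[g, ], each = 10), sd = 0.5), 10, p)
  }))
  labels <- rep(c("Ctrl", "3h LPS", "24h LPS"), each = 10)
  fit <- run_lda(X, labels)
  expect_gt(lda_separation(fit), 5)

  shuffled <- sample(labels)
  fit_perm <- run_lda(X, shuffled)
  expect_lt(lda_separation(fit_perm), lda_separation(fit) / 5)
})

test_that("LDA agrees with the classical solver on a low-dimensional fixture", {
  skip_if_not_installed("MASS")
  set.seed(61)
  X <- rbind(
    matrix(rnorm(40, mean = 0), 20, 2),
    matrix(rnorm(40, mean = 4), 20, 2)
  )
  labels <- rep(c("a", "b"), each = 20)
  ours <- run_lda(X, labels, shrinkage = 0)
  mass <- MASS::lda(X, grouping = labels)
  proj_ours <- ours$coordinates$LD1
  proj_mass <- as.numeric(predict(mass)$x[, 1])
  # identical axis up to sign/scale
  expect_gt(abs(cor(proj_ours, proj_mass)), 0.999999)
})

test_that("LDA is invariant to a common affine feature rescaling", {
  set.seed(71)
  X <- rbind(matrix(rnorm(60, 0), 15, 4), matrix(rnorm(60, 3), 15, 4),
             matrix(rnorm(60, -3), 15, 4))
  labels <- rep(c("x", "y", "z"), each = 15)
  f1 <- run_lda(X, labels)
  f2 <- run_lda(7.3 * X + 11, labels)
  expect_equal(lda_separation(f1), lda_separation(f2), tolerance = 1e-6)
})

test_that("degenerate and underpopulated classes are handled explicitly", {
  set.seed(81)
  X <- matrix(rnorm(40), 10, 4)
  expect_error(run_lda(X, c(rep("a", 9), "b")), "fewer than 2")
  # two statistically identical classes: near-zero between-class scatter
  Xi <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200), 100, 2))
  li <- rep(c("a", "b"), each = 100)
  fit <- run_lda(Xi, li)
  expect_lt(lda_separation(fit), 1)
})

test_that("tidiers expose fits as tibbles", {
  set.seed(91)
  X <- matrix(rexp(8 * 12), 8, 12)
  rownames(X) <- paste0("r", 1:8)
  fit <- run_nmf(X, k = 2, seed = 1, restarts = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 12)
  tw <- tidy(fit, matrix = "W")
  expect_equal(nrow(tw), 8 * 2)
  gl <- glance(fit)
  expect_equal(gl$k, 2)

  labels <- rep(c("a", "b"), each = 4)
  lfit <- run_lda(X, labels)
  expect_s3_class(tidy(lfit), "tbl_df")
  expect_equal(glance(lfit)$n_classes, 2L)
})
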