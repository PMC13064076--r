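#' Recording-by-feature matrix from per-recording histograms
#'
#' Concatenates the four per-threshold feature histograms of each recording
#' into one long non-negative row, giving the matrix X (recordings x
#' features) that the factorization decomposes. Columns that are zero in
#' every recording are pruned (their positions are kept in the attributes);
#' all-zero rows are retained but flagged.
#'
#' @param hists Named list of [accumulate_histograms()] results, one per
#'   recording (names become recording ids). All must share bins and ladder.
#' @param labels Optional character/factor vector of condition labels,
#'   parallel to `hists`.
#' @param normalization `"none"` (raw per-cell frequencies) or `"block_max"`
#'   (divide each feature block by its column maximum so no feature dominates
#'   by magnitude; default).
#' @return A `feature_matrix`: list with `X` (matrix), `labels`,
#'   `column_info` (tibble: feature, threshold, bin per retained column),
#'   `zero_rows`, `normalization`.
#' @export
build_feature_matrix <- function(hists, labels = NULL,
                                 normalization = c("block_max", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(length(hists) >= 1)
  if (is.null(names(hists))) names(hists) <- paste0("rec", seq_along(hists))
  key0 <- hists[[1]][, c("feature", "threshold", "bin")]
  for (h in hists) {
    stopifnot(inherits(h, "feature_histogram"))
    if (!identical(h[, c("feature", "threshold", "bin")], key0)) {
      stop("recordings have inconsistent binning or ladder", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(hists, function(h) h$freq))
  rownames(X) <- names(hists)
  column_info <- tibble::as_tibble(key0)

  zero_rows <- rownames(X)[rowSums(X) == 0]
  if (length(zero_rows)) {
    message("build_feature_matrix: all-zero rows retained: ",
            paste(zero_rows, collapse = ", "))
  }
  keep <- colSums(X) > 0
  X <- X[, keep, drop = FALSE]
  column_info <- column_info[keep, ]

  if (normalization == "block_max") {
    for (feat in unique(column_info$feature)) {
      j <- column_info$feature == feat
      mx <- max(X[, j])
      if (mx > 0) X[, j] <- X[, j] / mx
    }
  }
  if (!is.null(labels)) stopifnot(length(labels) == nrow(X))
  structure(
    list(X = X, labels = labels, column_info = column_info,
         zero_rows = zero_rows, normalization = normalization),
    class = "feature_matrix"
  )
}

# Nonnegative double SVD initialization (deterministic).
nndsvd_init <- function(X, k) {
  s <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k)
  H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sigma <- n_up * n_vp
        if (sigma > 0) {
          W[, j] <- sqrt(s$d[j] * sigma) * up / n_up
          H[j, ] <- sqrt(s$d[j] * sigma) * vp / n_vp
        }
      } else {
        sigma <- n_un * n_vn
        if (sigma > 0) {
          W[, j] <- sqrt(s$d[j] * sigma) * un / n_un
          H[j, ] <- sqrt(s$d[j] * sigma) * vn / n_vn
        }
      }
    }
  }
  eps <- 1e-9 * mean(X)
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

# Hierarchical alternating least squares (columnwise coordinate descent on
# the Frobenius objective) until the relative improvement stalls. Converges
# to exact factorizations far faster than plain multiplicative updates.
nmf_fit_once <- function(X, W, H, max_iter = 5000, tol = 1e-10) {
  eps <- .Machine$double.eps
  k <- ncol(W)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    WtX <- crossprod(W, X)
    WtW <- crossprod(W)
    for (j in seq_len(k)) {
      denom <- WtW[j, j]
      if (denom < eps) denom <- eps
      H[j, ] <- pmax(0, H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / denom)
    }
    XHt <- X %*% t(H)
    HHt <- tcrossprod(H)
    for (j in seq_len(k)) {
      denom <- HHt[j, j]
      if (denom < eps) denom <- eps
      W[, j] <- pmax(0, W[, j] + (XHt[, j] - W %*% HHt[, j]) / denom)
    }
    if (it %% 10 == 0 || it == max_iter) {
      err <- fnorm(X - W %*% H)
      if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps)) {
        return(list(W = W, H = H, error = err, iterations = it))
      }
      err_prev <- err
    }
  }
  list(W = W, H = H, error = fnorm(X - W %*% H), iterations = max_iter)
}

#' Non-negative matrix factorization of the feature matrix
#'
#' Factorizes X (recordings x features) into non-negative weights W
#' (recordings x k) and components H (k x features) with X ~ WH, minimizing
#' the Frobenius reconstruction error by alternating nonnegative coordinate
#' descent. The first
#' fit starts from a deterministic nonnegative double-SVD initialization;
#' the remaining `restarts - 1` fits start from seeded random exponential
#' factors. The best fit (lowest error) is returned, so the result is
#' reproducible for a fixed seed.
#'
#' @param fm A [build_feature_matrix()] result, or a bare non-negative
#'   matrix.
#' @param k Number of components (>= 1, <= min(dim(X))).
#' @param seed Integer seed for the random restarts.
#' @param restarts Total number of fits (>= 1).
#' @param max_iter,tol Update-loop controls.
#' @return An object of class `mted_nmf`: `W`, `H`, `k`,
#'   `reconstruction_error` (Frobenius norm of X - WH), `relative_error`
#'   (scaled by the norm of X), `labels`, `column_info`, `seed`.
#' @export
run_nmf <- function(fm, k = 3, seed = 1, restarts = 10,
                    max_iter = 5000, tol = 1e-10) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  labels <- if (inherits(fm, "feature_matrix")) fm$labels else NULL
  column_info <- if (inherits(fm, "feature_matrix")) fm$column_info else NULL
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  if (k < 1 || k > min(dim(X))) {
    stop("k must lie in [1, min(rows, cols)] = [1, ", min(dim(X)), "]",
         call. = FALSE)
  }

  fits <- vector("list", restarts)
  fits[[1]] <- with(nndsvd_init(X, k),
                    nmf_fit_once(X, W, H, max_iter, tol))
  if (restarts > 1) {
    with_seed(seed, {
      scale0 <- sqrt(mean(X) / k)
      for (r in 2:restarts) {
        W0 <- matrix(stats::rexp(nrow(X) * k, 1 / scale0), nrow(X), k)
        H0 <- matrix(stats::rexp(k * ncol(X), 1 / scale0), k, ncol(X))
        fits[[r]] <- nmf_fit_once(X, W0, H0, max_iter, tol)
      }
    })
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "error"))]]
  structure(
    list(W = best$W, H = best$H, k = k,
         reconstruction_error = best$error,
         relative_error = best$error / fnorm(X),
         iterations = best$iterations, restarts = restarts, seed = seed,
         labels = labels, column_info = column_info,
         recording_ids = rownames(X)),
    class = "mted_nmf"
  )
}

#' @export
print.mted_nmf <- function(x, ...) {
  cat(sprintf(
    "<mted_nmf> k = %d | %d recordings x %d features | rel. error %.3g (best of %d)\n",
    x$k, nrow(x$W), ncol(x$H), x$relative_error, x$restarts
  ))
  invisible(x)
}

#' Reconstruction error across component counts
#'
#' Refits the factorization for each `k` (best of `restarts`) and reports
#' the Frobenius reconstruction error, which is non-increasing in `k` for a
#' successful sweep.
#'
#' @inheritParams run_nmf
#' @param ks Component counts to try.
#' @return Tibble: `k`, `reconstruction_error`, `relative_error`.
#' @export
nmf_k_sweep <- function(fm, ks = 2:10, seed = 1, restarts = 10, ...) {
  purrr::map_dfr(ks, function(k) {
    fit <- run_nmf(fm, k = k, seed = seed, restarts = restarts, ...)
    tibble::tibble(k = k, reconstruction_error = fit$reconstruction_error,
                   relative_error = fit$relative_error)
  })
}

#' Condition-wise mean component weights
#'
#' Mean and standard deviation of each component's weight across the
#' recordings of every condition.
#'
#' @param fit An `mted_nmf` object.
#' @param labels Condition labels per recording; defaults to those stored in
#'   the fit.
#' @return Tibble: `condition`, `component`, `mean_weight`, `sd_weight`,
#'   `n_recordings`.
#' @export
mean_component_weights <- function(fit, labels = fit$labels) {
  stopifnot(inherits(fit, "mted_nmf"))
  if (is.null(labels)) stop("no condition labels available", call. = FALSE)
  stopifnot(length(labels) == nrow(fit$W))
  if (is.factor(labels) && any(table(labels) == 0)) {
    warning("condition(s) without recordings omitted: ",
            paste(names(which(table(labels) == 0)), collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(
    condition = rep(as.character(labels), fit$k),
    component = rep(seq_len(fit$k), each = nrow(fit$W)),
    weight = as.vector(fit$W)
  ) |>
    dplyr::group_by(.data$condition, .data$component) |>
    dplyr::summarise(
      mean_weight = mean(.data$weight),
      sd_weight = stats::sd(.data$weight),
      n_recordings = dplyr::n(),
      .groups = "drop"
    )
}

#' Match fitted components to reference profiles
#'
#' NMF is identifiable only up to permutation and scale, so fitted rows of H
#' are assigned to reference profiles by maximizing total cosine similarity
#' over all permutations (exhaustive assignment; component counts here are
#' small).
#'
#' @param H_fit,H_ref Matrices with components in rows and equal column
#'   counts.
#' @return Tibble: `reference` (row of `H_ref`), `fitted` (matched row of
#'   `H_fit`), `cosine`.
#' @export
match_components <- function(H_fit, H_ref) {
  k <- nrow(H_ref)
  stopifnot(nrow(H_fit) == k, ncol(H_fit) == ncol(H_ref))
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_sim(H_ref[i, ], H_fit[j, ])
  }
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  tibble::tibble(reference = seq_len(k), fitted = best,
                 cosine = sim[cbind(seq_len(k), best)])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Shrinkage linear discriminant analysis of recording features
#'
#' Projects labeled recordings onto at most `n_classes - 1` discriminant
#' axes that maximize between-class relative to within-class scatter. The
#' concatenated histogram space is much wider than the number of recordings,
#' so the data are first reduced to their principal-component span and the
#' within-class covariance is regularized with a trace-scaled ridge
#' (`(1 - shrinkage) * Sw + shrinkage * mean(diag(Sw)) * I`), keeping the
#' problem well-posed for collinear features.
#'
#' @param fm A [build_feature_matrix()] result or a bare matrix.
#' @param labels Condition labels (>= 2 classes, each with >= 2 recordings);
#'   defaults to the labels stored in `fm`.
#' @param shrinkage Ridge weight in \[0, 1).
#' @return An object of class `mted_lda`: `coordinates` (tibble with
#'   `recording_id`, `condition`, `LD1`, ...), `centroids`, `scalings`
#'   (feature-space discriminant vectors), `svd_basis`, `labels`,
#'   `shrinkage`.
#' @export
run_lda <- function(fm, labels = NULL, shrinkage = 0.1) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (is.null(labels) && inherits(fm, "feature_matrix")) labels <- fm$labels
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  labels <- as.factor(labels)
  stopifnot(length(labels) == nrow(X))
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 recordings: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }

  n <- nrow(X); g <- nlevels(labels)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  # reduce to the principal-component span of the centered data
  sv <- svd(Xc)
  q <- sum(sv$d > max(sv$d) * 1e-8)
  q <- max(q, 1)
  basis <- sv$v[, seq_len(q), drop = FALSE]
  Z <- Xc %*% basis

  means <- rowsum(Z, labels) / as.vector(counts)
  Sw <- matrix(0, q, q)
  for (lv in levels(labels)) {
    Zi <- Z[labels == lv, , drop = FALSE]
    Zi <- sweep(Zi, 2, means[lv, ])
    Sw <- Sw + crossprod(Zi)
  }
  Sw <- Sw / (n - g)
  Sb <- matrix(0, q, q)
  for (lv in levels(labels)) {
    dm <- means[lv, ] - colMeans(Z)
    Sb <- Sb + counts[[lv]] * tcrossprod(dm)
  }
  Sb <- Sb / (g - 1)

  ridge <- mean(diag(Sw))
  if (ridge == 0) ridge <- 1e-12
  Sw_reg <- (1 - shrinkage) * Sw + shrinkage * ridge * diag(q)
  M <- solve(Sw_reg, Sb)
  ei <- eigen(M)
  nd <- min(g - 1, q)
  vecs <- Re(ei$vectors[, seq_len(nd), drop = FALSE])
  # normalize to unit within-class variance per axis
  for (j in seq_len(nd)) {
    s <- sqrt(drop(t(vecs[, j]) %*% Sw_reg %*% vecs[, j]))
    if (s > 0) vecs[, j] <- vecs[, j] / s
  }
  proj <- Z %*% vecs
  colnames(proj) <- paste0("LD", seq_len(nd))

  coords <- tibble::as_tibble(proj)
  coords <- dplyr::mutate(coords,
                          recording_id = rownames(X) %||% as.character(seq_len(n)),
                          condition = as.character(labels),
                          .before = 1)
  centroids <- rowsum(proj, labels) / as.vector(counts)

  eigvals <- Re(ei$values[seq_len(nd)])
  if (max(eigvals) < 1e-10) {
    warning("near-zero between-class scatter; classes are not separable",
            call. = FALSE)
  }
  structure(
    list(coordinates = coords, centroids = centroids,
         scalings = basis %*% vecs, svd_basis = basis, labels = labels,
         eigenvalues = eigvals, shrinkage = shrinkage),
    class = "mted_lda"
  )
}

#' @export
print.mted_lda <- function(x, ...) {
  cat(sprintf("<mted_lda> %d recordings, %d classes, %d discriminant axis/axes\n",
              nrow(x$coordinates), nlevels(x$labels),
              ncol(x$centroids)))
  invisible(x)
}

#' Class-separation statistic of an LDA projection
#'
#' Minimum pairwise centroid distance divided by the pooled within-class
#' standard deviation in the projected space. Values near or below ~1 mean
#' the classes overlap; well-separated classes score far above that.
#'
#' @param fit An `mted_lda` object.
#' @return Scalar separation statistic.
#' @export
lda_separation <- function(fit) {
  stopifnot(inherits(fit, "mted_lda"))
  proj <- as.matrix(fit$coordinates[, grep("^LD", names(fit$coordinates)),
                                    drop = FALSE])
  labels <- fit$labels
  cen <- fit$centroids
  within <- numeric(0)
  for (lv in levels(labels)) {
    Zi <- sweep(proj[labels == lv, , drop = FALSE], 2, cen[lv, ])
    within <- c(within, rowSums(Zi^2))
  }
  pooled_sd <- sqrt(mean(within))
  dmin <- Inf
  lvs <- levels(labels)
  for (i in seq_along(lvs)) for (j in seq_along(lvs)) {
    if (j > i) {
      dmin <- min(dmin, sqrt(sum((cen[lvs[i], ] - cen[lvs[j], ])^2)))
    }
  }
  if (pooled_sd == 0) return(Inf)
  dmin / pooled_sd
}

`%||%` <- function(a, b) if (is.null(a)) b else a
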