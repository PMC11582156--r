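#' Marchenko-Pastur PCA denoising of one patch matrix
#'
#' Classifies the trailing eigenvalues of the patch covariance as noise
#' when their spread is consistent with the Marchenko-Pastur law, estimates
#' the noise variance jointly from that tail, and reconstructs the matrix
#' from the retained (signal) components.  With lam_i = s_i^2 / Q
#' (singular values s, Q = larger matrix dimension) sorted descending and
#' R the smaller dimension, the smallest p is chosen such that
#' \deqn{lam_{p+1} - lam_R \le 4\sqrt{(R-p)/Q}\;\bar{lam}_{tail}}
#' i.e. the tail spread does not exceed the MP support width at the
#' tail-mean variance.
#'
#' @param x Numeric matrix \code{[n_samples x n_measurements]}, both
#'   dimensions >= 2.
#' @return List: \code{denoised} (same shape), \code{sigma2} (noise
#'   variance estimate), \code{rank} (retained components).
#' @export
mppca_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("mppca_matrix needs at least 2 rows and 2 columns")
  flip <- nrow(x) > ncol(x)
  m <- if (flip) t(x) else x             # m: R x Q with R <= Q
  R <- nrow(m); Q <- ncol(m)
  sv <- svd(m)
  lam <- sv$d^2 / Q                      # descending
  lam[lam < lam[1] * 1e-14] <- 0         # numerical-rank floor
  p <- R                                 # default: keep everything
  sigma2 <- 0
  for (k in 0:(R - 1)) {
    tail <- lam[(k + 1):R]
    s1 <- mean(tail)
    edge <- 4 * sqrt((R - k) / Q) * s1
    if ((lam[k + 1] - lam[R]) <= edge) {
      p <- k
      sigma2 <- s1
      break
    }
  }
  den <- if (p == 0) {
    matrix(0, R, Q)
  } else if (p == R) {
    m
  } else {
    sv$u[, 1:p, drop = FALSE] %*%
      (sv$d[1:p] * t(sv$v[, 1:p, drop = FALSE]))
  }
  list(denoised = if (flip) t(den) else den, sigma2 = sigma2, rank = p)
}

# hard-threshold singular components at the Marchenko-Pastur bulk edge
# sigma2*(1+sqrt(R/Q))^2 implied by a known noise variance
mp_threshold_matrix <- function(x, sigma2) {
  R <- min(dim(x)); Q <- max(dim(x))
  sv <- svd(x)
  lam <- sv$d^2 / Q
  p <- sum(lam > sigma2 * (1 + sqrt(R / Q))^2)
  if (p >= length(sv$d)) return(x)
  if (p == 0) return(x * 0)
  ndx <- sv$u[, 1:p, drop = FALSE] %*%
    (sv$d[1:p] * t(sv$v[, 1:p, drop = FALSE]))
  ndx
}

# unfold tensor along one mode: rows = that mode, cols = the rest
unfold <- function(a, mode) {
  d <- dim(a)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(a, perm), nrow = d[mode])
}

refold <- function(m, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Tensor MP-PCA denoising of an MT-weighted image stack
#'
#' Sliding-window patch denoising: each spatial window is treated as a
#' tensor (patch voxels x powers x offsets) and denoised by sequential
#' mode unfoldings — spatial mode first, then powers, then offsets — each
#' thresholded by the Marchenko-Pastur criterion of [mppca_matrix()].
#' Overlapping patch estimates are combined by averaging (or the center
#' voxel only keeps its own patch's estimate).
#'
#' @param stack 4-D array \code{[y, x, n_powers, n_offsets]} or a
#'   \code{phantom_image_set} (denoised in place).
#' @param window Spatial window size per dimension (odd, default 3; the
#'   3-D analogue of the 3 x 3 x 3 window for volumes).
#' @param aggregation "average_overlaps" (default) or "center_voxel".
#' @return List of class \code{denoise_result}: \code{denoised} (array or
#'   image set, same shape/class as input), \code{sigma_map},
#'   \code{rank_map} (patch-center maps), \code{removed} (input minus
#'   denoised array).
#' @export
tmppca <- function(stack, window = 3,
                   aggregation = c("average_overlaps", "center_voxel")) {
  aggregation <- match.arg(aggregation)
  is_set <- inherits(stack, "phantom_image_set")
  arr <- if (is_set) stack$signal else stack
  d <- dim(arr)
  if (length(d) != 4)
    stop("expected a 4-D array [y, x, n_powers, n_offsets]")
  if (d[3] * d[4] < 2)
    stop("need >= 2 measurement volumes; use gaussian_baseline() for single volumes")
  if (window %% 2 != 1) stop("window must be odd")
  if (any(d[1:2] < window)) stop("spatial dims must be >= window")
  half <- (window - 1) / 2
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  sigma_map <- matrix(NA_real_, d[1], d[2])
  rank_map <- matrix(NA_integer_, d[1], d[2])
  centers_y <- (1 + half):(d[1] - half)
  centers_x <- (1 + half):(d[2] - half)
  for (cy in centers_y) for (cx in centers_x) {
    ys <- (cy - half):(cy + half)
    xs <- (cx - half):(cx + half)
    patch <- arr[ys, xs, , , drop = FALSE]
    dims3 <- c(window * window, d[3], d[4])
    ten <- array(patch, dim = dims3)
    # sequential mode denoising: spatial, then powers, then offsets
    r1 <- mppca_matrix(unfold(ten, 1))
    ten <- refold(r1$denoised, 1, dims3)
    # later (short) modes: too few eigenvalues for a reliable MP fit of
    # their own, so threshold them at the MP bulk edge implied by the
    # stage-1 noise estimate (conservative: the post-stage-1 noise level
    # is at most that); zero estimated noise passes the tensor through
    if (d[3] >= 2)
      ten <- refold(mp_threshold_matrix(unfold(ten, 2), r1$sigma2), 2, dims3)
    if (d[4] >= 2)
      ten <- refold(mp_threshold_matrix(unfold(ten, 3), r1$sigma2), 3, dims3)
    est <- array(ten, dim = c(window, window, d[3], d[4]))
    if (aggregation == "average_overlaps") {
      acc[ys, xs, , ] <- acc[ys, xs, , ] + est
      cnt[ys, xs, , ] <- cnt[ys, xs, , ] + 1
    } else {
      ci <- half + 1
      acc[cy, cx, , ] <- est[ci, ci, , ]
      cnt[cy, cx, , ] <- 1
    }
    sigma_map[cy, cx] <- sqrt(r1$sigma2)
    rank_map[cy, cx] <- r1$rank
  }
  if (aggregation == "center_voxel") {
    # border voxels have no patch centered on them: borrow the nearest
    # center's patch estimate
    for (cy in seq_len(d[1])) for (cx in seq_len(d[2])) {
      if (cnt[cy, cx, 1, 1] == 0) {
        ny <- min(max(cy, 1 + half), d[1] - half)
        nx <- min(max(cx, 1 + half), d[2] - half)
        ys <- (ny - half):(ny + half); xs <- (nx - half):(nx + half)
        patch <- array(arr[ys, xs, , , drop = FALSE],
                       dim = c(window * window, d[3] * d[4]))
        est <- array(mppca_matrix(patch)$denoised,
                     dim = c(window, window, d[3], d[4]))
        acc[cy, cx, , ] <- est[cy - ny + half + 1, cx - nx + half + 1, , ]
        cnt[cy, cx, , ] <- 1
      }
    }
  }
  den <- acc / cnt
  out <- if (is_set) { s <- stack; s$signal <- den; s } else den
  structure(list(denoised = out, sigma_map = sigma_map,
                 rank_map = rank_map, removed = arr - den,
                 method = "tmppca", window = window,
                 aggregation = aggregation),
            class = "denoise_result")
}

# separable Gaussian smoothing of one 2-D image, replicate padding
gaussian_smooth2d <- function(img, sd) {
  r <- ceiling(4 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(tmp, 1, pad_conv))
}

#' Gaussian-filter denoising baseline
#'
#' Each (power, offset) volume is smoothed independently in the spatial
#' dimensions with a Gaussian kernel (SD in voxels, default 1); no mixing
#' across measurement volumes.
#'
#' @param stack 4-D array or \code{phantom_image_set}.
#' @param sd Kernel standard deviation in voxels.
#' @return A \code{denoise_result} (empty sigma/rank maps).
#' @export
gaussian_baseline <- function(stack, sd = 1) {
  if (sd <= 0) stop("sd must be > 0")
  is_set <- inherits(stack, "phantom_image_set")
  arr <- if (is_set) stack$signal else stack
  d <- dim(arr)
  if (length(d) != 4)
    stop("expected a 4-D array [y, x, n_powers, n_offsets]")
  den <- arr
  for (i in seq_len(d[3])) for (j in seq_len(d[4]))
    den[, , i, j] <- gaussian_smooth2d(arr[, , i, j], sd)
  out <- if (is_set) { s <- stack; s$signal <- den; s } else den
  structure(list(denoised = out, sigma_map = NULL, rank_map = NULL,
                 removed = arr - den, method = "gaussian", sd = sd),
            class = "denoise_result")
}
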