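#' Principal-path cost functional
#'
#' The regularized k-means cost: the within-cluster sum of squared distances
#' of each sample to its representative, plus `s` times the sum of squared
#' distances between adjacent representatives along the path,
#' `cost = sum_i ||x_i - W_c(i)||^2 + s sum_j ||W_(j+1) - W_j||^2`.
#' Distances are Euclidean in the flattened sample space (3N coordinates for
#' conformations, after alignment to a common frame).
#'
#' @param frames numeric matrix, one sample per row.
#' @param W numeric matrix of K representatives (rows), same column count.
#' @param assignments integer vector (length `nrow(frames)`) of representative
#'   indices in `1..K`.
#' @param s non-negative regularization weight.
#' @return The scalar cost (squared-distance units).
#' @export
pp_cost <- function(frames, W, assignments, s) {
  frames <- as.matrix(frames); W <- as.matrix(W)
  if (s < 0) stop("s must be non-negative")
  if (length(assignments) != nrow(frames))
    stop("assignments length must match number of frames")
  if (any(assignments < 1 | assignments > nrow(W)))
    stop("assignments out of range")
  data_term <- sum((frames - W[assignments, , drop = FALSE])^2)
  spring_term <- sum(diff(W)^2)
  data_term + s * spring_term
}

assign_nearest <- function(frames, W) {
  # squared distances via ||x||^2 - 2 x.W + ||W||^2; ties -> lower index
  d2 <- outer(rowSums(frames^2), rowSums(W^2), "+") - 2 * frames %*% t(W)
  max.col(-d2, ties.method = "first")
}

#' Fit a principal path between two pinned endpoints
#'
#' Alternating minimization of [pp_cost()]: samples are assigned to their
#' nearest representative, then the interior representatives are updated by
#' solving the exact (tridiagonal) stationarity system of the cost with the
#' endpoint representatives pinned to `endpoint_A` and `endpoint_B`. Both
#' half-steps lower the cost, so convergence is monotone. Interior
#' representatives are initialized on the linear interpolation from A to B,
#' which makes the fit deterministic. Representatives are generally *not*
#' elements of the input sample: they optimize the variance of the path.
#'
#' @param frames numeric matrix, one flattened sample per row (use
#'   [traj_frame_matrix()] for conformations).
#' @param endpoint_A,endpoint_B vectors (same length as a sample row) the
#'   first and last representatives are pinned to.
#' @param K total number of representatives including the endpoints (>= 3).
#' @param s regularization weight (>= 0).
#' @param max_iter,tol iteration cap and relative cost-change tolerance.
#' @return An object of class `principal_path`: list with `W` (K-row matrix),
#'   `assignments`, `s`, `cost`, `cost_history`, `counts`, `converged`.
#' @examples
#' cl <- make_arc_cloud(200, noise_sd = 0.3)
#' fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 8, s = 1)
#' fit$cost
#' @export
fit_principal_path <- function(frames, endpoint_A, endpoint_B, K, s,
                               max_iter = 500L, tol = 1e-8) {
  frames <- as.matrix(frames)
  if (K < 3) stop("K must be >= 3")
  if (nrow(frames) < K) stop("need at least K frames")
  if (s < 0) stop("s must be non-negative")
  a <- as.numeric(endpoint_A); b <- as.numeric(endpoint_B)
  if (length(a) != ncol(frames) || length(b) != ncol(frames))
    stop("endpoint dimension must match frame dimension")
  t_init <- seq(0, 1, length.out = K)
  W <- outer(1 - t_init, a) + outer(t_init, b)
  cost_history <- numeric(0)
  assignments <- assign_nearest(frames, W)
  for (it in seq_len(max_iter)) {
    # W-step: exact minimization for the interior given assignments
    counts <- tabulate(assignments, nbins = K)
    Ki <- K - 2L
    S <- matrix(0, Ki, ncol(frames))
    for (j in seq_len(Ki)) {
      ix <- which(assignments == j + 1L)
      if (length(ix)) S[j, ] <- colSums(frames[ix, , drop = FALSE])
    }
    if (s > 0 || all(counts[2:(K - 1L)] > 0)) {
      M <- diag(counts[2:(K - 1L)] + 2 * s, Ki)
      if (Ki > 1) {
        ij <- cbind(1:(Ki - 1), 2:Ki)
        M[ij] <- M[ij[, 2:1, drop = FALSE]] <- -s
      }
      rhs <- S
      rhs[1, ] <- rhs[1, ] + s * a
      rhs[Ki, ] <- rhs[Ki, ] + s * b
      W[2:(K - 1L), ] <- solve(M, rhs)
    } else {
      # s = 0: plain k-means centroid update, empty clusters retained
      for (j in seq_len(Ki)) {
        if (counts[j + 1L] > 0) W[j + 1L, ] <- S[j, ] / counts[j + 1L]
      }
      warning("empty cluster(s) at s = 0: representative(s) retained")
    }
    # assignment step
    assignments <- assign_nearest(frames, W)
    cost <- pp_cost(frames, W, assignments, s)
    cost_history <- c(cost_history, cost)
    if (it > 1 &&
        abs(cost_history[it - 1] - cost) <=
          tol * max(abs(cost_history[it - 1]), 1e-12)) break
    if (s == 0 && any(counts[2:(K - 1L)] == 0)) next
  }
  structure(list(W = W, assignments = assignments, s = s,
                 cost = cost_history[length(cost_history)],
                 cost_history = cost_history,
                 counts = tabulate(assignments, nbins = K),
                 converged = length(cost_history) < max_iter),
            class = "principal_path")
}

#' @export
print.principal_path <- function(x, ...) {
  cat(sprintf("<principal_path> K = %d representatives, s = %.4g, cost = %.6g (%d iterations%s)\n",
              nrow(x$W), x$s, x$cost, length(x$cost_history),
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Select the regularization weight by Bayesian evidence maximization
#'
#' The cost functional is read as an energy: the posterior over the interior
#' representatives is proportional to `exp(-cost)`, i.e. a Gaussian
#' likelihood around the representatives times a pinned-chain Gaussian
#' smoothness prior with precision `s`. For each candidate `s` the path is
#' fitted and the marginal likelihood (evidence) is computed by the Laplace
#' approximation around the fitted optimum, *including the prior
#' normalization in s* — without it the evidence is monotone in `s` and
#' selection is meaningless. Up to s-independent constants,
#' `log ev(s) = -cost(W*) - 1/2 log det H + (d/2) log(2 s) + (D/2) log(K-1)`
#' with `H` the (block-tridiagonal) Hessian of the cost, `d = (K-2) D` free
#' dimensions, and `log(K-1)` the pinned-chain graph determinant.
#'
#' @inheritParams fit_principal_path
#' @param s_grid candidate weights; default 10 log-spaced values spanning
#'   `[1e-3, 1e3]` times the mean squared frame-to-frame displacement.
#' @return A list with `s_best`, `fit` (the path refitted at `s_best`), and
#'   `evidence`: a tibble (`s`, `cost`, `log_evidence`, `converged`).
#' @export
select_s <- function(frames, endpoint_A, endpoint_B, K, s_grid = NULL) {
  frames <- as.matrix(frames)
  if (is.null(s_grid)) {
    msd <- mean(rowSums(diff(frames)^2))
    if (!is.finite(msd) || msd <= 0) msd <- 1
    s_grid <- 10^seq(-3, 3, length.out = 10) * msd
  }
  if (any(s_grid <= 0)) stop("s_grid values must be positive")
  if (length(s_grid) == 1L) {
    warning("s_grid of length 1: no selection possible, returning that s")
    fit <- fit_principal_path(frames, endpoint_A, endpoint_B, K, s_grid)
    return(list(s_best = s_grid, fit = fit,
                evidence = tibble::tibble(s = s_grid, cost = fit$cost,
                                          log_evidence = NA_real_,
                                          converged = fit$converged)))
  }
  if (nrow(unique(frames)) < 2L)
    warning("degenerate input: all frames identical, evidence comparison ",
            "is not meaningful")
  D <- ncol(frames)
  Ki <- K - 2L
  ev <- vapply(s_grid, function(s) {
    fit <- fit_principal_path(frames, endpoint_A, endpoint_B, K, s)
    counts <- fit$counts
    # Hessian of cost wrt interior W: D identical tridiagonal blocks
    Tm <- diag(2 * (counts[2:(K - 1L)] + 2 * s), Ki)
    if (Ki > 1) {
      ij <- cbind(1:(Ki - 1), 2:Ki)
      Tm[ij] <- Tm[ij[, 2:1, drop = FALSE]] <- -2 * s
    }
    ld <- determinant(Tm, logarithm = TRUE)
    logdetH <- D * as.numeric(ld$modulus)
    loge <- -fit$cost - 0.5 * logdetH +
      (Ki * D / 2) * log(2 * s) + (D / 2) * log(K - 1)
    c(cost = fit$cost, log_evidence = loge, converged = fit$converged)
  }, c(cost = 0, log_evidence = 0, converged = 0))
  best <- which.max(ev["log_evidence", ])
  list(s_best = s_grid[best],
       fit = fit_principal_path(frames, endpoint_A, endpoint_B, K,
                                s_grid[best]),
       evidence = tibble::tibble(s = s_grid, cost = ev["cost", ],
                                 log_evidence = ev["log_evidence", ],
                                 converged = as.logical(ev["converged", ])))
}

#' Nearest trajectory frames to the path representatives
#'
#' For each representative, the index of the closest input sample (Euclidean
#' distance in the flattened space); ties are broken in favor of the earlier
#' frame. Used to extract an actual-simulation counterpart of the optimized
#' path.
#'
#' @param path a fitted `principal_path`.
#' @param frames the sample matrix the path was fitted on.
#' @return Integer vector of frame indices, one per representative.
#' @export
nearest_frames <- function(path, frames) {
  frames <- as.matrix(frames)
  W <- path$W
  d2 <- outer(rowSums(W^2), rowSums(frames^2), "+") - 2 * W %*% t(frames)
  apply(d2, 1, which.min)
}

#' Flatten and align trajectory frames for clustering
#'
#' Kabsch-superposes every frame onto a common reference conformation
#' (typically endpoint A) and flattens each to a 3N row vector, so Euclidean
#' distances between rows are pure shape distances.
#'
#' @param traj an `mcg_trajectory` or list of N x 3 frames.
#' @param reference conformation to align all frames to.
#' @return A matrix with one flattened aligned frame per row.
#' @export
traj_frame_matrix <- function(traj, reference) {
  frames <- if (inherits(traj, "mcg_trajectory")) traj$frames else traj
  ref <- coords_of(reference)
  do.call(rbind, lapply(frames, function(f)
    as.numeric(t(kabsch_superpose(coords_of(f), ref)$aligned))))
}
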