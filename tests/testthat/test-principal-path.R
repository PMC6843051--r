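test_that("pp_cost reduces to k-means WCSS at s = 0", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 5), 20, 2))
  km <- stats::kmeans(pts, centers = rbind(c(0, 0), c(5, 5)))
  expect_equal(pp_cost(pts, km$centers, km$cluster, 0), km$tot.withinss,
               tolerance = 1e-9)
})

test_that("pp_cost hand-computed spring case", {
  # one frame sitting on its representative; 3 collinear equidistant reps
  W <- matrix(c(0, 1, 2), ncol = 1) * 3
  fr <- matrix(3, 1, 1)
  expect_equal(pp_cost(fr, W, 2L, s = 0.5), 2 * 0.5 * 9)
  expect_error(pp_cost(fr, W, 2L, s = -1), "non-negative")
  expect_error(pp_cost(fr, W, 5L, 1), "range")
})

test_that("alternating minimization converges monotonically", {
  cl <- make_arc_cloud(300, noise_sd = 0.5, seed = 3)
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 8, s = 5)
  expect_true(all(diff(fit$cost_history) <= 1e-9))
  expect_true(fit$converged)
  expect_equal(nrow(fit$W), 8)
  expect_equal(fit$W[1, ], cl$A)
  expect_equal(fit$W[8, ], cl$B)
})

test_that("collinear data give ordered on-segment representatives", {
  t <- seq(0, 1, length.out = 60)
  seg <- cbind(t * 10, 0 * t)
  fit <- fit_principal_path(seg, c(0, 0), c(10, 0), K = 5, s = 1)
  expect_lt(max(abs(fit$W[, 2])), 1e-9)
  expect_true(all(diff(fit$W[, 1]) > 0))
})

test_that("spring-dominated limit spaces representatives uniformly", {
  cl <- make_arc_cloud(200, noise_sd = 0.4, seed = 5)
  s_big <- 1e6 * stats::var(as.numeric(cl$points))
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 6, s = s_big)
  steps <- sqrt(rowSums(diff(fit$W)^2))
  expect_lt(stats::sd(steps) / mean(steps), 1e-3)
  # and the path approaches the straight A-B segment
  t <- seq(0, 1, length.out = 6)
  straight <- outer(1 - t, cl$A) + outer(t, cl$B)
  expect_lt(max(abs(fit$W - straight)), 0.05 * cl$radius)
})

test_that("fitted path beats the straight-line alternative on arc data", {
  cl <- make_arc_cloud(400, noise_sd = 0.5, seed = 7)
  K <- 8; s <- 5
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K, s)
  t <- seq(0, 1, length.out = K)
  straight <- outer(1 - t, cl$A) + outer(t, cl$B)
  asg <- apply(outer(rowSums(cl$points^2), rowSums(straight^2), "+") -
                 2 * cl$points %*% t(straight), 1, which.min)
  expect_lte(fit$cost, pp_cost(cl$points, straight, asg, s))
  # representatives track the generating curve
  expect_lt(mean(cl$arc_distance(fit$W)), 2 * 0.5)
})

test_that("1-D fits match exhaustive grid search", {
  fr <- matrix(c(0.1, 0.25, 0.4, 0.55, 0.7, 0.9), ncol = 1)
  for (s in c(0.2, 0.7, 2)) {
    grid <- seq(0, 1, by = 0.01)
    best <- Inf
    for (w2 in grid) for (w3 in grid) {
      W <- matrix(c(0, w2, w3, 1), ncol = 1)
      d <- abs(outer(fr[, 1], W[, 1], "-"))
      asg <- apply(d, 1, which.min)
      cst <- pp_cost(fr, W, asg, s)
      if (cst < best) best <- cst
    }
    fit <- fit_principal_path(fr, 0, 1, K = 4, s = s)
    expect_lt(abs(fit$cost - best), 1e-3)  # within grid resolution
  }
})

test_that("evidence maximization selects an interior s", {
  hits <- 0
  for (rep in 1:10) {
    set.seed(rep)
    verts <- rbind(c(0, 0), c(3, 4), c(7, 4), c(10, 0))
    tt <- stats::runif(300); sg <- sample(1:3, 300, TRUE)
    pts <- t(vapply(1:300, function(i)
      verts[sg[i], ] * (1 - tt[i]) + verts[sg[i] + 1, ] * tt[i],
      numeric(2))) + matrix(stats::rnorm(600, sd = 0.3), 300, 2)
    sel <- select_s(pts, c(0, 0), c(10, 0), K = 6)
    if (sel$s_best > min(sel$evidence$s) && sel$s_best < max(sel$evidence$s))
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("degenerate selection inputs are handled with warnings", {
  fr <- matrix(rep(c(1, 2), each = 4), 4, 2)
  expect_warning(select_s(fr, c(1, 2), c(1, 2), K = 3, s_grid = c(1, 2)),
                 "degenerate|identical")
  cl <- make_arc_cloud(50, 0.2, 2)
  expect_warning(sel <- select_s(cl$points, cl$A, cl$B, K = 4, s_grid = 3),
                 "length 1")
  expect_equal(sel$s_best, 3)
})

test_that("nearest frames pick exact matches and break ties early", {
  cl <- make_arc_cloud(100, noise_sd = 0.3, seed = 9)
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 5, s = 2)
  # representative placed exactly on a frame
  fit$W[3, ] <- cl$points[42, ]
  expect_equal(nearest_frames(fit, cl$points)[3], 42L)
  # tie: two identical frames -> earlier index
  fr <- rbind(c(0, 0), c(5, 5), c(5, 5), c(10, 0))
  f2 <- fit_principal_path(fr, c(0, 0), c(10, 0), K = 3, s = 1)
  f2$W[2, ] <- c(5, 5)
  expect_equal(nearest_frames(f2, fr)[2], 2L)
})

test_that("nearest-frame energies lie at or above the representative cost", {
  # representatives minimize the quadratic cost, so swapping each for its
  # nearest actual frame cannot lower the data term
  cl <- make_arc_cloud(200, noise_sd = 0.5, seed = 12)
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 6, s = 2)
  nf <- nearest_frames(fit, cl$points)
  W_frames <- cl$points[nf, ]
  expect_gte(pp_cost(cl$points, W_frames, fit$assignments, fit$s), fit$cost)
})

test_that("tidiers summarize fits", {
  cl <- make_arc_cloud(80, noise_sd = 0.3, seed = 15)
  fit <- fit_principal_path(cl$points, cl$A, cl$B, K = 5, s = 1)
  td <- tidy(fit); gl <- glance(fit)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$n_assigned), 80)
  expect_equal(gl$K, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})
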