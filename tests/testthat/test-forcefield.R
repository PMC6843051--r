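test_that("angle stiffness follows the damped-sinc parameterization", {
  # frozen from independent evaluation of k(theta0) = (B sinc^2(b t) + k0)/sin^2 t
  expect_equal(angle_stiffness(pi / 1.667), 11.05302, tolerance = 1e-5)
  expect_equal(angle_stiffness(pi / 2), 119.1848, tolerance = 1e-5)
  expect_equal(angle_stiffness(120 * pi / 180), 51.8669, tolerance = 1e-5)
  expect_true(all(angle_stiffness(seq(0.1, 3.0, by = 0.05)) > 0))
  expect_warning(angle_stiffness(0.01), "clamped")
})

test_that("dihedral amplitude splits helices from strands at 80 degrees", {
  deg <- pi / 180
  expect_equal(dihedral_amplitude(50 * deg), 25)
  expect_equal(dihedral_amplitude(120 * deg), 5)
  expect_equal(dihedral_amplitude(80 * deg), 25)   # boundary included
  expect_equal(dihedral_amplitude(-50 * deg), 25)  # absolute-value rule
  expect_equal(dihedral_amplitude(-120 * deg), 5)
})

test_that("local Morse parameters decay from H-bond strength to the floor", {
  p38 <- local_morse_params(3.8)
  expect_equal(p38$epsilon, 3.764788, tolerance = 1e-5)
  expect_equal(p38$alpha, 2.850667, tolerance = 1e-5)
  p84 <- local_morse_params(8.4)
  expect_equal(p84$epsilon, 0.05, tolerance = 1e-3)
  expect_equal(p84$alpha, 0.70, tolerance = 1e-3)
  p0 <- local_morse_params(1e-6)
  expect_equal(p0$epsilon, 3.85, tolerance = 1e-6)
  expect_equal(p0$alpha, 2.90, tolerance = 1e-6)
  expect_error(local_morse_params(8.6), "non-local")
  # monotone non-increasing with floors
  r <- seq(0.5, 8.4, by = 0.1)
  lp <- local_morse_params(r)
  expect_true(all(diff(lp$epsilon) <= 0) && all(diff(lp$alpha) <= 0))
  expect_true(all(lp$epsilon >= 0.05) && all(lp$alpha >= 0.70))
})

test_that("topology compilation classifies pairs by the 8.5 A cutoff", {
  topo <- build_topology(make_helix(30))
  expect_equal(nrow(topo$bonds), 29)
  expect_equal(nrow(topo$angles), 28)
  expect_equal(nrow(topo$dihedrals), 27)
  # helix (i, i+4) contacts are local
  i4 <- topo$local_pairs[topo$local_pairs[, "j"] - topo$local_pairs[, "i"] == 4, ]
  expect_equal(nrow(i4), 26)
  expect_true(all(topo$local_pairs[, "r0"] < 8.5))
  # extended chain: all |i-j| > 3 pairs beyond cutoff (e.g. the 1-5 distance
  # of the zig-zag strand is 14.1 A)
  topo_s <- build_topology(make_strand(8))
  expect_equal(nrow(topo_s$local_pairs), 0)
  expect_true(all(topo_s$nonlocal_pairs[, "j"] - topo_s$nonlocal_pairs[, "i"] > 3))
})

test_that("pair partition is complete and disjoint on random traces", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(8:30, 1)
    topo <- build_topology(random_trace(n, sd = 0.4, seed = rep))
    expected <- sum(outer(1:n, 1:n, function(i, j) j - i > 3))
    keys <- c(paste(topo$local_pairs[, 1], topo$local_pairs[, 2]),
              paste(topo$nonlocal_pairs[, 1], topo$nonlocal_pairs[, 2]))
    expect_equal(length(keys), expected)
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("rigid motion leaves the compiled topology unchanged", {
  x <- make_helix(20)$coords
  set.seed(5)
  y <- sweep(x %*% random_rotation(), 2, rnorm(3, sd = 8), "+")
  ta <- build_topology(ca_trace(x)); tb <- build_topology(ca_trace(y))
  expect_equal(ta$bonds, tb$bonds, tolerance = 1e-9)
  expect_equal(ta$angles, tb$angles, tolerance = 1e-9)
  expect_equal(ta$dihedrals, tb$dihedrals, tolerance = 1e-9)
  expect_equal(ta$local_pairs, tb$local_pairs, tolerance = 1e-9)
})

test_that("energy at the reference sits at the biased minima", {
  h <- make_helix(25)
  topo <- build_topology(h)
  e <- mcg_energy(h, topo)
  expect_equal(e[["angle"]], 0, tolerance = 1e-12)
  expect_equal(e[["dihedral"]], 0, tolerance = 1e-12)
  expect_equal(e[["local"]], -sum(topo$local_pairs[, "epsilon"]),
               tolerance = 1e-9)
})

test_that("the generic non-local well has depth 0.05 at 9.5 A", {
  expect_equal(morse_energy(9.5, 0.05, 0.7, 9.5), -0.05)
  expect_equal(morse_energy(1e4, 0.05, 0.7, 9.5), 0, tolerance = 1e-12)
  # energy() applies the same generic well (truncated and shifted at 25 A)
  # to every non-local pair of an extended strand
  topo <- build_topology(make_strand(8))
  stopifnot(nrow(topo$local_pairs) == 0)
  x <- make_strand(8)$coords
  e0 <- mcg_energy(x, topo)[["nonlocal"]]
  expect_equal(e0,
    sum(apply(topo$nonlocal_pairs, 1, function(p) {
      r <- sqrt(sum((x[p[1], ] - x[p[2], ])^2))
      if (r >= 25) 0 else morse_energy(r, 0.05, 0.7, 9.5) -
        morse_energy(25, 0.05, 0.7, 9.5)
    })), tolerance = 1e-9)
})

test_that("overlapping beads are rejected by name", {
  h <- make_helix(12); topo <- build_topology(h)
  x <- h$coords; x[9, ] <- x[1, ] + c(0.01, 0, 0)
  expect_error(mcg_energy(x, topo), "overlapping")
})

test_that("analytic forces agree with finite differences", {
  topo <- build_topology(make_helix(20))
  worst <- 0
  for (rep in 1:50) {
    x <- perturbed_helix(20, sd = 0.35, seed = 100 + rep)
    f <- mcg_forces(x, topo, harmonic_k = 100)
    fd <- fd_forces(x, topo, harmonic_k = 100)
    rel <- max(abs(f - fd)) / max(abs(fd))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("biased terms exert no force at the reference", {
  h <- make_helix(20)
  topo <- build_topology(h)
  topo_b <- topo
  topo_b$nonlocal_pairs <- topo$nonlocal_pairs[0, , drop = FALSE]
  # without the (unbiased) non-local term every contribution is at its rest
  f <- mcg_forces(h, topo_b)
  expect_lt(max(abs(f)), 1e-8)
})

test_that("net force and torque vanish for any conformation", {
  topo <- build_topology(make_helix(20))
  for (rep in 1:5) {
    x <- perturbed_helix(20, sd = 0.4, seed = 200 + rep)
    f <- mcg_forces(x, topo, harmonic_k = 50)
    expect_lt(max(abs(colSums(f))), 1e-8)
    tq <- colSums(cbind(x[, 2] * f[, 3] - x[, 3] * f[, 2],
                        x[, 3] * f[, 1] - x[, 1] * f[, 3],
                        x[, 1] * f[, 2] - x[, 2] * f[, 1]))
    expect_lt(max(abs(tq)), 1e-8)
  }
})

test_that("each local Morse term has its minimum at r0 with depth epsilon", {
  topo <- build_topology(make_helix(15))
  for (p in seq_len(nrow(topo$local_pairs))) {
    r0 <- unname(topo$local_pairs[p, "r0"])
    eps <- unname(topo$local_pairs[p, "epsilon"])
    al <- unname(topo$local_pairs[p, "alpha"])
    o <- optimize(morse_energy, c(0.5, 24), epsilon = eps, alpha = al,
                  r0 = r0, tol = 1e-9)
    expect_equal(o$minimum, r0, tolerance = 1e-4)
    expect_equal(o$objective, -eps, tolerance = 1e-9)
  }
})

test_that("energy is invariant under rigid motion", {
  topo <- build_topology(make_helix(18))
  x <- perturbed_helix(18, sd = 0.3, seed = 31)
  e0 <- mcg_energy(x, topo)[["total"]]
  set.seed(32)
  for (i in 1:10) {
    y <- sweep(x %*% random_rotation(), 2, rnorm(3, sd = 30), "+")
    expect_equal(mcg_energy(y, topo)[["total"]], e0, tolerance = 1e-9)
  }
})

test_that("topology JSON round trip preserves every term", {
  topo <- build_topology(make_helix(15))
  p <- tempfile(fileext = ".json")
  write_topology_json(topo, p)
  back <- read_topology_json(p)
  expect_equal(back$bonds, topo$bonds)
  expect_equal(back$angles, topo$angles)
  expect_equal(back$dihedrals, topo$dihedrals)
  expect_equal(back$local_pairs, topo$local_pairs)
  expect_equal(back$nonlocal_pairs, topo$nonlocal_pairs)
  expect_equal(mcg_energy(make_helix(15), back),
               mcg_energy(make_helix(15), topo))
})
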