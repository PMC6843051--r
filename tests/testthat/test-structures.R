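test_that("read_ca_trace parses a C-alpha chain in file order", {
  x <- cbind(3.8 * (0:3), 0, 0)
  tr <- read_ca_trace(pdb_text(x))
  expect_s3_class(tr, "ca_trace")
  expect_equal(nrow(tr$coords), 4L)
  expect_equal(unname(tr$coords), unname(x), tolerance = 1e-6)
  d <- sqrt(rowSums(diff(tr$coords)^2))
  expect_equal(d, rep(3.8, 3), tolerance = 1e-6)
})

test_that("missing chain errors and names the available chains", {
  x <- cbind(3.8 * (0:3), 0, 0)
  expect_error(read_ca_trace(pdb_text(x, chain = "A"), chain = "Z"), "A")
})

test_that("altloc resolved to highest occupancy", {
  x <- cbind(3.8 * (0:3), 0, 0)
  xalt <- x; xalt[2, 2] <- 9.9
  lines <- c(pdb_text(x, altloc = c("", "A", "", ""),
                      occ = c(1, 0.6, 1, 1))[1:2],
             pdb_text(xalt, altloc = rep("B", 4), occ = rep(0.4, 4))[2],
             pdb_text(x)[3:4])
  # altloc records carry distinct atom serials in real files
  lines <- sprintf("%s%5d%s", substr(lines, 1, 6), seq_along(lines),
                   substr(lines, 12, nchar(lines)))
  tr <- read_ca_trace(lines)
  expect_equal(nrow(tr$coords), 4L)
  expect_equal(tr$coords[2, 2], 0)   # the 0.6-occupancy record wins
})

test_that("chain breaks and bad traces are rejected", {
  x <- cbind(c(0, 3.8, 30, 33.8), 0, 0)
  expect_error(ca_trace(x), "chain break")
  expect_error(ca_trace(cbind(0:2, 0, 0)), "at least 4")
  xx <- cbind(3.8 * (0:3), 0, 0); xx[1, 1] <- NaN
  expect_error(ca_trace(xx), "finite")
})

test_that("internal coordinates match closed-form cases", {
  sq <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0))
  ic <- compute_internal_coords(sq)
  expect_equal(ic$bond_angles, rep(pi / 2, 2))
  expect_equal(ic$dihedrals, 0)
  # ideal helix: all residues see the same geometry; closed-form from the
  # generator parameters (rise 1.5, radius 2.3, twist 100 deg)
  ic_h <- compute_internal_coords(make_helix(30))
  expect_lt(diff(range(ic_h$bond_angles)), 1e-9)
  expect_lt(diff(range(ic_h$dihedrals)), 1e-9)
  expect_true(all(abs(ic_h$bond_angles * 180 / pi - 91) < 1))
  expect_true(all(abs(ic_h$dihedrals * 180 / pi - 50) < 1))
  ic_s <- compute_internal_coords(make_strand(20))
  expect_true(all(ic_s$bond_angles * 180 / pi > 110))
})

test_that("collinear beads make the dihedral undefined", {
  x <- cbind(c(0, 3.8, 7.6, 9), c(0, 0, 0, 3), 0)
  expect_error(compute_internal_coords(x), "collinear")
})

test_that("internal coordinates are rigid-motion invariant", {
  set.seed(11)
  x <- make_helix(12)$coords
  ic0 <- compute_internal_coords(x)
  for (i in 1:5) {
    r <- random_rotation()
    y <- sweep(x %*% r, 2, rnorm(3, sd = 10), "+")
    ic <- compute_internal_coords(y)
    expect_equal(ic$bond_angles, ic0$bond_angles, tolerance = 1e-9)
    expect_equal(ic$dihedrals, ic0$dihedrals, tolerance = 1e-9)
  }
})

test_that("build_from_internal inverts compute_internal_coords", {
  ic <- compute_internal_coords(make_helix(15))
  x <- build_from_internal(ic$bond_lengths, ic$bond_angles, ic$dihedrals)
  ic2 <- compute_internal_coords(x)
  expect_equal(ic2$bond_lengths, ic$bond_lengths, tolerance = 1e-10)
  expect_equal(ic2$bond_angles, ic$bond_angles, tolerance = 1e-10)
  expect_equal(ic2$dihedrals, ic$dihedrals, tolerance = 1e-10)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  x <- make_helix(10)$coords
  rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))   # 90 deg about z
  y <- sweep(x %*% rz, 2, c(5, 5, 5), "+")
  fit <- kabsch_superpose(y, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  set.seed(4)
  for (i in 1:10) {
    r <- random_rotation(); t <- rnorm(3, sd = 20)
    expect_lt(kabsch_superpose(sweep(x %*% r, 2, t, "+"), x)$rmsd, 1e-9)
  }
})

test_that("mirror images are not superposable (chirality preserved)", {
  set.seed(7)
  x <- matrix(rnorm(12), 4, 3)
  mirror <- x %*% diag(c(-1, 1, 1))
  expect_gt(kabsch_superpose(mirror, x)$rmsd, 0.1)
})

test_that("Kabsch RMSD matches the quaternion oracle and is symmetric", {
  hp <- make_hinge_pair(40, 30, 120)
  a <- hp$A$coords; b <- hp$B$coords
  expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
               tolerance = 1e-8)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:10, ], b), "equal")
})

test_that("trajectory round trips preserve coordinates", {
  frames <- lapply(1:3, function(i) perturbed_helix(10, sd = 0.2, seed = i))
  xyz <- tempfile(fileext = ".xyz")
  write_trajectory(frames, xyz)
  back <- read_trajectory(xyz)
  expect_length(back, 3)
  for (i in 1:3)
    expect_lt(max(abs(back[[i]] - frames[[i]])), 1e-6)
  pdb <- tempfile(fileext = ".pdb")
  write_trajectory(frames, pdb)
  expect_equal(sum(grepl("^MODEL", readLines(pdb))), 3L)
  backp <- read_trajectory(pdb)
  for (i in 1:3)
    expect_lt(max(abs(backp[[i]] - frames[[i]])), 1e-3 + 1e-9)
  expect_error(write_trajectory(list(), tempfile(fileext = ".xyz")), "empty")
  expect_error(write_trajectory(frames, tempfile(), format = "dcd"))
})

test_that("single-trace PDB writer round trips through read_ca_trace", {
  h <- make_helix(12)
  p <- tempfile(fileext = ".pdb")
  write_ca_pdb(h, p)
  tr <- read_ca_trace(p)
  expect_lt(max(abs(tr$coords - h$coords)), 1e-3 + 1e-9)
})
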