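#' Ideal C-alpha helix
#'
#' Parametric alpha-helix-like C-alpha trace: rise 1.5 A per residue, radius
#' 2.3 A, twist 100 degrees per residue. The noiseless geometry lands in the
#' helical regime of the force field (pseudo bond angles near 90 degrees,
#' pseudo-dihedrals near 50 degrees, C-alpha spacing 3.8 +/- 0.1 A).
#'
#' @param n number of residues (>= 4).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param noise_sd isotropic Gaussian positional noise (Angstrom).
#' @param rise,radius,twist_deg helix parameters.
#' @return A [ca_trace()].
#' @examples
#' h <- make_helix(30)
#' range(compute_internal_coords(h)$bond_angles) * 180 / pi
#' @export
make_helix <- function(n, seed = 1L, noise_sd = 0, rise = 1.5, radius = 2.3,
                       twist_deg = 100) {
  if (n < 4L) stop("helix needs n >= 4")
  t <- (seq_len(n) - 1) * twist_deg * pi / 180
  x <- cbind(radius * cos(t), radius * sin(t), rise * (seq_len(n) - 1))
  x <- add_noise(x, noise_sd, seed)
  ca_trace(x, label = "helix")
}

#' Ideal extended C-alpha strand
#'
#' Planar zig-zag with bond vectors alternating +/- 25 degrees off the chain
#' axis (bond length 3.8 A), giving pseudo bond angles of 130 degrees and
#' pseudo-dihedrals of 180 degrees: squarely in the strand regime of the
#' force field (angles above 110 degrees, |dihedral| above 80 degrees).
#'
#' @inheritParams make_helix
#' @return A [ca_trace()].
#' @export
make_strand <- function(n, seed = 1L, noise_sd = 0) {
  if (n < 4L) stop("strand needs n >= 4")
  a <- 25 * pi / 180
  bonds <- cbind(3.8 * cos(a), 3.8 * sin(a) * (-1)^(seq_len(n - 1)), 0)
  x <- rbind(0, apply(bonds, 2, cumsum))
  x <- add_noise(x, noise_sd, seed)
  ca_trace(x, label = "strand")
}

add_noise <- function(x, noise_sd, seed) {
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow(x), 3)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  x
}

#' Two-state toy hinge protein
#'
#' Desk-scale analog of a two-state open/closed protein: two helical arms
#' joined by a 4-residue loop (bond angles 100 degrees, dihedrals 180
#' degrees). The two conformations share identical bonded internal
#' coordinates everywhere except the central loop bond angle, which is set
#' to the opening angle `chi_A` in state A and `chi_B` in state B — i.e.
#' state B is state A with the second arm rigidly rotated, in the hinge
#' plane, about the central loop bead. Small opening angles fold the arms
#' back onto each other (closed clamshell, with inter-arm contacts inside
#' the 8.5 A local cutoff); large ones splay them apart (open state).
#'
#' @param n total residues (>= 16).
#' @param chi_A,chi_B opening (hinge bond) angles in degrees, in (10, 170);
#'   must differ.
#' @param seed kept for API symmetry; the construction is deterministic.
#' @return A list with `ca_trace` elements `A` and `B`.
#' @examples
#' hp <- make_hinge_pair(40, 30, 120)
#' rmsd_after_fit(hp$A, hp$B)
#' @export
make_hinge_pair <- function(n, chi_A = 30, chi_B = 120, seed = 1L) {
  if (n < 16L) stop("hinge needs n >= 16")
  if (isTRUE(all.equal(chi_A, chi_B))) stop("chi_A and chi_B must differ")
  for (chi in c(chi_A, chi_B))
    if (!is.finite(chi) || chi <= 10 || chi >= 170)
      stop("invalid opening angle: need 10 < chi < 170 degrees")
  ref <- compute_internal_coords(make_helix(8))
  d_h <- mean(ref$bond_lengths)
  th_h <- ref$bond_angles[2]
  ph_h <- ref$dihedrals[2]
  m <- (n - 4L) %/% 2L                   # arm 1 = beads 1..m, loop = m+1..m+4
  in_arm <- function(j) j <= m | j > m + 4L
  # chi-independent base conformation
  cent <- 2:(n - 1L)                     # angle i is centered at bead i+1
  th <- ifelse(in_arm(cent), th_h, 100 * pi / 180)
  quad_arm <- vapply(seq_len(n - 3L), function(i)
    all(in_arm(i:(i + 3L))), logical(1))
  ph <- ifelse(quad_arm, ph_h, pi)
  x0 <- build_from_internal(rep(d_h, n - 1L), th, ph)
  # arm axes (dominant principal direction, oriented along the chain)
  axis_of <- function(x) {
    a <- svd(scale(x, scale = FALSE))$v[, 1]
    a * sign(sum((x[nrow(x), ] - x[1, ]) * a))
  }
  a1 <- axis_of(x0[1:m, , drop = FALSE])
  a2 <- axis_of(x0[(m + 5L):n, , drop = FALSE])
  # opening angle: between the arms as rods seen from the hinge, i.e. between
  # -a1 (hinge -> arm-1 tail) and +a2 (hinge -> arm-2 tip)
  open_angle <- function(b2) acos(pmin(1, pmax(-1, -sum(a1 * b2)))) * 180 / pi
  chi0 <- open_angle(a2)
  nhat <- cross3(a1, a2)
  nhat <- nhat / sqrt(sum(nhat^2))
  pivot <- x0[m + 2L, ]
  rotate_half <- function(delta_deg) {
    ang <- delta_deg * pi / 180
    K <- rbind(c(0, -nhat[3], nhat[2]), c(nhat[3], 0, -nhat[1]),
               c(-nhat[2], nhat[1], 0))
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    x <- x0
    idx <- (m + 3L):n
    x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2, pivot) %*% t(R),
                      2, pivot, "+")
    x
  }
  build <- function(chi_deg) {
    # rotate the second half about the hinge; pick the rotation sense that
    # realizes chi as the inter-arm-axis angle
    cand <- list(rotate_half(chi_deg - chi0), rotate_half(chi0 - chi_deg))
    realized <- vapply(cand, function(x)
      open_angle(axis_of(x[(m + 5L):n, , drop = FALSE])), numeric(1))
    cand[[which.min(abs(realized - chi_deg))]]
  }
  list(A = ca_trace(build(chi_A), label = "A"),
       B = ca_trace(build(chi_B), label = "B"))
}

#' Noisy quarter-circle arc cloud
#'
#' 2-D point cloud sampled uniformly along a quarter circle of given radius
#' with isotropic Gaussian noise; a standard fixture for path-clustering
#' algorithms, with the arc endpoints returned separately for pinning.
#'
#' @param n_points number of points.
#' @param noise_sd Gaussian noise standard deviation (same units as radius).
#' @param seed RNG seed.
#' @param radius arc radius (default 10).
#' @return A list with `points` (n x 2), `A`, `B` (endpoints), `radius`, and
#'   `arc_distance(p)` giving each row's distance to the true arc.
#' @export
make_arc_cloud <- function(n_points, noise_sd = 0, seed = 1L, radius = 10) {
  set.seed(seed)
  ang <- sort(runif(n_points, 0, pi / 2))
  pts <- radius * cbind(cos(ang), sin(ang))
  if (noise_sd > 0)
    pts <- pts + matrix(rnorm(2 * n_points, sd = noise_sd), n_points, 2)
  list(points = pts,
       A = c(radius, 0), B = c(0, radius), radius = radius,
       arc_distance = function(p) {
         p <- rbind(p)
         abs(sqrt(rowSums(p^2)) - radius)
       })
}
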