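#' Bond-angle stiffness from the reference rest angle
#'
#' The harmonic-cosine angle term `u = 1/2 k_theta (cos theta - cos theta0)^2`
#' uses a stiffness parameterized by a damped-sinc dependence on the rest
#' angle, `k(theta0) = B (sin(beta theta0) / (beta theta0))^2 + k0`, divided
#' by `sin^2(theta0)` to account for the cosine functional form. With
#' `beta = 1.667` per radian the sinc zero sits near 108 degrees, making the
#' term stiff for helical rest angles (~90 degrees) and soft for strand rest
#' angles (above 110 degrees). Rest angles are clamped to `theta_clamp_deg`
#' (default [5, 175] degrees) to avoid the `1/sin^2` divergence for
#' near-collinear reference geometry.
#'
#' @param theta0 rest angle(s) in radians.
#' @param params an [mcg_params()] object.
#' @return Stiffness `k_theta` in kcal/mol (vectorized).
#' @examples
#' angle_stiffness(pi / 2)       # helix regime, stiff
#' angle_stiffness(120 * pi / 180)  # strand regime, soft
#' @export
angle_stiffness <- function(theta0, params = mcg_params()) {
  lo <- params$theta_clamp_deg[1] * pi / 180
  hi <- params$theta_clamp_deg[2] * pi / 180
  if (any(theta0 < lo | theta0 > hi)) {
    warning("rest angle(s) clamped to [", params$theta_clamp_deg[1], ", ",
            params$theta_clamp_deg[2], "] degrees")
    theta0 <- pmin(hi, pmax(lo, theta0))
  }
  bt <- params$beta * theta0
  k <- params$B * (sin(bt) / bt)^2 + params$k0
  k / sin(theta0)^2
}

#' Dihedral amplitude from the reference rest dihedral
#'
#' Two-level secondary-structure rule: 25 kcal/mol for helical rest dihedrals
#' (|phi0| <= 80 degrees), 5 kcal/mol for strand-like ones (|phi0| > 80
#' degrees). The absolute value is used so that left- and right-handed
#' references are treated alike.
#'
#' @param phi0 rest dihedral(s) in radians, range (-pi, pi].
#' @param params an [mcg_params()] object.
#' @return Amplitude(s) in kcal/mol (vectorized).
#' @export
dihedral_amplitude <- function(phi0, params = mcg_params()) {
  thr <- params$dihedral_threshold * pi / 180
  ifelse(abs(phi0) <= thr, params$A_helix, params$A_strand)
}

#' Local Morse parameters from the reference pair distance
#'
#' Depth and inverse range of the structure-biased local Morse wells decay
#' with the reference distance r0 as
#' `eps = 3.8 exp(-(r0/6.1)^8) + 0.05` kcal/mol and
#' `alpha = 2.2 exp(-(r0/6.1)^8) + 0.70` per Angstrom: short reference
#' distances (H-bond range) give strong short-ranged wells, long ones decay
#' to the generic hydrophobic floor.
#'
#' @param r0 reference distance(s) in Angstrom, `0 < r0 < r_cut`.
#' @param params an [mcg_params()] object.
#' @return A list with vectors `epsilon` (kcal/mol) and `alpha` (1/Angstrom).
#' @export
local_morse_params <- function(r0, params = mcg_params()) {
  if (any(r0 >= params$r_cut))
    stop("r0 >= r_cut (", params$r_cut, " A): pair should be non-local")
  if (any(r0 <= 0)) stop("r0 must be positive")
  decay <- exp(-(r0 / params$local_decay_r)^params$local_decay_exp)
  list(epsilon = params$local_eps_scale * decay + params$local_eps_floor,
       alpha = params$local_alpha_scale * decay + params$local_alpha_floor)
}

#' Morse pair potential
#'
#' `u(r) = eps * ((exp(-alpha (r - r0)) - 1)^2 - 1)`: minimum `-eps` at `r0`,
#' dissociating to 0 at large separation.
#'
#' @param r distance(s), Angstrom.
#' @param epsilon well depth, kcal/mol.
#' @param alpha inverse range, 1/Angstrom.
#' @param r0 minimum location, Angstrom.
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
morse_energy <- function(r, epsilon, alpha, r0) {
  e <- exp(-alpha * (r - r0))
  epsilon * ((e - 1)^2 - 1)
}

#' Compile the biased force-field topology from a reference structure
#'
#' Reads all rest values off the reference C-alpha trace: bond lengths d0,
#' bond angles theta0 (with stiffness from [angle_stiffness()]), dihedrals
#' phi0 (with amplitude from [dihedral_amplitude()]), and classifies every
#' non-bonded pair (|i-j| > 3) as local iff its reference distance is
#' strictly below `r_cut` = 8.5 A (local pairs get structure-specific Morse
#' parameters from [local_morse_params()]; the rest interact through the
#' generic non-local well).
#'
#' @param reference a [ca_trace()] to bias toward.
#' @param params an [mcg_params()] object.
#' @return An object of class `mcg_topology`: list with `bonds` (i, j, d0),
#'   `angles` (i, j, k, theta0, k_theta), `dihedrals` (i, j, k, l, phi0, A),
#'   `local_pairs` (i, j, r0, epsilon, alpha), `nonlocal_pairs` (i, j),
#'   `n_beads`, `reference_label`, `params`.
#' @examples
#' topo <- build_topology(make_helix(30))
#' nrow(topo$local_pairs)
#' @export
build_topology <- function(reference, params = mcg_params()) {
  x <- coords_of(reference)
  n <- nrow(x)
  ic <- compute_internal_coords(x)
  bonds <- cbind(i = 1:(n - 1), j = 2:n, d0 = ic$bond_lengths)
  angles <- cbind(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
                  theta0 = ic$bond_angles,
                  k_theta = angle_stiffness(ic$bond_angles, params))
  dihedrals <- cbind(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1), l = 4:n,
                     phi0 = ic$dihedrals,
                     A = dihedral_amplitude(ic$dihedrals, params))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- pr[pr[, 2] - pr[, 1] > 3L, , drop = FALSE]
  d <- sqrt(rowSums((x[pr[, 1], , drop = FALSE] - x[pr[, 2], , drop = FALSE])^2))
  loc <- d < params$r_cut
  lp <- local_morse_params(d[loc], params)
  structure(list(
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    local_pairs = cbind(i = pr[loc, 1], j = pr[loc, 2], r0 = d[loc],
                        epsilon = lp$epsilon, alpha = lp$alpha),
    nonlocal_pairs = cbind(i = pr[!loc, 1], j = pr[!loc, 2]),
    n_beads = n,
    reference_label = if (inherits(reference, "ca_trace")) reference$label else "",
    params = params), class = "mcg_topology")
}

#' @export
print.mcg_topology <- function(x, ...) {
  cat(sprintf(paste0("<mcg_topology> %d beads%s: %d bonds, %d angles, ",
                     "%d dihedrals, %d local + %d non-local pairs\n"),
              x$n_beads,
              if (nzchar(x$reference_label))
                paste0(" (bias \"", x$reference_label, "\")") else "",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$local_pairs), nrow(x$nonlocal_pairs)))
  invisible(x)
}

#' Potential energy of a conformation under a biased topology
#'
#' Evaluates the per-term energies: angle `sum 1/2 k (cos t - cos t0)^2`,
#' dihedral `sum A (1 - cos(p - p0))`, local and non-local Morse sums (the
#' non-local sum truncated and shifted to zero at `nl_eval_cutoff`, 25 A),
#' and the bond restraint bookkeeping term `bond_penalty` (harmonic
#' `1/2 k (d - d0)^2` with `harmonic_k`; zero when bonds are treated as
#' exact holonomic constraints).
#'
#' @param coords N x 3 matrix or `ca_trace`.
#' @param topology an [build_topology()] result.
#' @param harmonic_k bond restraint stiffness, kcal/(mol A^2); 0 means
#'   constraint bookkeeping (term reported as 0).
#' @return Named numeric vector: `bond_penalty`, `angle`, `dihedral`,
#'   `local`, `nonlocal`, `total` (kcal/mol).
#' @examples
#' h <- make_helix(20); topo <- build_topology(h)
#' mcg_energy(h, topo)["angle"]   # zero at the reference
#' @export
mcg_energy <- function(coords, topology, harmonic_k = 0) {
  x <- coords_of(coords)
  if (nrow(x) != topology$n_beads)
    stop("coords have ", nrow(x), " beads, topology expects ", topology$n_beads)
  e <- mcg_energy_cpp(x, topology_cpp(topology), harmonic_k,
                      topology$params$nl_r0, topology$params$nl_eps,
                      topology$params$nl_alpha, topology$params$nl_eval_cutoff)
  setNames(as.numeric(e), c("bond_penalty", "angle", "dihedral", "local",
                            "nonlocal", "total"))
}

#' Analytic forces of the biased force field
#'
#' Negative gradient of [mcg_energy()] for all differentiable terms (angle,
#' dihedral, local/non-local Morse, and the harmonic bond restraint when
#' `harmonic_k > 0`).
#'
#' @inheritParams mcg_energy
#' @return N x 3 matrix of forces in kcal/(mol Angstrom).
#' @export
mcg_forces <- function(coords, topology, harmonic_k = 0) {
  x <- coords_of(coords)
  if (nrow(x) != topology$n_beads)
    stop("coords have ", nrow(x), " beads, topology expects ", topology$n_beads)
  mcg_forces_cpp(x, topology_cpp(topology), harmonic_k,
                 topology$params$nl_r0, topology$params$nl_eps,
                 topology$params$nl_alpha, topology$params$nl_eval_cutoff)
}

# 0-based integer/double matrices handed to the compiled core
topology_cpp <- function(topo) {
  list(bonds = unname(cbind(topo$bonds[, 1:2, drop = FALSE] - 1,
                            topo$bonds[, 3, drop = FALSE])),
       angles = unname(cbind(topo$angles[, 1:3, drop = FALSE] - 1,
                             topo$angles[, 4:5, drop = FALSE])),
       dihedrals = unname(cbind(topo$dihedrals[, 1:4, drop = FALSE] - 1,
                                topo$dihedrals[, 5:6, drop = FALSE])),
       local_pairs = unname(cbind(topo$local_pairs[, 1:2, drop = FALSE] - 1,
                                  topo$local_pairs[, 3:5, drop = FALSE])),
       nonlocal_pairs = unname(topo$nonlocal_pairs - 1))
}

#' Serialize / deserialize a topology as JSON
#'
#' Writes the complete compiled term lists (with parameters) to a documented
#' JSON file for reproducibility, and reads them back.
#'
#' @param topology an `mcg_topology`.
#' @param path file path.
#' @return `write_topology_json` returns `path` invisibly;
#'   `read_topology_json` returns an `mcg_topology`.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    n_beads = topology$n_beads,
    reference_label = topology$reference_label,
    params = unclass(topology$params),
    bonds = as.data.frame(topology$bonds),
    angles = as.data.frame(topology$angles),
    dihedrals = as.data.frame(topology$dihedrals),
    local_pairs = as.data.frame(topology$local_pairs),
    nonlocal_pairs = as.data.frame(topology$nonlocal_pairs))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  clamp <- unlist(p$theta_clamp_deg)
  p$theta_clamp_deg <- NULL
  params <- do.call(mcg_params, c(p, list(theta_clamp_deg = clamp)))
  as_mat <- function(df) {
    m <- as.matrix(df)
    rownames(m) <- NULL
    m
  }
  structure(list(bonds = as_mat(obj$bonds), angles = as_mat(obj$angles),
                 dihedrals = as_mat(obj$dihedrals),
                 local_pairs = as_mat(obj$local_pairs),
                 nonlocal_pairs = as_mat(obj$nonlocal_pairs),
                 n_beads = obj$n_beads, reference_label = obj$reference_label,
                 params = params), class = "mcg_topology")
}
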