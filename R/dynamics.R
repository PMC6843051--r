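#' Langevin dynamics simulation configuration
#'
#' Holds the protocol parameters for [run_ld()]. Defaults follow the model's
#' standard protocol: 0.01 ps timestep and an average dump rate of 0.1 per ps
#' (one frame every 10 ps). Bonds are treated as holonomic constraints by
#' default (SHAKE, tolerance 1e-8 A); a stiff-harmonic restraint mode is
#' available (100 kcal/(mol A^2)), useful when an exact conserved energy is
#' wanted (e.g. microcanonical checks at `gamma = 0`).
#'
#' @param dt timestep in ps.
#' @param temperature thermostat target in K.
#' @param gamma friction in 1/ps (0 disables the thermostat: NVE limit).
#' @param n_steps number of integration steps (>= 1).
#' @param dump_interval_steps frames are stored every this many steps.
#' @param seed integer RNG seed (velocities and thermostat noise).
#' @param mass_mode `"uniform"` (110 amu per bead, the average residue mass)
#'   or `"per_residue"` (standard residue masses from the trace).
#' @param bond_mode `"constraint"` or `"harmonic"`.
#' @param harmonic_k bond restraint stiffness, kcal/(mol A^2) (harmonic mode).
#' @param constraint_tol SHAKE tolerance in Angstrom.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, temperature = 300, gamma = 8,
                       n_steps = 1000L, dump_interval_steps = 1000L,
                       seed = 1L, mass_mode = c("uniform", "per_residue"),
                       bond_mode = c("constraint", "harmonic"),
                       harmonic_k = 100, constraint_tol = 1e-8) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0, constraint_tol > 0)
  if (n_steps < 1) stop("n_steps must be >= 1")
  dump_interval_steps <- max(1L, min(as.integer(dump_interval_steps),
                                     as.integer(n_steps)))
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 n_steps = as.integer(n_steps),
                 dump_interval_steps = dump_interval_steps,
                 seed = as.integer(seed),
                 mass_mode = match.arg(mass_mode),
                 bond_mode = match.arg(bond_mode),
                 harmonic_k = harmonic_k, constraint_tol = constraint_tol),
            class = "sim_config")
}

# average amino-acid residue masses (amu) for per_residue mode
.residue_mass <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)

bead_masses <- function(trace, mass_mode) {
  n <- n_beads(trace)
  if (mass_mode == "uniform" || !inherits(trace, "ca_trace"))
    return(rep(110, n))
  m <- .residue_mass[trace$residue_names]
  m[is.na(m)] <- 110
  unname(m)
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities from the Maxwell-Boltzmann distribution at the requested
#' temperature and removes the center-of-mass momentum. Reproducible for a
#' given seed.
#'
#' @param n_beads number of beads.
#' @param masses bead masses in amu (length 1 or `n_beads`).
#' @param temperature in K (0 gives all-zero velocities).
#' @param seed integer seed.
#' @return N x 3 matrix of velocities in Angstrom/ps.
#' @export
initialize_velocities <- function(n_beads, masses = 110, temperature = 300,
                                  seed = 1L) {
  stopifnot(temperature >= 0)
  masses <- rep_len(masses, n_beads)
  if (temperature == 0) return(matrix(0, n_beads, 3))
  kbT_int <- .kB * .KCAL_TO_INT * temperature  # amu A^2/ps^2
  set.seed(seed)
  v <- matrix(rnorm(3 * n_beads), n_beads, 3) * sqrt(kbT_int / masses)
  p <- colSums(v * masses)
  sweep(v, 2, p / sum(masses))
}

#' Run Langevin dynamics of the coarse-grained chain
#'
#' Integrates the Langevin equation with the BAOAB splitting under the biased
#' force field compiled in `topology`. Bond lengths are maintained at their
#' reference values either as holonomic constraints (SHAKE positions, RATTLE
#' velocity projection) or as stiff harmonic restraints. Per-term energies,
#' kinetic energy and instantaneous kinetic temperature are recorded at each
#' dumped frame (the instantaneous temperature accounts for the constrained
#' degrees of freedom).
#'
#' @param initial a [ca_trace()] (or N x 3 matrix) with the starting
#'   conformation; bead count must match the topology.
#' @param topology an [build_topology()] result (possibly biased to a
#'   different reference than `initial` — see [transition_run()]).
#' @param config a [sim_config()].
#' @param velocities optional initial velocities (default: Maxwell-Boltzmann
#'   at the target temperature with the config seed).
#' @return An object of class `mcg_trajectory`: list with `times` (ps),
#'   `frames` (list of N x 3 matrices), `energies` (tibble: time_ps,
#'   E_bond_penalty, E_angle, E_dihedral, E_local, E_nonlocal, E_pot, E_kin,
#'   T_inst), `config`, `topology_label`, `final_velocities`.
#' @examples
#' h <- make_helix(10)
#' traj <- run_ld(h, build_topology(h), sim_config(n_steps = 100,
#'   dump_interval_steps = 50, temperature = 200))
#' traj$energies
#' @export
run_ld <- function(initial, topology, config = sim_config(),
                   velocities = NULL) {
  x0 <- coords_of(initial)
  n <- nrow(x0)
  if (n != topology$n_beads)
    stop("initial conformation has ", n, " beads, topology expects ",
         topology$n_beads)
  masses <- bead_masses(initial, config$mass_mode)
  if (is.null(velocities))
    velocities <- initialize_velocities(n, masses, config$temperature,
                                        config$seed)
  # constraint mode: start exactly on the constraint manifold
  dof <- if (config$bond_mode == "constraint") 3L * n - (n - 1L) else 3L * n
  p <- topology$params
  res <- run_ld_cpp(x0, velocities, topology_cpp(topology), masses,
                    config$dt, config$gamma, config$temperature,
                    config$n_steps, config$dump_interval_steps,
                    config$seed + 1L,
                    if (config$bond_mode == "constraint") 0L else 1L,
                    config$harmonic_k, config$constraint_tol,
                    p$nl_r0, p$nl_eps, p$nl_alpha, p$nl_eval_cutoff, dof)
  en <- res$energies
  energies <- tibble::tibble(
    time_ps = as.numeric(res$times),
    E_bond_penalty = en[, 1], E_angle = en[, 2], E_dihedral = en[, 3],
    E_local = en[, 4], E_nonlocal = en[, 5], E_pot = en[, 6],
    E_kin = as.numeric(res$ekin), T_inst = as.numeric(res$tinst))
  structure(list(times = as.numeric(res$times), frames = res$frames,
                 energies = energies, config = config,
                 topology_label = topology$reference_label,
                 final_velocities = res$velocities),
            class = "mcg_trajectory")
}

#' @export
print.mcg_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<mcg_trajectory> %d frames, %d beads, %.4g ps%s\n",
                     "  mean T = %.1f K, mean E_pot = %.2f kcal/mol\n"),
              length(x$frames), nrow(x$frames[[1]]),
              max(x$times),
              if (nzchar(x$topology_label))
                paste0(", FF bias \"", x$topology_label, "\"") else "",
              mean(x$energies$T_inst[-1]), mean(x$energies$E_pot)))
  invisible(x)
}

#' Simulate a conformational transition under the opposite-state bias
#'
#' Convenience wrapper for the dual-bias transition protocol: a simulation
#' started from one reference state under the force field biased toward the
#' other reference, so the run relaxes across the transition (e.g. start in
#' the closed state under the open-state force field).
#'
#' @param start a [ca_trace()] with the starting state.
#' @param target_topology topology biased toward the *other* state; bead
#'   count must match `start`.
#' @param config a [sim_config()].
#' @return An `mcg_trajectory` (labeled with the bias reference).
#' @export
transition_run <- function(start, target_topology, config = sim_config()) {
  if (n_beads(start) != target_topology$n_beads)
    stop("start state and bias reference have different bead counts")
  run_ld(start, target_topology, config)
}
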