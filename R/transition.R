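#' Transition-progress coordinate sigma
#'
#' For a query conformation r and two reference states A and B,
#' `sigma(r) = 1/2 (RMSD_A(r) - RMSD_B(r)) / RMSD_AB + 1/2`, with each RMSD
#' computed after an independent optimal (Kabsch) superposition onto its
#' reference, and `RMSD_AB` the superposed RMSD between the references.
#' sigma is 0 in state A and 1 in state B, and is deliberately not clipped:
#' conformations farther from one state than the opposite reference can fall
#' slightly outside [0, 1].
#'
#' @param coords query conformation (N x 3 matrix or `ca_trace`).
#' @param ref_A,ref_B the two reference states, same bead count as `coords`.
#' @return A list with `rmsd_A`, `rmsd_B` (Angstrom), `sigma`, `rmsd_AB`.
#' @examples
#' hp <- make_hinge_pair(40, 30, 120)
#' sigma_of(hp$A, hp$A, hp$B)$sigma   # 0
#' sigma_of(hp$B, hp$A, hp$B)$sigma   # 1
#' @export
sigma_of <- function(coords, ref_A, ref_B) {
  a <- coords_of(ref_A); b <- coords_of(ref_B)
  rmsd_ab <- kabsch_superpose(a, b)$rmsd
  if (rmsd_ab < 1e-9)
    stop("reference states A and B are identical (RMSD_AB = 0): ",
         "sigma is undefined")
  ra <- kabsch_superpose(coords, a)$rmsd
  rb <- kabsch_superpose(coords, b)$rmsd
  list(rmsd_A = ra, rmsd_B = rb,
       sigma = 0.5 * (ra - rb) / rmsd_ab + 0.5, rmsd_AB = rmsd_ab)
}

#' Per-frame RMSD / sigma table of a trajectory
#'
#' Computes RMSD to both references and the sigma progress coordinate for
#' every frame — the data behind RMSD_B-vs-RMSD_A transition scatter plots.
#'
#' @param traj an `mcg_trajectory`, or a list of N x 3 frames.
#' @param ref_A,ref_B reference states.
#' @return A tibble of class `transition_record` with columns `frame`,
#'   `time_ps`, `rmsd_A`, `rmsd_B`, `sigma`, and `E_pot` when energies are
#'   available; `rmsd_AB` is stored as an attribute.
#' @export
scatter_table <- function(traj, ref_A, ref_B) {
  if (inherits(traj, "mcg_trajectory")) {
    frames <- traj$frames
    times <- traj$times
    epot <- traj$energies$E_pot
  } else {
    frames <- if (is.list(traj)) traj else list(coords_of(traj))
    times <- seq_along(frames) - 1
    epot <- rep(NA_real_, length(frames))
  }
  res <- lapply(frames, sigma_of, ref_A = ref_A, ref_B = ref_B)
  out <- tibble::tibble(
    frame = seq_along(frames),
    time_ps = times,
    rmsd_A = vapply(res, `[[`, numeric(1), "rmsd_A"),
    rmsd_B = vapply(res, `[[`, numeric(1), "rmsd_B"),
    sigma = vapply(res, `[[`, numeric(1), "sigma"),
    E_pot = epot)
  attr(out, "rmsd_AB") <- res[[1]]$rmsd_AB
  class(out) <- c("transition_record", class(out))
  out
}

#' sigma-binned potential-energy profile
#'
#' Groups frames into regular sigma intervals spanning the observed sigma
#' range and reports the per-bin mean potential energy, sample standard
#' deviation and count. The last bin is right-closed so the frame at
#' `max(sigma)` is counted. Empty bins are kept (count 0, mean NA), never
#' interpolated.
#'
#' @param records a `transition_record` tibble (from [scatter_table()]) or a
#'   numeric vector of sigma values.
#' @param energies per-frame potential energies; defaults to the `E_pot`
#'   column of `records`.
#' @param n_bins number of regular sigma intervals (>= 2; default 20).
#' @param ff_label optional label of the force field the energies come from.
#' @return A tibble of class `energy_profile` with columns `bin_lo`,
#'   `bin_hi`, `sigma_mid`, `mean`, `sd`, `n`.
#' @export
bin_by_sigma <- function(records, energies = NULL, n_bins = 20,
                         ff_label = "") {
  sigma <- if (is.data.frame(records)) records$sigma else as.numeric(records)
  if (is.null(energies)) {
    if (is.data.frame(records) && "E_pot" %in% names(records))
      energies <- records$E_pot
    else stop("energies must be supplied")
  }
  if (length(sigma) == 0L) stop("empty input")
  if (length(sigma) != length(energies))
    stop("records and energies have different lengths")
  if (n_bins < 2) stop("n_bins must be >= 2")
  lo <- min(sigma); hi <- max(sigma)
  if (hi - lo < 1e-12) hi <- lo + 1e-12
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(n_bins, findInterval(sigma, edges, rightmost.closed = TRUE))
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    sigma_mid = (edges[-length(edges)] + edges[-1]) / 2,
    mean = vapply(seq_len(n_bins), function(b) {
      e <- energies[idx == b]
      if (length(e)) mean(e) else NA_real_
    }, numeric(1)),
    sd = vapply(seq_len(n_bins), function(b) {
      e <- energies[idx == b]
      if (length(e) > 1) stats::sd(e) else if (length(e) == 1) 0 else NA_real_
    }, numeric(1)),
    n = vapply(seq_len(n_bins), function(b) sum(idx == b), integer(1)))
  attr(out, "ff_label") <- ff_label
  class(out) <- c("energy_profile", class(out))
  out
}

#' Align the energy scales of two biased force fields
#'
#' Potential energies from two differently biased force fields have no common
#' zero. The two sigma-binned profiles are aligned by matching their means in
#' the bin containing a chosen sigma value `sigma_star` — picked where the
#' trajectories from the two force fields come closest in conformation space
#' (around sigma = 0.4 for the dual-bias transition protocol), so that
#' similar structures are assigned similar energies.
#'
#' @param profile_A,profile_B [bin_by_sigma()] profiles from the two force
#'   fields.
#' @param sigma_star sigma value at which the scales are matched.
#' @return The additive shift (kcal/mol) to apply to `profile_B` energies so
#'   the two profiles agree at the `sigma_star` bin.
#' @export
align_energy_scales <- function(profile_A, profile_B, sigma_star = 0.4) {
  pick <- function(prof, who) {
    b <- which(sigma_star >= prof$bin_lo & sigma_star <= prof$bin_hi)
    b <- b[prof$n[b] > 0]
    if (!length(b))
      stop("profile ", who, " has no populated bin containing sigma = ",
           sigma_star, "; choose a different sigma_star")
    prof$mean[b[1]]
  }
  pick(profile_A, "A") - pick(profile_B, "B")
}
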