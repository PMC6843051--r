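#' Tidy the per-frame record of a trajectory
#'
#' @param x an `mcg_trajectory`.
#' @param ... unused.
#' @return The per-frame energy/temperature tibble.
#' @export
tidy.mcg_trajectory <- function(x, ...) x$energies

#' One-row summary of a trajectory
#'
#' @param x an `mcg_trajectory`.
#' @param burn_in_ps frames before this time are excluded from the averages.
#' @param ... unused.
#' @return A one-row tibble: frame/bead counts, simulated time, mean and
#'   standard error of the kinetic temperature, mean potential energy.
#' @export
glance.mcg_trajectory <- function(x, burn_in_ps = 0, ...) {
  e <- x$energies[x$energies$time_ps > burn_in_ps, ]
  tibble::tibble(
    n_frames = length(x$frames),
    n_beads = nrow(x$frames[[1]]),
    time_ps = max(x$times),
    mean_T = mean(e$T_inst),
    se_T = stats::sd(e$T_inst) / sqrt(nrow(e)),
    mean_E_pot = mean(e$E_pot),
    ff_label = x$topology_label)
}

#' Tidy a fitted principal path
#'
#' @param x a `principal_path`.
#' @param ... unused.
#' @return A tibble with one row per representative: index, assigned sample
#'   count, and distance to the previous representative.
#' @export
tidy.principal_path <- function(x, ...) {
  K <- nrow(x$W)
  tibble::tibble(
    representative = seq_len(K),
    n_assigned = x$counts,
    step_length = c(NA_real_, sqrt(rowSums(diff(x$W)^2))))
}

#' One-row summary of a fitted principal path
#'
#' @param x a `principal_path`.
#' @param ... unused.
#' @return A one-row tibble: K, s, final cost, iterations, convergence flag.
#' @export
glance.principal_path <- function(x, ...) {
  tibble::tibble(K = nrow(x$W), s = x$s, cost = x$cost,
                 n_iter = length(x$cost_history), converged = x$converged)
}

#' @export
autoplot.mcg_trajectory <- function(object, ...) {
  e <- object$energies
  df <- tibble::tibble(
    time_ps = rep(e$time_ps, 3),
    value = c(e$T_inst, e$E_pot, e$E_pot + e$E_kin),
    what = rep(c("T_inst (K)", "E_pot (kcal/mol)", "E_tot (kcal/mol)"),
               each = nrow(e)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ps, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ps)", y = NULL)
}

#' @export
autoplot.energy_profile <- function(object, ...) {
  df <- object[object$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma_mid, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(sigma), y = "potential energy (kcal/mol)")
}

#' @export
autoplot.principal_path <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$cost_history),
                       cost = object$cost_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "principal-path cost")
}

#' RMSD transition scatter plot
#'
#' RMSD to state B against RMSD to state A for every frame, colored by the
#' sigma progress coordinate; the references sit at (0, RMSD_AB) and
#' (RMSD_AB, 0).
#'
#' @param records a `transition_record` from [scatter_table()].
#' @return A ggplot object.
#' @export
plot_rmsd_scatter <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$rmsd_A, y = .data$rmsd_B,
                                        color = .data$sigma)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = expression(RMSD[A] ~ (ring(A))),
                  y = expression(RMSD[B] ~ (ring(A)))) +
    ggplot2::coord_equal()
}

#' @importFrom ggplot2 .data
NULL
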