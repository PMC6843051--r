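#' Force-field parameter set of the minimalist coarse-grained (MCG) model
#'
#' Returns the constants of the biased C-alpha force field. The bonded terms
#' are parameterized from the reference structure: the bond-angle stiffness
#' follows a damped-sinc dependence on the rest angle (strong for helical
#' angles near 90 degrees, soft for extended strands above 110 degrees), the
#' dihedral amplitude is a two-level rule splitting helices from strands at
#' 80 degrees, and non-bonded pairs are Morse wells whose depth and range decay
#' with the reference distance. Pairs beyond `r_cut` in the reference structure
#' interact through a single generic hydrophobic Morse well.
#'
#' @param ... named overrides of any default constant.
#'
#' @return An object of class `mcg_params`: a named list with elements
#'   `B`, `k0` (kcal/mol), `beta` (1/rad), `A_helix`, `A_strand` (kcal/mol),
#'   `dihedral_threshold` (degrees), `r_cut` (Angstrom),
#'   `local_eps_scale` (kcal/mol), `local_alpha_scale` (1/Angstrom),
#'   `local_decay_r` (Angstrom), `local_decay_exp`, `local_eps_floor`,
#'   `local_alpha_floor`, `nl_r0` (Angstrom), `nl_eps` (kcal/mol),
#'   `nl_alpha` (1/Angstrom), `nl_eval_cutoff` (Angstrom),
#'   `theta_clamp_deg` (degrees).
#' @examples
#' p <- mcg_params()
#' p$r_cut
#' mcg_params(r_cut = 9)$r_cut
#' @export
mcg_params <- function(...) {
  p <- list(
    B = 3000, k0 = 10, beta = 1.667,
    A_helix = 25, A_strand = 5, dihedral_threshold = 80,
    r_cut = 8.5,
    local_eps_scale = 3.8, local_alpha_scale = 2.2,
    local_decay_r = 6.1, local_decay_exp = 8,
    local_eps_floor = 0.05, local_alpha_floor = 0.70,
    nl_r0 = 9.5, nl_eps = 0.05, nl_alpha = 0.70,
    nl_eval_cutoff = 25,
    theta_clamp_deg = c(5, 175)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  num <- p[setdiff(names(p), "theta_clamp_deg")]
  if (any(vapply(num, function(x) !is.numeric(x) || any(x <= 0), logical(1))))
    stop("all mcg_params constants must be positive numbers")
  structure(p, class = "mcg_params")
}

#' @export
print.mcg_params <- function(x, ...) {
  cat("<mcg_params> minimalist coarse-grained force field constants\n")
  cat(sprintf("  angle: B = %g, k0 = %g kcal/mol, beta = %g rad^-1\n",
              x$B, x$k0, x$beta))
  cat(sprintf("  dihedral: A = %g (helix) / %g (strand) kcal/mol, threshold %g deg\n",
              x$A_helix, x$A_strand, x$dihedral_threshold))
  cat(sprintf("  local Morse: eps = %g exp(-(r0/%g)^%g) + %g kcal/mol, r_cut = %g A\n",
              x$local_eps_scale, x$local_decay_r, x$local_decay_exp,
              x$local_eps_floor, x$r_cut))
  cat(sprintf("  non-local Morse: r0 = %g A, eps = %g kcal/mol, alpha = %g A^-1\n",
              x$nl_r0, x$nl_eps, x$nl_alpha))
  invisible(x)
}
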