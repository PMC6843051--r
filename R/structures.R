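#' Construct a C-alpha trace
#'
#' The universal structural container of the package: one chain reduced to its
#' ordered C-alpha positions. Consecutive C-alpha distances are validated
#' against the physical virtual-bond range (about 3.8 Angstrom for a trans
#' peptide): distances outside [2.5, 4.5] A raise a warning, distances above
#' 6 A indicate a chain break and are an error.
#'
#' @param coords numeric N x 3 matrix of positions (Angstrom).
#' @param residue_ids integer residue numbers (default `1:N`).
#' @param residue_names 3-letter residue codes (default `"GLY"`).
#' @param label free-text label, e.g. `"A"` or `"B"`.
#'
#' @return An object of class `ca_trace` with fields `coords`, `residue_ids`,
#'   `residue_names`, `label`.
#' @examples
#' tr <- ca_trace(cbind(3.8 * (0:4), 0, 0))
#' tr$coords
#' @export
ca_trace <- function(coords, residue_ids = NULL, residue_names = NULL,
                     label = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 4L) stop("a ca_trace needs at least 4 residues, got ", n)
  if (!all(is.finite(coords))) stop("non-finite coordinates in ca_trace")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (is.null(residue_names)) residue_names <- rep("GLY", n)
  if (length(residue_ids) != n || length(residue_names) != n)
    stop("residue_ids / residue_names length must match number of residues")
  d <- sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE])^2))
  if (any(d > 6))
    stop("chain break: C-alpha to C-alpha distance ", format(max(d), digits = 4),
         " A > 6 A after residue index ", which(d > 6)[1])
  if (any(d < 2.5 | d > 4.5))
    warning("C-alpha spacing outside [2.5, 4.5] A at bond(s) ",
            paste(utils::head(which(d < 2.5 | d > 4.5), 5), collapse = ", "))
  structure(list(residue_ids = as.integer(residue_ids),
                 residue_names = as.character(residue_names),
                 coords = coords, label = label),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d residues%s\n", nrow(x$coords),
              if (nzchar(x$label)) paste0(", label \"", x$label, "\"") else ""))
  invisible(x)
}

#' Number of beads in a trace or coordinate matrix
#' @param x a `ca_trace` or an N x 3 matrix.
#' @return integer bead count.
#' @export
n_beads <- function(x) nrow(coords_of(x))

coords_of <- function(x) {
  if (inherits(x, "ca_trace")) x$coords else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts the C-alpha atoms of one chain from a PDB file (via
#' [bio3d::read.pdb()]). Alternate locations are resolved by keeping the
#' highest-occupancy record per residue; only ATOM records with atom name
#' `CA` are used.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @param model_index which MODEL to use for multi-model files (default 1).
#'
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(pdb_source, chain = NULL, model_index = 1L) {
  path <- pdb_source
  if (length(pdb_source) > 1L || grepl("\n", pdb_source[1]) ||
      !file.exists(pdb_source[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb_source, "\n", fixed = TRUE)), path)
    on.exit(unlink(path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$.pos <- seq_len(nrow(at))           # positional index into pdb$xyz
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", path)
  chains <- unique(ca$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    stop("chain \"", chain, "\" not found; available chain(s): ",
         paste(chains, collapse = ", "))
  ca <- ca[ca$chain == chain, , drop = FALSE]
  # altloc: keep the highest-occupancy CA per residue, first on ties
  if (any(!is.na(ca$alt) & ca$alt != "")) {
    keep <- unlist(lapply(split(seq_len(nrow(ca)), ca$resno), function(ix) {
      occ <- ca$o[ix]
      occ[is.na(occ)] <- 1
      ix[which.max(occ)]
    }))
    ca <- ca[sort(keep), , drop = FALSE]
  }
  if (nrow(ca) < 4L) stop("fewer than 4 C-alpha atoms in chain ", chain)
  nmodel <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > nmodel)
    stop("model_index ", model_index, " out of range (file has ", nmodel,
         " model(s))")
  xyz_idx <- bio3d::atom2xyz(ca$.pos)
  xyz <- matrix(pdb$xyz[model_index, xyz_idx], ncol = 3, byrow = TRUE)
  # chain break: gap in numbering AND broken geometry
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  gap <- diff(ca$resno) != 1L
  if (any(gap & d > 6))
    stop("chain break in chain ", chain, " after residue ",
         ca$resno[which(gap & d > 6)[1]],
         " (residue-number gap and C-alpha distance > 6 A)")
  ca_trace(xyz, residue_ids = ca$resno, residue_names = ca$resid,
           label = chain)
}

#' Internal coordinates of a C-alpha trace
#'
#' Computes the virtual-bond lengths d_i (N-1), the pseudo bond angles theta_i
#' over consecutive triples (N-2, radians), and the signed pseudo-dihedrals
#' phi_i over consecutive quadruples (N-3, radians, right-hand IUPAC
#' convention, range (-pi, pi]). Together (theta, phi) encode secondary
#' structure in a C-alpha-only chain.
#'
#' @param trace a [ca_trace()] or an N x 3 coordinate matrix.
#' @return A list of class `internal_coords` with `bond_lengths`,
#'   `bond_angles`, `dihedrals`.
#' @examples
#' ic <- compute_internal_coords(make_helix(10))
#' range(ic$bond_angles) * 180 / pi
#' @export
compute_internal_coords <- function(trace) {
  x <- coords_of(trace)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 beads")
  b <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]   # bond vectors
  d <- sqrt(rowSums(b^2))
  # angles at beads 2..n-1 between -b[i] and b[i+1] reversed: use u=-b_i, v=b_{i+1}
  u <- -b[-(n - 1L), , drop = FALSE]
  v <- b[-1L, , drop = FALSE]
  ct <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  theta <- acos(pmin(1, pmax(-1, ct)))
  # dihedrals over quadruples
  nb <- n - 1L
  phi <- numeric(n - 3L)
  for (i in seq_len(n - 3L)) {
    b1 <- b[i, ]; b2 <- b[i + 1L, ]; b3 <- b[i + 2L, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14)
      stop("dihedral undefined: collinear consecutive beads near index ", i)
    m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
    phi[i] <- atan2(-sum(m1 * n2), sum(n1 * n2))
  }
  phi[phi <= -pi + 1e-15] <- pi  # range (-pi, pi]
  structure(list(bond_lengths = d, bond_angles = theta, dihedrals = phi),
            class = "internal_coords")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a chain from internal coordinates
#'
#' Inverse of [compute_internal_coords()]: places beads sequentially from bond
#' lengths, bond angles and dihedrals (NeRF construction). The first three
#' beads are placed in the xy-plane.
#'
#' @param bond_lengths N-1 lengths (Angstrom).
#' @param bond_angles N-2 angles (radians).
#' @param dihedrals N-3 signed dihedrals (radians).
#' @return N x 3 coordinate matrix.
#' @export
build_from_internal <- function(bond_lengths, bond_angles, dihedrals) {
  n <- length(bond_lengths) + 1L
  stopifnot(length(bond_angles) == n - 2L, length(dihedrals) == n - 3L)
  x <- matrix(0, n, 3)
  x[2, ] <- c(bond_lengths[1], 0, 0)
  x[3, ] <- x[2, ] + bond_lengths[2] *
    c(-cos(bond_angles[1]), sin(bond_angles[1]), 0)
  for (i in 4:n) {
    a <- x[i - 3L, ]; b2 <- x[i - 2L, ]; c2 <- x[i - 1L, ]
    r <- bond_lengths[i - 1L]
    th <- bond_angles[i - 2L]; ph <- dihedrals[i - 3L]
    bc <- c2 - b2; bc <- bc / sqrt(sum(bc^2))
    nv <- cross3(b2 - a, bc)
    nv <- nv / sqrt(sum(nv^2))
    mv <- cross3(nv, bc)
    d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    x[i, ] <- c2 + d2[1] * bc + d2[2] * mv + d2[3] * nv
  }
  x
}

#' Kabsch rigid-body superposition
#'
#' Least-RMSD superposition of `mobile` onto `reference` by the Kabsch
#' algorithm (SVD of the covariance with determinant correction, so only
#' proper rotations are returned and chirality is preserved).
#'
#' @param mobile,reference N x 3 coordinate matrices (or `ca_trace`), equal N,
#'   N >= 3.
#' @return A list with `aligned` (mobile after superposition), `rotation`
#'   (3 x 3, applied as `x %*% rotation`), `translation` (length-3), and
#'   `rmsd` = sqrt(mean over beads of squared 3-D deviation) in Angstrom.
#' @examples
#' a <- make_helix(10)$coords
#' kabsch_superpose(a + 5, a)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  p <- coords_of(mobile); q <- coords_of(reference)
  if (nrow(p) != nrow(q)) stop("mobile and reference must have equal bead counts")
  if (nrow(p) < 3L) stop("need at least 3 points")
  cp <- colMeans(p); cq <- colMeans(q)
  pm <- sweep(p, 2, cp); qm <- sweep(q, 2, cq)
  h <- crossprod(pm, qm)                 # 3x3 covariance
  sv <- svd(h)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)  # applied as pm %*% rot
  aligned <- pm %*% rot
  rmsd <- sqrt(mean(rowSums((aligned - qm)^2)))
  translation <- cq - drop(cp %*% rot)
  list(aligned = sweep(aligned, 2, cq, "+"), rotation = rot,
       translation = translation, rmsd = rmsd)
}

#' Root-mean-square deviation after optimal superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_after_fit <- function(mobile, reference)
  kabsch_superpose(mobile, reference)$rmsd
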