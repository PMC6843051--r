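# Shared fixtures and independent oracles for the suite.

# Minimal PDB text for a C-alpha-only chain; coords is N x 3.
pdb_text <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                     altloc = rep("", nrow(coords)),
                     occ = rep(1, nrow(coords))) {
  sprintf("ATOM  %5d  CA %1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          seq_len(nrow(coords)), altloc, "GLY", chain, resno,
          coords[, 1], coords[, 2], coords[, 3], occ)
}

# Independent superposition oracle: Horn's quaternion method. The optimal
# RMSD is sqrt((Sp + Sq - 2 lambda_max) / N) with lambda_max the largest
# eigenvalue of the 4x4 quaternion matrix of the covariance.
quaternion_rmsd <- function(p, q) {
  p <- sweep(p, 2, colMeans(p)); q <- sweep(q, 2, colMeans(q))
  m <- crossprod(p, q)
  sxx <- m[1,1]; sxy <- m[1,2]; sxz <- m[1,3]
  syx <- m[2,1]; syy <- m[2,2]; syz <- m[2,3]
  szx <- m[3,1]; szy <- m[3,2]; szz <- m[3,3]
  K <- matrix(c(
    sxx+syy+szz, syz-szy,      szx-sxz,      sxy-syx,
    syz-szy,     sxx-syy-szz,  sxy+syx,      szx+sxz,
    szx-sxz,     sxy+syx,     -sxx+syy-szz,  syz+szy,
    sxy-syx,     szx+sxz,      syz+szy,     -sxx-syy+szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(0, msd))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_res)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# central finite-difference force oracle
fd_forces <- function(coords, topology, harmonic_k = 0, h = 1e-5) {
  f <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    xp <- coords; xp[i, k] <- xp[i, k] + h
    xm <- coords; xm[i, k] <- xm[i, k] - h
    f[i, k] <- -(mcg_energy(xp, topology, harmonic_k)[["total"]] -
                 mcg_energy(xm, topology, harmonic_k)[["total"]]) / (2 * h)
  }
  f
}

# a mildly perturbed helix conformation that stays clash-free
perturbed_helix <- function(n = 20, sd = 0.3, seed = 1) {
  set.seed(seed)
  make_helix(n)$coords + matrix(rnorm(3 * n, sd = sd), n, 3)
}

# ca_trace for randomly perturbed geometry, ignoring the spacing advisory
random_trace <- function(n, sd = 0.3, seed = 1)
  suppressWarnings(ca_trace(perturbed_helix(n, sd, seed)))
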