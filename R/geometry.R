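# Internal vectorized geometry: dihedrals and internal-coordinate chain
# building.  All functions operate row-wise on n x 3 matrices so that a whole
# ensemble of frames can be processed per chain position in one call.

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a * a))

vunit <- function(a) a / vnorm(a)

# signed dihedral (degrees, in (-180, 180]) of point quadruples, row-wise
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

# planar angle (degrees) at p2 of triples, row-wise
bond_angle_deg <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(pmin(1, pmax(-1, rowSums(u * v)))) * 180 / pi
}

# Place the next atom D given A, B, C (rows = independent chains/frames),
# bond length |CD| = r, angle B-C-D = theta (deg), dihedral A-B-C-D = tau
# (deg).  Sign convention verified against dihedral_deg in the test suite.
nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d_local <- cbind(-r * cos(th),
                   r * sin(th) * cos(ta),
                   -r * sin(th) * sin(ta))
  C + d_local[, 1] * bc + d_local[, 2] * m + d_local[, 3] * n
}

# All virtual CA torsions of a CA-only ensemble: frames x (n_res - 3) matrix;
# column j is the dihedral over CA atoms j..j+3.
ca_virtual_torsions <- function(ens) {
  n <- n_residues(ens)
  if (n < 4L) stop("need at least 4 residues for a CA virtual torsion")
  xyz <- ens$xyz
  get <- function(j) xyz[, c(3L * j - 2L, 3L * j - 1L, 3L * j),
                         drop = FALSE]
  out <- matrix(NA_real_, n_frames(ens), n - 3L)
  for (j in seq_len(n - 3L))
    out[, j] <- dihedral_deg(get(j), get(j + 1L), get(j + 2L), get(j + 3L))
  out
}

# phi/psi (degrees) of an N-CA-C ensemble; list of two frames x n_res
# matrices with NA at undefined chain-terminal positions.
backbone_phi_psi <- function(ens) {
  top <- ens$topology
  n <- n_residues(ens)
  iN <- which(top$atoms$elety == "N")
  iCA <- which(top$atoms$elety == "CA")
  iC <- which(top$atoms$elety == "C")
  if (length(iN) != n || length(iCA) != n || length(iC) != n)
    stop("phi/psi require N, CA and C atoms for every residue")
  xyz <- ens$xyz
  get <- function(a) xyz[, c(3L * a - 2L, 3L * a - 1L, 3L * a),
                         drop = FALSE]
  phi <- psi <- matrix(NA_real_, n_frames(ens), n)
  for (i in seq_len(n)) {
    if (i > 1L)
      phi[, i] <- dihedral_deg(get(iC[i - 1L]), get(iN[i]),
                               get(iCA[i]), get(iC[i]))
    if (i < n)
      psi[, i] <- dihedral_deg(get(iN[i]), get(iCA[i]),
                               get(iC[i]), get(iN[i + 1L]))
  }
  list(phi = phi, psi = psi)
}
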