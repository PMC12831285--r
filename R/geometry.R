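# Internal 3D geometry helpers: torsion-based backbone construction,
# rigid-body superposition, rotations.  Bond lengths/angles are the usual
# Engh & Huber-style ideals; they only need to be self-consistent, the
# fixtures are geometric stand-ins rather than physical models.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.522
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.6
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension of reference frame (NeRF): position atom D given the
# three preceding atoms A-B-C, the C-D bond length, the B-C-D bond angle
# (degrees) and the A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- -deg2rad(dihedral)   # sign fixed so dihedral_angle() reads back
                              # the requested torsion
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Build an N/CA/C/O/CB backbone from per-residue (phi, psi) torsions.
# Returns a list of L x 3 matrices.  omega is fixed trans (180 degrees).
# phi[1] is unused (no preceding C); psi[L] orients the final carbonyl.
build_backbone <- function(phi, psi, glycine = NULL) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 1)
  if (is.null(glycine)) glycine <- rep(FALSE, L)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- deg2rad(ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND_N_CA, ANGLE_C_N_CA, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] - 180)
    if (!glycine[i]) {
      bv <- CA[i, ] - N[i, ]
      cv <- C[i, ] - CA[i, ]
      av <- cross3(bv, cv)
      CB[i, ] <- -0.58273431 * av + 0.56802827 * bv - 0.54067466 * cv +
        CA[i, ]
    }
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

# Rotation matrix about a unit axis by angle (degrees), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_from_euler <- function(a, b, c) {
  rotation_about_axis(c(0, 0, 1), c) %*%
    rotation_about_axis(c(0, 1, 0), b) %*%
    rotation_about_axis(c(1, 0, 0), a)
}

# Kabsch least-squares superposition of x onto y (both n x 3).  Returns
# the proper rotation R and translation t with fitted = x %*% R + t, and
# the RMSD over the n pairs.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3, ncol(x) == 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fitted <- sweep(x %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, fitted = fitted)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% rotation, 2, translation, "+")
}
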