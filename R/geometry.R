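# Dihedral angle (degrees) defined by four points, standard atan2 form.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D at bond length r from C, bond angle theta (deg) at C with B,
# and dihedral phi (deg) about B-C relative to A (NeRF construction).
.placeAtom <- function(A, B, C, r, theta, phi) {
  # sign flipped so that dihedralAngle(A, B, C, placed) == phi
  th <- theta * pi / 180; ph <- -phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bc * (-r * cos(th)) + m * (r * sin(th) * cos(ph)) +
    n * (r * sin(th) * sin(ph))
}

# Build an ideal peptide backbone (N, CA, C per residue) from phi/psi
# vectors, with trans peptide bonds and standard bond geometry. Returns a
# list of 3 matrices (n x 3).
buildBackbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi[i - 1])
      CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
  }
  list(N = N, CA = CA, C = C)
}

# RMSD of points from their least-squares plane (smallest singular
# direction of the centered coordinates).
planeRMSD <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) return(0)
  cen <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(cen)
  normal <- sv$v[, 3]
  sqrt(mean((cen %*% normal)^2))
}
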