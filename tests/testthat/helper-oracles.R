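# Independent oracles used to check the geometric kernels. These are
# deliberately different constructions from the package implementation.

# Projection-formula dihedral: project the outer bond vectors onto the
# plane perpendicular to the central bond and take the signed angle
# between the projections.
oracle_dihedral <- function(p1, p2, p3, p4) {
  e <- p3 - p2
  e <- e / sqrt(sum(e^2))
  u <- (p1 - p2) - sum((p1 - p2) * e) * e
  w <- (p4 - p3) - sum((p4 - p3) * e) * e
  cx <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  ang <- atan2(sum(cx * e), sum(u * w)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Rotation-grid RMSD oracle: exhaustive search over Euler angles followed
# by local polish with optim (no SVD anywhere).
oracle_rmsd <- function(A, B, step = 15) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    a <- ang[1]; b <- ang[2]; c <- ang[3]
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((A0 - B0 %*% t(rotmat(ang)))^2)))
  st <- step * pi / 180
  best <- c(0, 0, 0)
  best_v <- obj(best)
  for (a in seq(0, 2 * pi - st, by = st))
    for (b in seq(0, pi, by = st))
      for (c in seq(0, 2 * pi - st, by = st)) {
        v <- obj(c(a, b, c))
        if (v < best_v) {
          best_v <- v
          best <- c(a, b, c)
        }
      }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# random rigid motion applied to a coordinate matrix
random_rigid_motion <- function(xyz) {
  ang <- stats::runif(3, -pi, pi)
  Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                 sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), -sin(ang[2]),
                 0, sin(ang[2]), cos(ang[2])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[3]), 0, sin(ang[3]), 0, 1, 0,
                 -sin(ang[3]), 0, cos(ang[3])), 3, byrow = TRUE)
  R <- Rz %*% Rx %*% Ry
  tr <- stats::runif(3, -20, 20)
  sweep(xyz %*% t(R), 2, -tr)
}

rigid_move_conformer <- function(conformer) {
  conformer$xyz <- random_rigid_motion(conformer$xyz)
  conformer
}

# minimal conformer-like object for kernel tests on hand-built geometry
fake_conformer <- function(xyz, masses = rep(12.011, nrow(xyz))) {
  colnames(xyz) <- c("x", "y", "z")
  list(topology = list(atoms = data.frame(mass = masses)), xyz = xyz)
}
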