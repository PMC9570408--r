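# Pure geometric kernels: dihedrals, centroids, inter-base descriptors,
# radius of gyration, superposed RMSD. All coordinates are Angstroms; all
# angles are degrees.

RAD2DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion about the p2--p3 axis following the IUPAC convention:
#' the eclipsed (cis) arrangement is 0 degrees and a clockwise rotation of
#' p4 relative to p1, viewed from p2 towards p3, is positive. The result is
#' invariant under rigid motion of all four points.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b2) < 1e-12)
    stop("degenerate geometry: central atoms coincide")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear atom triple in dihedral")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * (b2 / vnorm(b2)))
  ang <- atan2(y, x) * RAD2DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Wrap an angle into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180] <- w[w <= -180] + 360
  # map exact -180 to +180 so the interval is (-180, 180]
  w[abs(w + 180) < 1e-12] <- 180
  w
}

#' Centroid of a named ring
#'
#' Unweighted arithmetic mean of the ring heavy-atom coordinates.
#'
#' @param conformer A `nad_conformer`.
#' @param ring Character vector of atom names (6 for the
#'   nicotinamide/pyridone ring, 9 for the fused purine).
#' @return Numeric 3-vector.
#' @export
ring_centroid <- function(conformer, ring) {
  xyz <- conformer_xyz(conformer)
  miss <- setdiff(ring, rownames(xyz))
  if (length(miss))
    stop("missing ring atom(s): ", paste(miss, collapse = ", "))
  colMeans(xyz[ring, , drop = FALSE])
}

#' Inter-base centroid--centroid distance
#'
#' Distance between the centroids of the nicotinamide (or pyridone) ring
#' and the adenine fused-ring system, the molecule's end-to-end descriptor.
#'
#' @param conformer A `nad_conformer`.
#' @return Distance in Angstroms.
#' @export
interbase_distance <- function(conformer) {
  top <- conformer$topology
  cn <- ring_centroid(conformer, top$rings$nicotinamide)
  ca <- ring_centroid(conformer, top$rings$adenine)
  vnorm(cn - ca)
}

#' Inter-base plane (normal--normal) angle
#'
#' The nicotinamide-plane normal is (N1N->C2N) x (N1N->C6N); the adenine
#' normal is (C5A->C4A) x (C5A->C6A). Both normals are unit-normalized and
#' the angle is the arccosine of their dot product (clamped to [-1, 1]).
#' 0 or 180 degrees corresponds to parallel base stacking.
#'
#' @param conformer A `nad_conformer`.
#' @return Angle in degrees in [0, 180].
#' @export
interbase_plane_angle <- function(conformer) {
  xyz <- conformer_xyz(conformer)
  need <- c("N1N", "C2N", "C6N", "C5A", "C4A", "C6A")
  miss <- setdiff(need, rownames(xyz))
  if (length(miss))
    stop("missing atom(s) for plane angle: ", paste(miss, collapse = ", "))
  a <- xyz["C2N", ] - xyz["N1N", ]
  b <- xyz["C6N", ] - xyz["N1N", ]
  cc <- xyz["C4A", ] - xyz["C5A", ]
  d <- xyz["C6A", ] - xyz["C5A", ]
  n1 <- vcross(a, b)
  n2 <- vcross(cc, d)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate geometry: zero cross product in plane angle")
  dt <- sum(n1 * n2) / (vnorm(n1) * vnorm(n2))
  dt <- min(1, max(-1, dt))
  acos(dt) * RAD2DEG
}

#' Mass-weighted radius of gyration
#'
#' Root-mean-square (mass-weighted) distance of the atoms from the
#' molecule's center of mass.
#'
#' @param conformer A `nad_conformer`.
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(conformer) {
  xyz <- conformer_xyz(conformer)
  m <- conformer$topology$atoms$mass
  com <- colSums(xyz * m) / sum(m)
  dx <- sweep(xyz, 2, com)
  sqrt(sum(m * rowSums(dx^2)) / sum(m))
}

# Kabsch optimal rotation: returns the RMSD after least-squares rigid-body
# superposition of B onto A (n x 3 matrices, rows paired).
kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Br <- B0 %*% t(R)
  sqrt(sum((A0 - Br)^2) / nrow(A))
}

#' RMSD between two conformers
#'
#' Root-mean-square deviation over a selection of atoms, by default after
#' optimal rigid-body (Kabsch) superposition so that rigid motion does not
#' register. Heavy atoms are used when no selection is given.
#'
#' @param confA,confB `nad_conformer` objects sharing a topology.
#' @param selection Character vector of atom names; default all heavy atoms.
#' @param superpose Superpose before the deviation is taken (default TRUE).
#'   `FALSE` gives the raw coordinate RMSD in the frames as given.
#' @return RMSD in Angstroms.
#' @export
rmsd_superposed <- function(confA, confB, selection = NULL, superpose = TRUE) {
  if (!identical(confA$topology$species, confB$topology$species))
    stop("topology mismatch: conformers are different species")
  xa <- conformer_xyz(confA)
  xb <- conformer_xyz(confB)
  if (is.null(selection))
    selection <- heavy_atoms(confA$topology)
  if (!length(selection)) stop("empty atom selection")
  miss <- setdiff(selection, rownames(xa))
  if (length(miss))
    stop("selection names unknown atoms: ", paste(miss, collapse = ", "))
  A <- xa[selection, , drop = FALSE]
  B <- xb[selection, , drop = FALSE]
  if (superpose) kabsch_rmsd(A, B) else sqrt(mean(rowSums((A - B)^2)))
}

# The four intramolecular hydrogen-bond distance groups used for fold
# tracking. A group with two member pairs counts via its minimum distance.
hbond_pair_groups <- function() {
  list(
    o3N_o2A = list(c("O3'N", "O2'A")),
    o3A_o1N = list(c("O3'A", "O1N")),
    ribA_o4N = list(c("O3'A", "O4'N"), c("O2'A", "O4'N")),
    ribN_o4A = list(c("O3'N", "O4'A"), c("O2'N", "O4'A"))
  )
}

atom_dist <- function(xyz, a, b) vnorm(xyz[a, ] - xyz[b, ])

#' Per-conformer metric set
#'
#' Computes every per-frame descriptor used by the pipeline: inter-base
#' centroid distance d, inter-base plane angle, the four named dihedrals
#' (theta, nu2, chi_N, chi_A), radius of gyration, the four intramolecular
#' hydrogen-bond group distances (minimum over a group's member pairs), and
#' the O4'N--C4A folded-event distance.
#'
#' @param conformer A `nad_conformer`.
#' @return One-row data.frame of metrics.
#' @export
compute_metrics <- function(conformer) {
  xyz <- conformer_xyz(conformer)
  dih <- measure_dihedrals(conformer)
  grp <- hbond_pair_groups()
  hb <- vapply(grp, function(pairs) {
    min(vapply(pairs, function(p) atom_dist(xyz, p[1], p[2]), 0))
  }, 0)
  data.frame(
    d = interbase_distance(conformer),
    plane_angle = interbase_plane_angle(conformer),
    theta = dih[["theta"]],
    nu2 = dih[["nu2"]],
    chi_N = dih[["chi_N"]],
    chi_A = dih[["chi_A"]],
    rg = radius_of_gyration(conformer),
    hb_o3N_o2A = hb[["o3N_o2A"]],
    hb_o3A_o1N = hb[["o3A_o1N"]],
    hb_ribA_o4N = hb[["ribA_o4N"]],
    hb_ribN_o4A = hb[["ribN_o4A"]],
    fold_event_distance = atom_dist(xyz, "O4'N", "C4A")
  )
}

#' Measure the four named conformational dihedrals
#'
#' theta (amide, C4N-C3N-C7N-N7N), nu2 (sugar, C1'N-C2'N-C3'N-C4'N),
#' chi_N (glycosidic, O4'N-C1'N-N1N-C2N) and chi_A (glycosidic,
#' C4A-N9A-C1'A-O4'A).
#'
#' @param conformer A `nad_conformer`.
#' @return Named numeric vector of angles in degrees.
#' @export
measure_dihedrals <- function(conformer) {
  xyz <- conformer_xyz(conformer)
  defs <- dihedral_definitions()
  vapply(defs, function(q) {
    dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
  }, 0)
}

#' Atom quadruples defining the named dihedrals
#' @return Named list of length-4 character vectors.
#' @export
dihedral_definitions <- function() {
  list(
    theta = c("C4N", "C3N", "C7N", "N7N"),
    nu2 = c("C1'N", "C2'N", "C3'N", "C4'N"),
    chi_N = c("O4'N", "C1'N", "N1N", "C2N"),
    chi_A = c("C4A", "N9A", "C1'A", "O4'A")
  )
}
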