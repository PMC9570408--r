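# All-atom template conformers from idealized internal coordinates.
#
# The builder places atoms sequentially by bond length / bond angle /
# torsion (natural-extension-of-reference-frame construction). Bond
# lengths and angles are fixed idealized small-molecule values; all
# conformational freedom lives in the named torsions (chi_N, chi_A, theta,
# the eight pyrophosphate backbone torsions) and the two sugar
# pseudorotation phases. Ring closure bonds (C4'-O4' of each furanose) are
# implied by the endocyclic torsions and close to within a few hundredths
# of an Angstrom, which is immaterial for torsion/distance analysis.

NU_MAX <- 38  # furanose pseudorotation amplitude, degrees

# endocyclic torsions nu0..nu4 for pseudorotation phase P (degrees)
pucker_nus <- function(P) {
  j <- 0:4
  nus <- NU_MAX * cos((P + 144 * (j - 2)) * pi / 180)
  names(nus) <- paste0("nu", j)
  nus
}

#' Pseudorotation phases of the stored sugar geometries
#' @return Named numeric vector (degrees): C2p_endo, C3p_endo, flat.
#' @export
pucker_phases <- function() {
  c(C2p_endo = 162, C3p_endo = 18, flat = 90)
}

# Rodrigues rotation of points (n x 3) about unit axis u through origin.
rotate_about_axis <- function(pts, u, ang_deg) {
  a <- ang_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ca + ux^2 * (1 - ca), ux * uy * (1 - ca) - uz * sa, ux * uz * (1 - ca) + uy * sa,
    uy * ux * (1 - ca) + uz * sa, ca + uy^2 * (1 - ca), uy * uz * (1 - ca) - ux * sa,
    uz * ux * (1 - ca) - uy * sa, uz * uy * (1 - ca) + ux * sa, ca + uz^2 * (1 - ca)
  ), nrow = 3, byrow = TRUE)
  pts %*% t(R)
}

# Place atom D given A, B, C: |C-D| = r, angle(B,C,D) = theta_deg,
# dihedral(A,B,C,D) = phi_deg.
nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  b2 <- C - B
  b2 <- b2 / vnorm(b2)
  b1 <- B - A
  n <- vcross(b1, b2)
  n <- n / vnorm(n)
  m <- vcross(n, b2)
  C + r * (-cos(th) * b2 + sin(th) * (cos(ph) * m + sin(ph) * n))
}

# Planar idealized adenine (9-atom fused purine + N6 amino + hydrogens),
# z = 0. Six-ring is a regular hexagon; the five-ring is a regular
# pentagon sharing the C4A-C5A edge.
adenine_fragment <- function() {
  s <- 1.36
  hex_names <- c("N1A", "C2A", "N3A", "C4A", "C5A", "C6A")
  ang <- (90 + 60 * (0:5)) * pi / 180
  hx <- cbind(s * cos(ang), s * sin(ang), 0)
  rownames(hx) <- hex_names
  P1 <- hx["C4A", 1:2]; P2 <- hx["C5A", 1:2]
  M <- (P1 + P2) / 2
  u <- M / sqrt(sum(M^2))           # outward from hexagon center (origin)
  apo <- s / (2 * tan(36 * pi / 180))
  Cp <- M + apo * u
  a1 <- atan2(P1[2] - Cp[2], P1[1] - Cp[1])
  a2 <- atan2(P2[2] - Cp[2], P2[1] - Cp[1])
  step <- 72 * pi / 180
  # direction s.t. stepping from C4A away from C5A walks N9A, C8A, N7A
  dirn <- if (abs(wrap_angle((a1 + step - a2) * 180 / pi)) < 1) 1 else -1
  Rp <- s / (2 * sin(36 * pi / 180))
  pent <- function(k) Cp + Rp * c(cos(a1 - dirn * step * k),
                                  sin(a1 - dirn * step * k))
  co <- rbind(
    hx,
    N9A = c(pent(1), 0), C8A = c(pent(2), 0), N7A = c(pent(3), 0)
  )
  radial <- function(at, center, len) {
    v <- co[at, 1:2] - center
    c(co[at, 1:2] + len * v / sqrt(sum(v^2)), 0)
  }
  co <- rbind(co,
    N6A = radial("C6A", c(0, 0), 1.34),
    H2A = radial("C2A", c(0, 0), 1.08),
    H8A = radial("C8A", Cp, 1.08)
  )
  # amino hydrogens in-plane at +-60 deg from the C6A->N6A direction
  v <- co["N6A", 1:2] - co["C6A", 1:2]
  v <- v / sqrt(sum(v^2))
  rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                           sin(a) * v[1] + cos(a) * v[2])
  co <- rbind(co,
    H61A = c(co["N6A", 1:2] + 1.01 * rot2(v, 60 * pi / 180), 0),
    H62A = c(co["N6A", 1:2] + 1.01 * rot2(v, -60 * pi / 180), 0)
  )
  co
}

#' Default conformational parameters of the template
#'
#' chi/theta/backbone torsions in degrees; P_A and P_N are the furanose
#' pseudorotation phases (18 = C3'-endo). The backbone defaults give the
#' extended, Rossmann-like conformation.
#'
#' @return Named list of parameters.
#' @export
template_params <- function() {
  list(
    chi_A = -110, chi_N = -160, theta = 0,
    P_A = 18, P_N = 18,
    gamma_A = 180, beta_A = 180, alpha_A = -60, zeta_A = 180,
    zeta_N = -60, alpha_N = -60, beta_N = 180, gamma_N = 180
  )
}

# Z-matrix rows for everything downstream of the adenine fragment.
# Torsion entries are expressions evaluated against the parameter set
# (plus nu*_A / nu*_N pseudorotation torsions).
template_zmatrix <- function() {
  R <- function(name, A, B, C, r, ang, tor) list(name = name, A = A, B = B,
                                                 C = C, r = r, ang = ang,
                                                 tor = tor)
  list(
    R("C1'A", "C4A", "C8A", "N9A", 1.47, 127.0, "180"),
    R("O4'A", "C4A", "N9A", "C1'A", 1.41, 108.2, "chi_A"),
    R("C2'A", "N9A", "O4'A", "C1'A", 1.53, 106.1, "c2a_sign * 121"),
    R("H1'A", "N9A", "O4'A", "C1'A", 1.09, 109.0, "-c2a_sign * 119"),
    R("C3'A", "O4'A", "C1'A", "C2'A", 1.53, 101.5, "nu1_A"),
    R("C4'A", "C1'A", "C2'A", "C3'A", 1.53, 102.6, "nu2_A"),
    R("O2'A", "C4'A", "C3'A", "C2'A", 1.41, 113.0, "nu2_A + o2a_sign * 120"),
    R("H2'A", "C4'A", "C3'A", "C2'A", 1.09, 111.0, "nu2_A - o2a_sign * 120"),
    R("HO2'A", "C3'A", "C2'A", "O2'A", 0.97, 108.5, "-60"),
    R("O3'A", "C1'A", "C2'A", "C3'A", 1.42, 110.5, "nu2_A + o3a_sign * 120"),
    R("H3'A", "C1'A", "C2'A", "C3'A", 1.09, 111.0, "nu2_A - o3a_sign * 120"),
    R("HO3'A", "C2'A", "C3'A", "O3'A", 0.97, 108.5, "-60"),
    R("C5'A", "C2'A", "C3'A", "C4'A", 1.51, 115.5, "nu3_A + c5a_sign * 120"),
    R("H4'A", "C2'A", "C3'A", "C4'A", 1.09, 109.0, "nu3_A - c5a_sign * 120"),
    R("O5'A", "C3'A", "C4'A", "C5'A", 1.44, 110.9, "gamma_A"),
    R("H5'A", "C3'A", "C4'A", "C5'A", 1.09, 109.5, "gamma_A + 120"),
    R("H5''A", "C3'A", "C4'A", "C5'A", 1.09, 109.5, "gamma_A - 120"),
    R("PA", "C4'A", "C5'A", "O5'A", 1.60, 119.0, "beta_A"),
    R("O3", "C5'A", "O5'A", "PA", 1.61, 101.8, "alpha_A"),
    R("O1A", "C5'A", "O5'A", "PA", 1.48, 108.0, "alpha_A + 120"),
    R("O2A", "C5'A", "O5'A", "PA", 1.48, 108.0, "alpha_A - 120"),
    R("PN", "O5'A", "PA", "O3", 1.61, 132.5, "zeta_A"),
    R("O5'N", "PA", "O3", "PN", 1.61, 101.8, "zeta_N"),
    R("O1N", "PA", "O3", "PN", 1.48, 108.0, "zeta_N + 120"),
    R("O2N", "PA", "O3", "PN", 1.48, 108.0, "zeta_N - 120"),
    R("C5'N", "O3", "PN", "O5'N", 1.44, 119.0, "alpha_N"),
    R("C4'N", "PN", "O5'N", "C5'N", 1.51, 110.9, "beta_N"),
    R("H5'N", "PN", "O5'N", "C5'N", 1.09, 109.5, "beta_N + 120"),
    R("H5''N", "PN", "O5'N", "C5'N", 1.09, 109.5, "beta_N - 120"),
    R("C3'N", "O5'N", "C5'N", "C4'N", 1.53, 115.5, "gamma_N"),
    R("O4'N", "O5'N", "C5'N", "C4'N", 1.44, 109.0, "gamma_N + o4n_sign * 120"),
    R("H4'N", "O5'N", "C5'N", "C4'N", 1.09, 109.0, "gamma_N - o4n_sign * 120"),
    R("C2'N", "O4'N", "C4'N", "C3'N", 1.53, 102.6, "nu3_N"),
    R("O3'N", "O4'N", "C4'N", "C3'N", 1.42, 110.5, "nu3_N + o3n_sign * 120"),
    R("H3'N", "O4'N", "C4'N", "C3'N", 1.09, 111.0, "nu3_N - o3n_sign * 120"),
    R("HO3'N", "C4'N", "C3'N", "O3'N", 0.97, 108.5, "-60"),
    R("C1'N", "C4'N", "C3'N", "C2'N", 1.53, 101.5, "nu2_N"),
    R("O2'N", "C4'N", "C3'N", "C2'N", 1.41, 113.0, "nu2_N + o2n_sign * 120"),
    R("H2'N", "C4'N", "C3'N", "C2'N", 1.09, 111.0, "nu2_N - o2n_sign * 120"),
    R("HO2'N", "C3'N", "C2'N", "O2'N", 0.97, 108.5, "-60"),
    R("N1N", "C3'N", "C2'N", "C1'N", 1.48, 112.0, "nu1_N + base_sign * 120"),
    R("H1'N", "C3'N", "C2'N", "C1'N", 1.09, 109.0, "nu1_N - base_sign * 120"),
    R("C2N", "O4'N", "C1'N", "N1N", 1.37, 120.5, "chi_N"),
    R("C6N", "O4'N", "C1'N", "N1N", 1.37, 120.5, "chi_N + 180"),
    R("C3N", "C6N", "N1N", "C2N", 1.39, 120.0, "0"),
    R("C4N", "N1N", "C2N", "C3N", 1.39, 120.0, "0"),
    R("C5N", "C2N", "C3N", "C4N", 1.39, 120.0, "0"),
    R("C7N", "N1N", "C2N", "C3N", 1.50, 120.0, "180"),
    R("N7N", "C4N", "C3N", "C7N", 1.33, 116.5, "theta"),
    R("O7N", "C4N", "C3N", "C7N", 1.23, 121.5, "theta + 180"),
    R("H71N", "O7N", "C7N", "N7N", 1.01, 120.0, "0"),
    R("H72N", "O7N", "C7N", "N7N", 1.01, 120.0, "180"),
    R("H2N", "C6N", "N1N", "C2N", 1.08, 120.0, "180"),
    R("O2X", "C6N", "N1N", "C2N", 1.23, 120.0, "180"),
    R("H4N", "C2N", "C3N", "C4N", 1.08, 120.0, "180"),
    R("O4X", "C2N", "C3N", "C4N", 1.24, 120.0, "180"),
    R("H41N", "C2N", "C3N", "C4N", 1.10, 109.0, "122"),
    R("H42N", "C2N", "C3N", "C4N", 1.10, 109.0, "-122"),
    R("H5N", "C3N", "C4N", "C5N", 1.08, 120.0, "180"),
    R("H6N", "C4N", "C5N", "C6N", 1.08, 120.0, "180"),
    R("O6X", "C4N", "C5N", "C6N", 1.23, 120.0, "180")
  )
}

# chirality / substituent-face signs (fixed package constants; the
# combination yields beta-D riboses with the base and C5' on one face)
template_signs <- function() {
  list(c2a_sign = 1, o2a_sign = -1, o3a_sign = 1, c5a_sign = -1,
       o4n_sign = -1, o3n_sign = -1, o2n_sign = -1, base_sign = 1)
}

# parse-once caches (the zmatrix torsion expressions and the planar
# adenine fragment are fixed package constants)
.template_cache <- new.env(parent = emptyenv())

compiled_zmatrix <- function() {
  if (is.null(.template_cache$zmx)) {
    zmx <- template_zmatrix()
    for (i in seq_along(zmx)) zmx[[i]]$tor <- parse(text = zmx[[i]]$tor)[[1]]
    .template_cache$zmx <- zmx
  }
  .template_cache$zmx
}

cached_adenine <- function() {
  if (is.null(.template_cache$adenine))
    .template_cache$adenine <- adenine_fragment()
  .template_cache$adenine
}

#' Build an idealized all-atom conformer for a species
#'
#' Constructs the dinucleotide from idealized internal coordinates. The
#' default parameters give the extended conformation (inter-base centroid
#' distance in the 12-15 Angstrom window) with anti glycosidic bonds and
#' C3'-endo sugars.
#'
#' @param species One of `nad_species()`.
#' @param params Named list overriding entries of `template_params()`.
#' @return A `nad_conformer`.
#' @export
build_template <- function(species, params = list()) {
  species <- match.arg(species, nad_species())
  top <- build_topology(species)
  p <- utils::modifyList(template_params(), params)
  env <- new.env(parent = baseenv())
  for (nm in names(p)) assign(nm, p[[nm]], envir = env)
  for (nm in names(template_signs()))
    assign(nm, template_signs()[[nm]], envir = env)
  nus_A <- pucker_nus(p$P_A)
  nus_N <- pucker_nus(p$P_N)
  for (j in 0:4) {
    assign(paste0("nu", j, "_A"), nus_A[[paste0("nu", j)]], envir = env)
    assign(paste0("nu", j, "_N"), nus_N[[paste0("nu", j)]], envir = env)
  }
  coords <- cached_adenine()
  want <- top$atoms$name
  for (row in compiled_zmatrix()) {
    if (!(row$name %in% want)) next
    tor <- eval(row$tor, envir = env)
    D <- nerf_place(coords[row$A, ], coords[row$B, ], coords[row$C, ],
                    row$r, row$ang, tor)
    coords <- rbind(coords, matrix(D, 1, 3, dimnames = list(row$name)))
  }
  miss <- setdiff(want, rownames(coords))
  if (length(miss))
    stop("internal error: template missing atoms: ",
         paste(miss, collapse = ", "))
  nad_conformer(top, coords[want, , drop = FALSE])
}

#' Drive a named rotatable torsion to a target value
#'
#' Rigidly rotates the bond's moving subtree about the bond axis so the
#' defining dihedral equals `target`. Bond lengths and everything outside
#' the subtree are untouched.
#'
#' @param conformer A `nad_conformer`.
#' @param name A rotatable-bond name (see `names(topology$rotatable)`).
#' @param target Target dihedral, degrees.
#' @return The modified `nad_conformer`.
#' @export
set_dihedral <- function(conformer, name, target) {
  rot <- conformer$topology$rotatable[[name]]
  if (is.null(rot))
    stop("unknown rotatable bond: ", name)
  xyz <- conformer$xyz
  q <- rot$dihedral
  cur <- dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
  delta <- wrap_angle(target - cur)
  axis <- xyz[q[3], ] - xyz[q[2], ]
  axis <- axis / vnorm(axis)
  mov <- rot$moving
  pivot <- xyz[q[2], ]
  shifted <- sweep(xyz[mov, , drop = FALSE], 2, pivot)
  xyz[mov, ] <- sweep(rotate_about_axis(shifted, axis, delta), 2, -pivot)
  conformer$xyz <- xyz
  conformer
}

#' Set several named torsions at once
#' @param conformer A `nad_conformer`.
#' @param targets Named numeric vector of target torsions (degrees).
#' @return The modified `nad_conformer`.
#' @export
set_dihedrals <- function(conformer, targets) {
  for (nm in names(targets))
    conformer <- set_dihedral(conformer, nm, targets[[nm]])
  conformer
}

# measure pseudorotation phase from nu1, nu2 of one sugar
measure_phase <- function(nu1, nu2) {
  c144 <- cos(144 * pi / 180); s144 <- sin(144 * pi / 180)
  cp <- nu2 / NU_MAX
  cp <- min(1, max(-1, cp))
  sp <- (nu1 / NU_MAX - cp * c144) / s144
  wrap_angle(atan2(sp, cp) * 180 / pi)
}

measure_template_params <- function(conformer) {
  xyz <- conformer$xyz
  dih <- function(a, b, c, d) dihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  rot <- conformer$topology$rotatable
  tors <- lapply(rot, function(r) dih(r$dihedral[1], r$dihedral[2],
                                      r$dihedral[3], r$dihedral[4]))
  nu1_N <- dih("O4'N", "C1'N", "C2'N", "C3'N")
  nu2_N <- dih("C1'N", "C2'N", "C3'N", "C4'N")
  nu1_A <- dih("O4'A", "C1'A", "C2'A", "C3'A")
  nu2_A <- dih("C1'A", "C2'A", "C3'A", "C4'A")
  c(tors, list(P_N = measure_phase(nu1_N, nu2_N),
               P_A = measure_phase(nu1_A, nu2_A)))
}

#' Swap the nicotinamide-ribose pucker
#'
#' Replaces the nicotinamide/pyridone ribose geometry with the stored
#' rigid sugar template for the requested pucker (C2'-endo, C3'-endo, or
#' flat), preserving every named torsion (including chi_N) and the
#' molecule's global pose (the rebuilt conformer is superposed onto the
#' original over the ADP-moiety heavy atoms).
#'
#' @param conformer A `nad_conformer`.
#' @param target One of "C2p_endo", "C3p_endo", "flat".
#' @return The modified `nad_conformer`.
#' @export
set_pucker <- function(conformer, target) {
  target <- match.arg(target, names(pucker_phases()))
  pars <- measure_template_params(conformer)
  pars$P_N <- unname(pucker_phases()[target])
  new <- build_template(conformer$topology$species, pars)
  # superpose onto the original over the ADP moiety
  adp <- grep("A$|^O3$|^PA$|^PN$|^O1N$|^O2N$", heavy_atoms(conformer$topology),
              value = TRUE)
  align_onto(new, conformer, adp)
}

# rigid-transform `mobile` so that `sel` atoms best match `ref`
align_onto <- function(mobile, ref, sel) {
  A <- ref$xyz[sel, , drop = FALSE]
  B <- mobile$xyz[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new_xyz <- sweep(sweep(mobile$xyz, 2, cb) %*% t(R), 2, -ca)
  dimnames(new_xyz) <- dimnames(mobile$xyz)
  mobile$xyz <- new_xyz
  mobile
}
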