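# Species definitions and covalent topology for the five dinucleotides:
# NAD+, NADH, and the three pyridone adenine dinucleotides (2-, 4-,
# 6-ox-NAD). Atom names follow the superscript-N/A convention used for
# dinucleotide conformation work, in ASCII (e.g. O4'N is the
# nicotinamide-ribose ring oxygen). The pyridone carbonyl oxygens are named
# O2X/O4X/O6X to avoid colliding with the phosphate oxygens O1N/O2N.

.topology_cache <- new.env(parent = emptyenv())

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

#' The five dinucleotide species
#' @return Character vector of species names.
#' @export
nad_species <- function() {
  c("NAD_plus", "NADH", "ox2_NAD", "ox4_NAD", "ox6_NAD")
}

element_of <- function(name) substr(sub("^H[A-Z0-9']*$", "H", name), 1, 1)

# Shared ADP + nicotinamide-riboside scaffold (the NAD+ layout). Order:
# ADP moiety (adenine base, adenosine ribose, the two phosphates) first,
# then the nicotinamide riboside; hydrogens directly after their parent
# heavy atom.
nad_plus_atom_names <- function() {
  c(
    # adenine base
    "N9A", "C8A", "H8A", "N7A", "C5A", "C6A", "N6A", "H61A", "H62A",
    "N1A", "C2A", "H2A", "N3A", "C4A",
    # adenosine ribose
    "C1'A", "H1'A", "O4'A", "C2'A", "H2'A", "O2'A", "HO2'A",
    "C3'A", "H3'A", "O3'A", "HO3'A", "C4'A", "H4'A",
    "C5'A", "H5'A", "H5''A", "O5'A",
    # pyrophosphate (charge -2: no acidic hydrogens)
    "PA", "O1A", "O2A", "O3", "PN", "O1N", "O2N", "O5'N",
    # nicotinamide ribose
    "C5'N", "H5'N", "H5''N", "C4'N", "H4'N", "O4'N",
    "C3'N", "H3'N", "O3'N", "HO3'N", "C2'N", "H2'N", "O2'N", "HO2'N",
    "C1'N", "H1'N",
    # nicotinamide base + carboxamide
    "N1N", "C2N", "H2N", "C3N", "C7N", "O7N", "N7N", "H71N", "H72N",
    "C4N", "H4N", "C5N", "H5N", "C6N", "H6N"
  )
}

nad_plus_bonds <- function() {
  b <- list(
    # adenine
    c("N9A", "C8A"), c("C8A", "N7A"), c("N7A", "C5A"), c("C5A", "C4A"),
    c("C4A", "N9A"), c("C5A", "C6A"), c("C6A", "N1A"), c("N1A", "C2A"),
    c("C2A", "N3A"), c("N3A", "C4A"), c("C6A", "N6A"),
    c("C8A", "H8A"), c("C2A", "H2A"), c("N6A", "H61A"), c("N6A", "H62A"),
    # glycosidic (adenosine)
    c("N9A", "C1'A"),
    # adenosine ribose
    c("C1'A", "O4'A"), c("C1'A", "C2'A"), c("C2'A", "C3'A"),
    c("C3'A", "C4'A"), c("C4'A", "O4'A"), c("C2'A", "O2'A"),
    c("C3'A", "O3'A"), c("C4'A", "C5'A"), c("C5'A", "O5'A"),
    c("C1'A", "H1'A"), c("C2'A", "H2'A"), c("O2'A", "HO2'A"),
    c("C3'A", "H3'A"), c("O3'A", "HO3'A"), c("C4'A", "H4'A"),
    c("C5'A", "H5'A"), c("C5'A", "H5''A"),
    # pyrophosphate bridge
    c("O5'A", "PA"), c("PA", "O1A"), c("PA", "O2A"), c("PA", "O3"),
    c("O3", "PN"), c("PN", "O1N"), c("PN", "O2N"), c("PN", "O5'N"),
    c("O5'N", "C5'N"),
    # nicotinamide ribose
    c("C5'N", "C4'N"), c("C4'N", "O4'N"), c("C4'N", "C3'N"),
    c("C3'N", "C2'N"), c("C2'N", "C1'N"), c("C1'N", "O4'N"),
    c("C2'N", "O2'N"), c("C3'N", "O3'N"),
    c("C5'N", "H5'N"), c("C5'N", "H5''N"), c("C4'N", "H4'N"),
    c("C3'N", "H3'N"), c("O3'N", "HO3'N"), c("C2'N", "H2'N"),
    c("O2'N", "HO2'N"), c("C1'N", "H1'N"),
    # glycosidic (nicotinamide)
    c("C1'N", "N1N"),
    # nicotinamide ring + carboxamide
    c("N1N", "C2N"), c("C2N", "C3N"), c("C3N", "C4N"), c("C4N", "C5N"),
    c("C5N", "C6N"), c("C6N", "N1N"),
    c("C3N", "C7N"), c("C7N", "O7N"), c("C7N", "N7N"),
    c("C2N", "H2N"), c("C4N", "H4N"), c("C5N", "H5N"), c("C6N", "H6N"),
    c("N7N", "H71N"), c("N7N", "H72N")
  )
  do.call(rbind, b)
}

insert_after <- function(x, after, values) {
  i <- match(after, x)
  append(x, values, after = i)
}

# Species edits relative to the NAD+ scaffold. NADH gains a second H at
# C4N (1,4-dihydro ring, neutral N1N). Each ox species swaps the ring H at
# the oxidized carbon for a carbonyl oxygen; N1N is ribose-substituted and
# therefore carries no hydrogen in any species.
species_atom_names <- function(species) {
  a <- nad_plus_atom_names()
  switch(species,
    NAD_plus = a,
    NADH = insert_after(setdiff(a, "H4N"), "C4N", c("H41N", "H42N")),
    ox2_NAD = insert_after(setdiff(a, "H2N"), "C2N", "O2X"),
    ox4_NAD = insert_after(setdiff(a, "H4N"), "C4N", "O4X"),
    ox6_NAD = insert_after(setdiff(a, "H6N"), "C6N", "O6X"),
    stop("unknown species: ", species)
  )
}

species_bonds <- function(species) {
  b <- nad_plus_bonds()
  drop_bond <- function(b, h) b[!(b[, 1] == h | b[, 2] == h), , drop = FALSE]
  switch(species,
    NAD_plus = b,
    NADH = rbind(drop_bond(b, "H4N"), c("C4N", "H41N"), c("C4N", "H42N")),
    ox2_NAD = rbind(drop_bond(b, "H2N"), c("C2N", "O2X")),
    ox4_NAD = rbind(drop_bond(b, "H4N"), c("C4N", "O4X")),
    ox6_NAD = rbind(drop_bond(b, "H6N"), c("C6N", "O6X")),
    stop("unknown species: ", species)
  )
}

# Named rotatable bonds. The dihedral quadruple both defines the torsion
# and fixes which side moves: the subtree reached from the third atom
# (excluding the bond) is rotated rigidly.
rotatable_bond_table <- function() {
  list(
    chi_A = c("C4A", "N9A", "C1'A", "O4'A"),
    chi_N = c("O4'N", "C1'N", "N1N", "C2N"),
    theta = c("C4N", "C3N", "C7N", "N7N"),
    gamma_A = c("C3'A", "C4'A", "C5'A", "O5'A"),
    beta_A = c("C4'A", "C5'A", "O5'A", "PA"),
    alpha_A = c("C5'A", "O5'A", "PA", "O3"),
    zeta_A = c("O5'A", "PA", "O3", "PN"),
    zeta_N = c("PA", "O3", "PN", "O5'N"),
    alpha_N = c("O3", "PN", "O5'N", "C5'N"),
    beta_N = c("PN", "O5'N", "C5'N", "C4'N"),
    gamma_N = c("O5'N", "C5'N", "C4'N", "C3'N")
  )
}

#' Backbone torsion names of the pyrophosphate linker
#' @return Character vector of rotatable backbone torsion names.
#' @export
backbone_torsion_names <- function() {
  c("gamma_A", "beta_A", "alpha_A", "zeta_A",
    "zeta_N", "alpha_N", "beta_N", "gamma_N")
}

# Connected component of `start` in the bond graph with one bond removed.
subtree_atoms <- function(bonds, drop_a, drop_b, start) {
  keep <- !((bonds[, 1] == drop_a & bonds[, 2] == drop_b) |
            (bonds[, 1] == drop_b & bonds[, 2] == drop_a))
  b <- bonds[keep, , drop = FALSE]
  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Build the covalent topology of a dinucleotide species
#'
#' Returns the atom table (names, elements, masses), bond list, ring
#' memberships (6-atom nicotinamide/pyridone ring, 9-atom fused purine),
#' and the named rotatable bonds with their rigid moving subtrees. The
#' pyrophosphate is modeled fully deprotonated (charge -2, as at pH 7);
#' NAD+ carries the pyridinium N1N (no H), NADH the 1,4-dihydro ring with
#' two hydrogens at C4N, and each ox species a single carbonyl oxygen at
#' the oxidized ring carbon. Atom counts are 70 for NAD+ and the ox
#' species and 71 for NADH.
#'
#' @param species One of `nad_species()`.
#' @return An object of class `nad_topology`.
#' @export
build_topology <- function(species) {
  species <- match.arg(species, nad_species())
  if (!is.null(.topology_cache[[species]]))
    return(.topology_cache[[species]])
  names <- species_atom_names(species)
  el <- element_of(names)
  atoms <- data.frame(
    name = names, element = el, mass = unname(ATOMIC_MASS[el]),
    stringsAsFactors = FALSE
  )
  bonds <- species_bonds(species)
  rot <- lapply(rotatable_bond_table(), function(q) {
    list(
      dihedral = q,
      bond = q[2:3],
      moving = subtree_atoms(bonds, q[2], q[3], q[3])
    )
  })
  top <- structure(
    list(
      species = species,
      atoms = atoms,
      bonds = bonds,
      rings = list(
        nicotinamide = c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N"),
        adenine = c("N9A", "C8A", "N7A", "C5A", "C6A", "N1A", "C2A",
                    "N3A", "C4A")
      ),
      rotatable = rot
    ),
    class = "nad_topology"
  )
  .topology_cache[[species]] <- top
  top
}

#' Heavy (non-hydrogen) atom names of a topology
#' @param topology A `nad_topology`.
#' @return Character vector.
#' @export
heavy_atoms <- function(topology) {
  topology$atoms$name[topology$atoms$element != "H"]
}

#' @export
print.nad_topology <- function(x, ...) {
  cat("nad_topology:", x$species, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

#' Bind coordinates to a topology
#' @param topology A `nad_topology`.
#' @param xyz Numeric matrix, one row per atom, 3 columns, Angstroms. Row
#'   order must follow `topology$atoms$name`.
#' @return An object of class `nad_conformer`.
#' @export
nad_conformer <- function(topology, xyz) {
  stopifnot(inherits(topology, "nad_topology"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(topology$atoms))
    stop("coordinate count (", nrow(xyz), ") != atom count (",
         nrow(topology$atoms), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rownames(xyz) <- topology$atoms$name
  colnames(xyz) <- c("x", "y", "z")
  structure(list(topology = topology, xyz = xyz), class = "nad_conformer")
}

#' Coordinates of a conformer as a named matrix
#' @param conformer A `nad_conformer`.
#' @return Numeric matrix with atom-name rownames.
#' @export
conformer_xyz <- function(conformer) conformer$xyz

#' @export
print.nad_conformer <- function(x, ...) {
  cat("nad_conformer:", x$topology$species, "-", nrow(x$xyz), "atoms\n")
  invisible(x)
}

# ---- atom-name mapping -----------------------------------------------------

# wwPDB chemical-component naming (components NAD and NAI): the adenosine
# ribose uses suffix B, the nicotinamide ribose suffix D, primes dropped.
paper_to_component_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Z]+)([0-9]*)('{1,2})([AN])$", name))[[1]]
  if (length(m)) {
    suffix <- if (m[5] == "A") "B" else "D"
    prime2 <- if (m[4] == "''") "2" else if (m[2] == "H" && m[3] == "5") "1" else ""
    # H5'A -> H51B, H5''A -> H52B; heavy atoms keep just the digit: C1'A -> C1B
    if (m[2] == "HO") return(paste0("HO", m[3], suffix))
    if (substr(m[2], 1, 1) == "H")
      return(paste0(m[2], m[3], prime2, suffix))
    return(paste0(m[2], m[3], suffix))
  }
  name
}

#' Atom-name map between analysis names and component-dictionary names
#'
#' Analysis names carry a prime and an A/N suffix (e.g. O4'N); the wwPDB
#' components NAD and NAI name the adenosine ribose with suffix B and the
#' nicotinamide ribose with suffix D (O4'N -> O4D). Non-ribose names
#' coincide. The map is bijective over all atoms of the species.
#'
#' @param species One of `nad_species()`.
#' @return data.frame with columns `paper` and `component`.
#' @export
atom_name_map <- function(species = "NAD_plus") {
  paper <- species_atom_names(species)
  comp <- vapply(paper, paper_to_component_name, "", USE.NAMES = FALSE)
  if (anyDuplicated(comp))
    stop("internal error: component-name map not bijective")
  data.frame(paper = paper, component = comp, stringsAsFactors = FALSE)
}

#' Translate atom names between the two naming schemes
#'
#' @param names Character vector of atom names to translate.
#' @param direction "component_to_paper" (default) or "paper_to_component".
#' @param species Species whose map to use.
#' @return Character vector of translated names.
#' @export
map_atom_names <- function(names,
                           direction = c("component_to_paper",
                                         "paper_to_component"),
                           species = "NAD_plus") {
  direction <- match.arg(direction)
  map <- atom_name_map(species)
  from <- if (direction == "component_to_paper") map$component else map$paper
  to <- if (direction == "component_to_paper") map$paper else map$component
  i <- match(names, from)
  if (anyNA(i))
    stop("unknown atom name(s): ", paste(names[is.na(i)], collapse = ", "))
  to[i]
}

# ---- plain-text serialization ---------------------------------------------

#' Write a topology to a plain-text file
#'
#' Atom table followed by the bond list, both tab-delimited.
#' @param topology A `nad_topology`.
#' @param path Output file path.
#' @export
write_topology_file <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nad_topology\t", topology$species), con)
  writeLines(paste0("# atoms\t", nrow(topology$atoms)), con)
  utils::write.table(topology$atoms, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0("# bonds\t", nrow(topology$bonds)), con)
  utils::write.table(as.data.frame(topology$bonds), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
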