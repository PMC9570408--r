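# Synthetic mining fixtures: small, syntactically valid mmCIF entries
# embedding a protein stub and NAD/NAI ligand instance(s), together with
# a manifest stating which entries must survive the dataset filters.
# Everything is generated in code (seeded) — no deposited coordinates are
# used or imitated.

#' Template conformer adjusted to an exact inter-base distance
#'
#' Solves one backbone torsion (zeta_A, falling back to alpha_N) so that
#' the inter-base centroid distance equals `target` to 1e-6 Angstroms.
#'
#' @param species One of `nad_species()`.
#' @param target Target inter-base distance, Angstroms.
#' @param params Extra template parameter overrides.
#' @return A `nad_conformer` with `interbase_distance()` == target.
#' @export
template_with_d <- function(species, target, params = list()) {
  for (knob in c("zeta_A", "alpha_N", "beta_N")) {
    f <- function(z) {
      p <- utils::modifyList(params, stats::setNames(list(z), knob))
      interbase_distance(build_template(species, p)) - target
    }
    grid <- seq(-180, 180, by = 10)
    fv <- vapply(grid, f, 0)
    br <- which(fv[-1] * fv[-length(fv)] <= 0)
    if (length(br)) {
      z <- stats::uniroot(f, c(grid[br[1]], grid[br[1] + 1]),
                          tol = 1e-9)$root
      p <- utils::modifyList(params, stats::setNames(list(z), knob))
      return(build_template(species, p))
    }
  }
  stop("target inter-base distance ", target, " A not reachable")
}

# A small poly-alanine stub placed beyond `offset` Angstroms from the
# ligand along +x. Full backbone (N, CA, C, O, CB) or CA-only.
protein_stub <- function(n_res = 4, calpha_only = FALSE, offset = c(25, 0, 0)) {
  rows <- list()
  for (r in seq_len(n_res)) {
    base <- offset + c(3.8 * (r - 1), 0, 0)
    at <- if (calpha_only) {
      list(CA = base)
    } else {
      list(N = base + c(-1.2, 0.6, 0), CA = base,
           C = base + c(1.3, 0.5, 0), O = base + c(1.4, 1.7, 0),
           CB = base + c(0.1, -1.0, 1.0))
    }
    for (nm in names(at)) {
      rows[[length(rows) + 1]] <- data.frame(
        group_PDB = "ATOM", type_symbol = substr(nm, 1, 1),
        label_atom_id = nm, label_alt_id = ".", label_comp_id = "ALA",
        label_asym_id = "A", auth_seq_id = r,
        x = at[[nm]][1], y = at[[nm]][2], z = at[[nm]][3],
        occupancy = 1, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

ligand_site_rows <- function(conformer, comp, asym = "B", seq_id = 101) {
  top <- conformer$topology
  nm <- map_atom_names(top$atoms$name, "paper_to_component", top$species)
  data.frame(
    group_PDB = "HETATM", type_symbol = top$atoms$element,
    label_atom_id = nm, label_alt_id = ".", label_comp_id = comp,
    label_asym_id = asym, auth_seq_id = seq_id,
    x = conformer$xyz[, 1], y = conformer$xyz[, 2], z = conformer$xyz[, 3],
    occupancy = 1, stringsAsFactors = FALSE
  )
}

write_fixture_cif <- function(path, id, method, resolution, site,
                              covalent = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", id),
    paste0("_entry.id ", id),
    paste0("_exptl.method '", method, "'"),
    sprintf("_refine.ls_d_res_high %.2f", resolution)
  ), con)
  if (covalent) {
    writeLines(c(
      "loop_",
      "_struct_conn.id",
      "_struct_conn.conn_type_id",
      "_struct_conn.ptnr1_label_comp_id",
      "_struct_conn.ptnr2_label_comp_id",
      "covale1 covale ALA NAD"
    ), con)
  }
  writeLines(c(
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy"
  ), con)
  lines <- sprintf("%s %d %s %s %s %s %s %d %.3f %.3f %.3f %.2f",
                   site$group_PDB, seq_len(nrow(site)), site$type_symbol,
                   site$label_atom_id, site$label_alt_id,
                   site$label_comp_id, site$label_asym_id, site$auth_seq_id,
                   site$x, site$y, site$z, site$occupancy)
  writeLines(lines, con)
  invisible(path)
}

#' Default fixture set specification
#'
#' Covers the filter boundary cases: resolutions 2.8 / 2.9 (kept,
#' inclusive cutoff) / 3.0 (dropped), one C-alpha-only entry, one entry
#' with a declared covalent link, one non-X-ray entry, and both NAD and
#' NAI components; one entry carries two ligand copies.
#'
#' @return data.frame fixture specification.
#' @export
default_fixture_spec <- function() {
  data.frame(
    id = c("SYN1", "SYN2", "SYN3", "SYN4", "SYN5", "SYN6", "SYN7"),
    resolution = c(2.8, 2.9, 3.0, 2.0, 2.5, 2.5, 2.2),
    method = c(rep("X-RAY DIFFRACTION", 6), "SOLUTION NMR"),
    ligand = c("NAD", "NAD", "NAD", "NAI", "NAD", "NAD", "NAI"),
    n_copies = c(1, 1, 1, 2, 1, 1, 1),
    calpha_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    covalent = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate a mining fixture set
#'
#' Writes one mmCIF file per specified entry into `dir` plus a
#' tab-delimited manifest stating which entries must survive filtering
#' (X-ray, resolution <= 2.9 A, full protein model, noncovalent ligand)
#' and why the others are dropped. Ligand conformers are extended
#' template conformers with seeded torsion jitter.
#'
#' @param dir Output directory (created if absent).
#' @param spec Fixture specification (see `default_fixture_spec()`).
#' @param seed Integer seed for the ligand conformer jitter.
#' @return The manifest data.frame (also written to
#'   `file.path(dir, "manifest.tsv")`), with a `path` column.
#' @export
make_mining_fixtures <- function(dir, spec = default_fixture_spec(),
                                 seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  manifest <- spec
  manifest$keep <- with(spec, grepl("x-ray", method, ignore.case = TRUE) &
                          resolution <= 2.9 & !calpha_only & !covalent)
  manifest$reason <- ifelse(manifest$keep, "",
    ifelse(!grepl("x-ray", spec$method, ignore.case = TRUE), "not_xray",
    ifelse(spec$resolution > 2.9, "resolution",
    ifelse(spec$calpha_only, "calpha_only", "covalent"))))
  manifest$path <- file.path(dir, paste0(spec$id, ".cif"))
  for (k in seq_len(nrow(spec))) {
    species <- component_species(spec$ligand[k])
    site <- protein_stub(calpha_only = spec$calpha_only[k])
    for (cp in seq_len(spec$n_copies[k])) {
      conf <- build_template(species, list(
        chi_N = wrap_angle(-160 + stats::rnorm(1, 0, 15)),
        chi_A = wrap_angle(-110 + stats::rnorm(1, 0, 15)),
        theta = wrap_angle(180 + stats::rnorm(1, 0, 15)),
        zeta_A = stats::runif(1, 150, 210)
      ))
      site <- rbind(site, ligand_site_rows(conf, spec$ligand[k],
                                           asym = LETTERS[1 + cp],
                                           seq_id = 100 + cp))
    }
    write_fixture_cif(manifest$path[k], spec$id[k], spec$method[k],
                      spec$resolution[k], site,
                      covalent = spec$covalent[k])
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
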