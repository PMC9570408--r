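# Multi-model PDB output/input for conformer ensembles. Atom names are
# written in component-dictionary style (NAD/NAI conventions; suffix B =
# adenosine ribose, D = nicotinamide ribose). Coordinates round-trip at
# PDB precision (1e-3 Angstroms).

species_component_id <- function(species) {
  switch(species, NAD_plus = "NAD", NADH = "NAI",
         ox2_NAD = "OX2", ox4_NAD = "OX4", ox6_NAD = "OX6")
}

component_species <- function(comp) {
  switch(comp, NAD = "NAD_plus", NAI = "NADH",
         OX2 = "ox2_NAD", OX4 = "ox4_NAD", OX6 = "ox6_NAD",
         stop("unknown component id: ", comp))
}

format_pdb_atom <- function(serial, name, resname, chain, resno, xyz,
                            element, hetatm = TRUE) {
  # PDB v3 name justification: element starts in column 14 for 1-2 char
  # names unless the name is 4 characters long
  nm <- if (nchar(name) >= 4) substr(name, 1, 4)
        else paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetatm) "HETATM" else "ATOM", serial, nm, resname, chain,
          resno, xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

write_model_atoms <- function(con, xyz, names_out, resname, elements,
                              serial0 = 0L, chain = "A", resno = 1L) {
  lines <- vapply(seq_len(nrow(xyz)), function(i) {
    format_pdb_atom(serial0 + i, names_out[i], resname, chain, resno,
                    xyz[i, ], elements[i])
  }, "")
  writeLines(lines, con)
}

#' Write a single conformer to a PDB file
#'
#' One HETATM record per atom, component-dictionary atom names.
#' @param conformer A `nad_conformer`.
#' @param path Output path.
#' @param remarks Optional character vector written as REMARK records.
#' @export
write_conformer_pdb <- function(conformer, path, remarks = character(0)) {
  top <- conformer$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (r in remarks) writeLines(paste("REMARK 300", r), con)
  names_out <- map_atom_names(top$atoms$name, "paper_to_component",
                              top$species)
  write_model_atoms(con, conformer$xyz, names_out,
                    species_component_id(top$species), top$atoms$element)
  writeLines("END", con)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; species, time-per-frame and
#' replicate id are recorded as REMARK 300 lines.
#'
#' @param ensemble A `nad_ensemble`.
#' @param path Output path.
#' @export
write_multimodel_pdb <- function(ensemble, path) {
  top <- ensemble$topology
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("REMARK 300 SPECIES", top$species),
    paste("REMARK 300 TIME_PER_FRAME_PS", ensemble$time_per_frame),
    paste("REMARK 300 REPLICATE",
          paste(unique(ensemble$replicate), collapse = " "))
  ), con)
  names_out <- map_atom_names(top$atoms$name, "paper_to_component",
                              top$species)
  for (i in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    write_model_atoms(con, ensemble$coords[, , i], names_out,
                      species_component_id(top$species), top$atoms$element)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

parse_pdb_atom_lines <- function(lines) {
  data.frame(
    name = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE
  )
}

#' Read a multi-model PDB file as an ensemble
#'
#' Models are split on MODEL/ENDMDL records; a file without MODEL records
#' is treated as a single frame. Atom names are translated back from
#' component-dictionary style; a model whose atom count does not match
#' the species topology is a parse error naming the model.
#'
#' @param path Input path.
#' @param species Species expected in the file; default is taken from the
#'   REMARK header (or the residue name).
#' @return A `nad_ensemble` (without labels).
#' @export
read_multimodel_pdb <- function(path, species = NULL) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no atom records in ", path)
  if (is.null(species)) {
    hdr <- grep("^REMARK 300 SPECIES ", lines, value = TRUE)
    species <- if (length(hdr)) sub("^REMARK 300 SPECIES ", "", hdr[1])
               else component_species(trimws(substr(lines[is_atom][1], 18, 20)))
  }
  top <- build_topology(species)
  tpf_line <- grep("^REMARK 300 TIME_PER_FRAME_PS ", lines, value = TRUE)
  tpf <- if (length(tpf_line))
    as.numeric(sub("^REMARK 300 TIME_PER_FRAME_PS ", "", tpf_line[1])) else 1
  rep_line <- grep("^REMARK 300 REPLICATE ", lines, value = TRUE)
  rep_id <- if (length(rep_line))
    as.integer(strsplit(sub("^REMARK 300 REPLICATE ", "", rep_line[1]),
                        " ")[[1]])[1] else 1L
  model_starts <- grep("^MODEL", lines)
  n_at <- nrow(top$atoms)
  if (!length(model_starts)) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  coords <- array(NA_real_, dim = c(n_at, 3, length(blocks)))
  for (m in seq_along(blocks)) {
    at <- parse_pdb_atom_lines(lines[blocks[[m]]])
    if (nrow(at) != n_at)
      stop("model ", m, ": expected ", n_at, " atoms, found ", nrow(at),
           " (near line ", blocks[[m]][1], ")")
    paper <- map_atom_names(at$name, "component_to_paper", species)
    i <- match(top$atoms$name, paper)
    if (anyNA(i))
      stop("model ", m, ": missing atom(s) ",
           paste(top$atoms$name[is.na(i)], collapse = ", "))
    coords[, , m] <- as.matrix(at[i, c("x", "y", "z")])
  }
  nad_ensemble(top, coords, tpf, rep_id)
}
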