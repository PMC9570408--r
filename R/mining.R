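# Mining of protein-bound NAD(H) ligand conformations from structure
# files. The selection criteria: X-ray entries at resolution <= 2.9 A
# (inclusive) containing at least one NAD (NAD+) or NAI (NADH) ligand
# noncovalently bound to the protein; entries whose protein is modeled as
# C-alpha only are dropped. A minimal mmCIF reader covers the categories
# the fixture generator emits; full-coordinate PDB-format entries go
# through the multi-model reader.

LIGAND_COMPONENTS <- c("NAD", "NAI")

# ---- minimal mmCIF parsing -------------------------------------------------

# Parses key-value pairs and loop_ blocks of an mmCIF file into a list of
# per-category data.frames. Handles quoted values; not a general STAR
# parser — covers the subset mining entries use.
read_mmcif <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  i <- 1
  split_tokens <- function(s) {
    m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", s)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    gsub("^['\"]|['\"]$", "", toks)
  }
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^data_", ln)) {
      out$data_block <- sub("^data_", "", ln)
      i <- i + 1
    } else if (ln == "loop_") {
      i <- i + 1
      cols <- character(0)
      while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
        cols <- c(cols, trimws(lines[i]))
        i <- i + 1
      }
      cat_name <- sub("\\..*$", "", sub("^_", "", cols[1]))
      fields <- sub("^_[^.]+\\.", "", cols)
      rows <- list()
      while (i <= length(lines) &&
             !grepl("^(_|loop_|data_)", trimws(lines[i]))) {
        rows[[length(rows) + 1]] <- split_tokens(trimws(lines[i]))
        i <- i + 1
      }
      if (length(rows)) {
        mat <- do.call(rbind, rows)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- fields
        out[[cat_name]] <- df
      }
    } else if (grepl("^_", ln)) {
      toks <- split_tokens(ln)
      key <- toks[1]
      cat_name <- sub("\\..*$", "", sub("^_", "", key))
      field <- sub("^_[^.]+\\.", "", key)
      val <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else NA
      if (is.null(out[[cat_name]])) out[[cat_name]] <- list()
      out[[cat_name]][[field]] <- val
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  out
}

#' Read one structure entry for mining
#'
#' Parses a (minimal) mmCIF file into a mining entry: id, experimental
#' method, resolution, the polymer atom records, the NAD/NAI ligand
#' instances, and any declared covalent links to the polymer.
#'
#' @param path Path to an mmCIF file.
#' @return List of class `mining_entry`.
#' @export
read_mining_entry <- function(path) {
  cif <- read_mmcif(path)
  atoms <- cif$atom_site
  if (is.null(atoms)) stop("no atom_site records in ", path)
  num <- function(x) suppressWarnings(as.numeric(x))
  atoms$Cartn_x <- num(atoms$Cartn_x)
  atoms$Cartn_y <- num(atoms$Cartn_y)
  atoms$Cartn_z <- num(atoms$Cartn_z)
  atoms$occupancy <- if ("occupancy" %in% names(atoms))
    num(atoms$occupancy) else 1
  if (!"label_alt_id" %in% names(atoms)) atoms$label_alt_id <- "."
  res_raw <- cif$refine$ls_d_res_high
  method <- cif$exptl$method
  covalent_ligand <- FALSE
  if (!is.null(cif$struct_conn)) {
    sc <- cif$struct_conn
    lig_in_conn <- sc$ptnr1_label_comp_id %in% LIGAND_COMPONENTS |
      sc$ptnr2_label_comp_id %in% LIGAND_COMPONENTS
    covalent_ligand <- any(grepl("covale", sc$conn_type_id, ignore.case = TRUE)
                           & lig_in_conn)
  }
  structure(
    list(
      id = if (!is.null(cif$entry$id)) cif$entry$id else cif$data_block,
      method = if (!is.null(method)) method else NA_character_,
      resolution = if (!is.null(res_raw)) num(res_raw) else NA_real_,
      atoms = atoms,
      declared_covalent = covalent_ligand,
      path = path
    ),
    class = "mining_entry"
  )
}

#' Download mmCIF entries from the wwPDB archive
#'
#' Thin fetch layer for live mining runs; everything downstream
#' (`read_mining_entry()`, `filter_entries()`, `mine_metrics()`) is
#' file-based, so analyses are reproducible offline from the downloaded
#' files or from generated fixtures. Requires network access; never
#' called by the test-suite or the bundled analyses.
#'
#' @param ids Character vector of 4-character entry ids.
#' @param dir Download directory.
#' @param base_url Archive URL template.
#' @return Paths of the downloaded files.
#' @export
fetch_pdb_entries <- function(ids, dir,
                              base_url = "https://files.rcsb.org/download") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(ids, function(id) {
    dest <- file.path(dir, paste0(tolower(id), ".cif"))
    if (!file.exists(dest))
      utils::download.file(sprintf("%s/%s.cif", base_url, toupper(id)),
                           dest, quiet = TRUE)
    dest
  }, "")
}

entry_polymer <- function(entry) {
  entry$atoms[entry$atoms$group_PDB == "ATOM", , drop = FALSE]
}

entry_ligand_atoms <- function(entry) {
  entry$atoms[entry$atoms$group_PDB == "HETATM" &
              entry$atoms$label_comp_id %in% LIGAND_COMPONENTS, ,
              drop = FALSE]
}

# entry is C-alpha-only when every polymer chain has > `frac` of its
# residues represented solely by the alpha carbon
is_calpha_only <- function(entry, frac = 0.95) {
  poly <- entry_polymer(entry)
  if (!nrow(poly)) return(FALSE)
  res <- split(poly$label_atom_id,
               paste(poly$label_asym_id, poly$auth_seq_id))
  ca_only <- vapply(res, function(a) length(a) == 1 && a == "CA", TRUE)
  mean(ca_only) > frac
}

# covalent if declared in struct_conn, or any ligand heavy atom sits
# within `cutoff` (1.8 A) of a polymer heavy atom
has_covalent_geometry <- function(entry, lig_atoms, cutoff = 1.8) {
  poly <- entry_polymer(entry)
  poly <- poly[poly$type_symbol != "H", , drop = FALSE]
  lig <- lig_atoms[lig_atoms$type_symbol != "H", , drop = FALSE]
  if (!nrow(poly) || !nrow(lig)) return(FALSE)
  P <- as.matrix(poly[, c("Cartn_x", "Cartn_y", "Cartn_z")])
  L <- as.matrix(lig[, c("Cartn_x", "Cartn_y", "Cartn_z")])
  for (i in seq_len(nrow(L))) {
    if (any(rowSums(sweep(P, 2, L[i, ])^2) < cutoff^2)) return(TRUE)
  }
  FALSE
}

#' Filter mining entries by the dataset criteria
#'
#' Keeps entries that are X-ray, at resolution <= `max_resolution`
#' (inclusive), not C-alpha-only, and contain at least one noncovalently
#' bound NAD/NAI instance. Entries with missing metadata are routed to
#' the rejects table with a reason code rather than erroring.
#'
#' @param entries List of `mining_entry` objects.
#' @param max_resolution Resolution cutoff, Angstroms (default 2.9).
#' @return List with `kept` (entries) and `rejects` (data.frame of id +
#'   reason codes).
#' @export
filter_entries <- function(entries, max_resolution = 2.9) {
  reasons <- character(0)
  ids <- character(0)
  kept <- list()
  for (e in entries) {
    reason <- NULL
    if (is.na(e$method) || is.na(e$resolution)) {
      reason <- "missing_metadata"
    } else if (!grepl("x-ray", e$method, ignore.case = TRUE)) {
      reason <- "not_xray"
    } else if (e$resolution > max_resolution) {
      reason <- "resolution"
    } else if (is_calpha_only(e)) {
      reason <- "calpha_only"
    } else if (!nrow(entry_ligand_atoms(e))) {
      reason <- "no_ligand"
    } else if (!length(extract_instances(e))) {
      reason <- "no_noncovalent_ligand"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1]] <- e
    } else {
      ids <- c(ids, e$id)
      reasons <- c(reasons, reason)
    }
  }
  list(kept = kept,
       rejects = data.frame(id = ids, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Extract noncovalent ligand instances from an entry
#'
#' Each NAD/NAI residue becomes one instance; alternate locations are
#' resolved to the highest-occupancy conformer (ties break to the
#' alphabetically first alt-id); atom names are translated to analysis
#' names. Instances with missing atoms are retained — downstream metrics
#' are computed per-metric and flagged NA where atoms are absent.
#'
#' @param entry A `mining_entry`.
#' @return List of instances: each has entry id, instance id, component
#'   id, species, and a named coordinate matrix.
#' @export
extract_instances <- function(entry) {
  lig <- entry_ligand_atoms(entry)
  if (!nrow(lig)) return(list())
  inst_key <- paste(lig$label_asym_id, lig$auth_seq_id, lig$label_comp_id)
  out <- list()
  for (key in unique(inst_key)) {
    at <- lig[inst_key == key, , drop = FALSE]
    if (entry$declared_covalent || has_covalent_geometry(entry, at)) next
    # resolve altlocs: keep '.'/'A'-style best-occupancy set per atom
    if (any(at$label_alt_id != ".")) {
      keep <- unlist(lapply(split(seq_len(nrow(at)), at$label_atom_id),
        function(ix) {
          sub <- at[ix, ]
          ord <- order(-sub$occupancy, sub$label_alt_id)
          ix[ord[1]]
        }))
      at <- at[sort(keep), , drop = FALSE]
    }
    comp <- at$label_comp_id[1]
    species <- component_species(comp)
    map <- atom_name_map(species)
    known <- at$label_atom_id %in% map$component
    at <- at[known, , drop = FALSE]
    xyz <- as.matrix(at[, c("Cartn_x", "Cartn_y", "Cartn_z")])
    rownames(xyz) <- map_atom_names(at$label_atom_id, "component_to_paper",
                                    species)
    colnames(xyz) <- c("x", "y", "z")
    out[[length(out) + 1]] <- list(
      entry = entry$id, instance = key, component = comp,
      species = species, xyz = xyz
    )
  }
  out
}

# per-instance metrics from a possibly incomplete coordinate set; each
# metric is NA when any required atom is missing (per-metric flagging,
# instances are never dropped wholesale)
instance_metrics <- function(inst) {
  xyz <- inst$xyz
  have <- rownames(xyz)
  ring_n <- c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N")
  ring_a <- c("N9A", "C8A", "N7A", "C5A", "C6A", "N1A", "C2A", "N3A", "C4A")
  cen <- function(ring) if (all(ring %in% have))
    colMeans(xyz[ring, , drop = FALSE]) else NULL
  cn <- cen(ring_n); ca <- cen(ring_a)
  d <- if (!is.null(cn) && !is.null(ca)) vnorm(cn - ca) else NA_real_
  dih <- function(q) {
    if (all(q %in% have))
      dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    else NA_real_
  }
  defs <- dihedral_definitions()
  data.frame(
    entry = inst$entry, instance = inst$instance,
    component = inst$component,
    d = d,
    chi_A = dih(defs$chi_A), chi_N = dih(defs$chi_N),
    theta = dih(defs$theta), nu2 = dih(defs$nu2),
    stringsAsFactors = FALSE
  )
}

#' Conformational metrics over mined ligand instances
#'
#' One row per instance (inter-base distance d, chi_A, chi_N, theta,
#' nu2; NA where the required atoms are missing), plus the aggregate mean
#' and sample SD of d, a histogram of d, and the theta-vs-chi_N scatter
#' table.
#'
#' @param instances List of instances from `extract_instances()`.
#' @param bin_width Histogram bin width, Angstroms.
#' @return List of class `mining_table`: `table`, `d_mean`, `d_sd`
#'   (NA for a single instance), `histogram`, `scatter`.
#' @export
mine_metrics <- function(instances, bin_width = 0.5) {
  if (!length(instances)) stop("no ligand instances to mine")
  tab <- do.call(rbind, lapply(instances, instance_metrics))
  dd <- tab$d[!is.na(tab$d)]
  hist <- replicate_histogram(dd, rep(1L, length(dd)),
                              bin_width = bin_width, range = c(0, 20))
  structure(
    list(table = tab,
         d_mean = mean(dd),
         d_sd = if (length(dd) > 1) stats::sd(dd) else NA_real_,
         histogram = hist,
         scatter = data.frame(chi_N = tab$chi_N, theta = tab$theta)),
    class = "mining_table"
  )
}

#' @export
print.mining_table <- function(x, ...) {
  cat("mining_table:", nrow(x$table), "instance(s); d mean",
      round(x$d_mean, 2), "A, SD",
      if (is.na(x$d_sd)) "undefined (n=1)" else round(x$d_sd, 2), "\n")
  invisible(x)
}
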