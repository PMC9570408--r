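# End-to-end orchestration: a run configuration (species, ensemble spec,
# classification windows, histogram/clustering settings, seed) drives
# simulate -> analyze -> report. Every output table carries the
# serialized configuration (and its hash) in comment headers, so a rerun
# with the same configuration is byte-identical.

#' Assemble a run configuration
#'
#' @param species One of `nad_species()`.
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param n_frames,n_replicates Ensemble size per replicate / replicates.
#' @param windows Classification windows.
#' @param bin_width Histogram bin width, Angstroms.
#' @param cluster_cutoff RMSD cluster cutoff, Angstroms.
#' @param cluster_spacing_ns Minimum time separation of cluster frames, ns.
#' @param cluster_max Maximum cluster frames.
#' @param output_dir Output directory for report files.
#' @return List of class `run_config`.
#' @export
run_config <- function(species, seed, n_frames = 200, n_replicates = 5,
                       windows = classification_windows(), bin_width = 0.5,
                       cluster_cutoff = 1.0, cluster_spacing_ns = 5,
                       cluster_max = 10, output_dir = tempfile("nadfold_")) {
  structure(
    list(species = match.arg(species, nad_species()), seed = as.integer(seed),
         n_frames = n_frames, n_replicates = n_replicates, windows = windows,
         bin_width = bin_width, cluster_cutoff = cluster_cutoff,
         cluster_spacing_ns = cluster_spacing_ns, cluster_max = cluster_max,
         output_dir = output_dir),
    class = "run_config"
  )
}

# 31-bit polynomial rolling hash over the serialized configuration text
# (provenance stamp only, not cryptographic)
config_hash <- function(config) {
  txt <- paste(format_config(config), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a run configuration as plain text
#' @param config A `run_config`.
#' @return Character vector of key = value lines.
#' @export
format_config <- function(config) {
  c(paste("species =", config$species),
    paste("seed =", config$seed),
    paste("n_frames =", config$n_frames),
    paste("n_replicates =", config$n_replicates),
    paste("bin_width =", config$bin_width),
    paste("cluster_cutoff =", config$cluster_cutoff),
    paste("cluster_spacing_ns =", config$cluster_spacing_ns),
    paste("cluster_max =", config$cluster_max),
    format_windows(config$windows))
}

write_report_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", c(paste("config_hash =", config_hash(config)),
                          format_config(config))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Samples a labeled synthetic ensemble for the configured species,
#' concatenates the replicates, computes per-frame metrics and state
#' assignments, the replicate-averaged inter-base distance histogram,
#' the H-bond fold tally, folded events, representative frames and an
#' RMSD cluster around the most common folded frame, and writes each
#' result as a delimited table under `config$output_dir`.
#'
#' @param config A `run_config`.
#' @return Invisible list with every in-memory result (`ensemble`,
#'   `metrics`, `states`, `fractions`, `histogram`, `tally`, `events`,
#'   `representatives`, `cluster`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- ensemble_spec(config$species, n_frames = config$n_frames,
                        n_replicates = config$n_replicates,
                        seed = config$seed)
  reps <- sample_ensemble(spec)
  ens <- concatenate_replicates(reps)
  metrics <- ensemble_metrics(ens)
  states <- classify_states(metrics, config$windows)
  fractions <- state_fractions(states$foldedness)
  hist <- replicate_histogram(metrics$d, metrics$replicate,
                              bin_width = config$bin_width)
  tally <- track_fold_bins(metrics)
  events <- detect_folded_events(metrics)
  repr <- select_representative_frames(metrics, tally, hist, config$windows)
  cluster <- integer(0)
  if (length(repr$folded)) {
    ref <- get_frame(ens, repr$folded[1])
    cluster <- cluster_by_rmsd(ens, ref, config$cluster_cutoff,
                               config$cluster_spacing_ns, config$cluster_max)
  }
  files <- c(
    metrics = write_report_table(cbind(metrics, states),
                                 file.path(config$output_dir, "metrics.tsv"),
                                 config),
    histogram = write_report_table(
      data.frame(mid = hist$mid, mean = hist$mean, sd = hist$sd),
      file.path(config$output_dir, "histogram_d.tsv"), config),
    fractions = write_report_table(
      data.frame(state = names(fractions), fraction = as.numeric(fractions)),
      file.path(config$output_dir, "state_fractions.tsv"), config),
    tally = write_report_table(
      data.frame(bin = names(tally$counts),
                 count = as.integer(tally$counts),
                 most_prevalent = names(tally$counts) == tally$most_prevalent),
      file.path(config$output_dir, "fold_tally.tsv"), config),
    selections = write_report_table(
      data.frame(
        class = c(rep("folded", length(repr$folded)),
                  rep("semi_extended", length(repr$semi_extended)),
                  rep("extended", length(repr$extended)),
                  rep("cluster", length(cluster)),
                  rep("folded_event", length(events))),
        frame = c(repr$folded, repr$semi_extended, repr$extended,
                  cluster, events)),
      file.path(config$output_dir, "selections.tsv"), config)
  )
  # representative conformers as single-model PDB files
  for (cls in c("folded", "semi_extended", "extended")) {
    idx <- repr[[cls]]
    if (length(idx)) {
      write_conformer_pdb(
        get_frame(ens, idx[1]),
        file.path(config$output_dir, paste0("representative_", cls, ".pdb")),
        remarks = c(paste("CLASS", cls), paste("FRAME", idx[1]),
                    paste("CONFIG", config_hash(config))))
    }
  }
  invisible(list(ensemble = ens, metrics = metrics, states = states,
                 fractions = fractions, histogram = hist, tally = tally,
                 events = events, representatives = repr, cluster = cluster,
                 files = files))
}
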