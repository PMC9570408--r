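#!/usr/bin/env Rscript
# Sample synthetic replicate ensembles for all five species using the
# per-species default compositions (trimodal foldedness, syn/anti,
# pucker, amide) and store them as multi-model PDB trajectories plus
# ground-truth label tables.

suppressPackageStartupMessages(library(nadfold))
dir.create("results/ensembles", recursive = TRUE, showWarnings = FALSE)

seed0 <- 20220 # base seed; per-species offsets keep streams distinct
n_frames <- 200
n_replicates <- 5

for (sp in nad_species()) {
  spec <- ensemble_spec(sp, n_frames = n_frames,
                        n_replicates = n_replicates,
                        seed = seed0 + match(sp, nad_species()))
  reps <- sample_ensemble(spec)
  labels <- list()
  for (r in seq_along(reps)) {
    write_multimodel_pdb(
      reps[[r]],
      file.path("results/ensembles", sprintf("%s_rep%02d.pdb", sp, r)))
    labels[[r]] <- cbind(replicate = r,
                         frame = seq_len(n_frames),
                         reps[[r]]$labels)
  }
  lab <- do.call(rbind, labels)
  write.table(lab,
              file.path("results/ensembles", paste0(sp, "_labels.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sp, ": ", n_replicates, "x", n_frames, "frames;",
      "drawn foldedness composition:",
      paste(sprintf("%s %.2f", names(table(lab$mode)),
                    as.numeric(table(lab$mode)) / nrow(lab)),
            collapse = ", "), "\n")
}
cat("\nEnsembles written under results/ensembles/ (1 ps per frame).\n")
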