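#!/usr/bin/env Rscript
# Force-dependent measurement noise of floppy vs rigid linkers.
#
# Simulates force ramps of the conventional dsDNA linker and the rigid
# ten-helix-bundle linker in the dual-trap assay and compares the
# ensemble-averaged moving-window extension SD across the 1-10 pN working
# range. The rigid linker clamps the beads and suppresses the thermal
# noise precisely where protein conformational dynamics live.

suppressPackageStartupMessages(library(rigidlink))
dir.create("results", showWarnings = FALSE)

n_traces <- 50   # per arm; the reference ensemble size is 200

message("simulating ", n_traces, " pulls per linker system ...")
arms <- list(dsDNA = "dsDNA_linker", tenhelix = "tenhelix_linker")
profiles <- lapply(names(arms), function(nm) {
  cfg <- preset_config(arms[[nm]])
  cfg$step_size <- 3  # ~50% Metropolis acceptance
  prof <- ensemble_noise_sd(cfg, n_traces = n_traces, max_force = 12,
                            breaks = seq(1, 10, by = 0.5),
                            seed = match(nm, names(arms)) * 1000)
  names(prof)[2] <- paste0("sd_nm_", nm)
  prof
})
tab <- Reduce(function(a, b) merge(a, b, by = "force_mid"), profiles)
tab$suppression <- tab$sd_nm_dsDNA / tab$sd_nm_tenhelix

write.table(format(tab, digits = 4), "results/noise_vs_force.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("noise amplitude (nm) by mean force (pN):")
print(tab, digits = 3)
message(sprintf(
  "stiff-linker noise is below the dsDNA linker at every force bin: %s",
  all(tab$sd_nm_tenhelix < tab$sd_nm_dsDNA)))
message(sprintf("median suppression factor: %.2fx",
                median(tab$suppression)))
message("wrote results/noise_vs_force.tsv")
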