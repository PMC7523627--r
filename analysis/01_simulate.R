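#!/usr/bin/env Rscript
# Stage 1: simulate the spike-in experiment.
#
# Generates the default 20-species staggered community diluted with
# 0/10/90/99 % murine DNA (1e6 reads per sample), with host-associated and
# reagent contaminants plus Escherichia coli misassignment, and writes the
# species profile, the synthetic taxonomy and the full simulation config
# under results/analysis/.

suppressPackageStartupMessages(library(spikeval))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(depth = 1e6, seed = seed)
expt <- simulate_experiment(cfg)

write_sim_config(cfg, file.path(out, "sim_config.yaml"))
write_taxonomy_tsv(cfg$taxonomy, file.path(out, "taxonomy.tsv"))
write_profile_tsv(expt$profile, file.path(out, "profile.tsv"))
utils::write.table(
  data.frame(taxid = names(expt$truth$taxon_class),
             class = expt$truth$taxon_class, row.names = NULL),
  file.path(out, "truth_labels.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

tot <- colSums(expt$profile$counts)
message(sprintf("simulated %d samples x %d taxa at depth %g (seed %d)",
                ncol(expt$profile$counts), nrow(expt$profile$counts),
                cfg$depth, seed))
message(sprintf("host reads: %s",
                paste(sprintf("%s %d", names(tot),
                              expt$profile$counts[as.character(
                                cfg$design$host$taxid), ]),
                      collapse = ", ")))
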