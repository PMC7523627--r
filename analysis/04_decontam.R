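#!/usr/bin/env Rscript
# Stage 4: frequency-based contaminant identification and removal.
#
# Applies the frequency test (species frequency among microbial reads vs
# total microbial reads as the concentration proxy) to every microbial
# species, removes called contaminants, and reports removal statistics.

suppressPackageStartupMessages(library(spikeval))

out <- "results/analysis"
cfg <- read_sim_config(file.path(out, "sim_config.yaml"))
tax <- read_taxonomy_tsv(file.path(out, "taxonomy.tsv"))
profile <- read_profile_tsv(file.path(out, "profile.tsv"), tax)

lab <- label_taxa(profile, cfg$design$members$taxid,
                  cfg$design$host$taxid)
calls <- call_contaminants(profile, lab)
res <- filter_contaminants(profile, calls, lab)

calls_out <- calls
calls_out$score <- formatC(calls_out$score, format = "g", digits = 6)
utils::write.table(calls_out, file.path(out, "contaminant_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_profile_tsv(res$filtered, file.path(out, "filtered_profile.tsv"))

st <- res$stats
message(sprintf("%d species called contaminant at threshold %.2g",
                st$n_called, attr(calls, "threshold")))
message(sprintf("target species called contaminant: %d",
                sum(calls$call == "contaminant" &
                      calls$label == "target-species")))
message(sprintf("off-target reads removed: %s",
                paste(sprintf("%s %.3g", names(st$offtarget_reads_removed),
                              st$offtarget_reads_removed), collapse = ", ")))
message(sprintf("off-target species removed: %s",
                paste(sprintf("%s %.3g",
                              names(st$offtarget_species_removed),
                              st$offtarget_species_removed),
                      collapse = ", ")))
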