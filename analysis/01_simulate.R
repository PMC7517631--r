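#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-condition study.
#
# Emulates the study design: 5 patients, paired biopsies at pre-ischemia,
# ischemia and reperfusion; negative-binomial counts with a large flat
# background and four planted 4-fold trajectory classes; one planted gene
# set per class plus decoys. Stage seeds match run_pipeline(seed = 1).

library(somtraj)

outdir <- "results/simdata"
sim <- simulate_counts(seed = 102)
gs <- simulate_genesets(sim$truth, seed = 308)
write_simulation(sim, outdir, gs$sets)

message("samples: ", nrow(sim$design), " (", length(unique(sim$design$patient_id)),
        " patients x 3 conditions)")
message("transcripts: ", nrow(sim$counts$counts))
print(table(sim$truth$class))
message("gene sets: ", length(gs$sets), " (4 planted + ",
        length(gs$sets) - 4, " decoys)")
message("library sizes: ",
        paste(range(colSums(sim$counts$counts)), collapse = " - "))
message("written to ", outdir)
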