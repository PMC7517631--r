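#!/usr/bin/env Rscript
# Stage 4: batch SOM on the retained condition profiles, module summaries,
# condition-specific cluster selection, and recovery against the planted
# truth.

library(somtraj)

profiles <- read_tsv("results/profiles.tsv")
kept <- profiles[profiles$retained, c("transcript_id", "p_med", "i_med",
                                      "r_med")]
mat <- as.matrix(kept[, c("p_med", "i_med", "r_med")])
rownames(mat) <- kept$transcript_id

cfg <- som_config(seed = 212)   # 7 x 7 grid, default training schedule
model <- som_fit(mat, cfg)
n_modules <- cfg$rows * cfg$cols
message(sprintf("SOM: %d modules, %d empty, quantization error %.4f",
                n_modules, sum(tabulate(model$assignment, n_modules) == 0),
                quantization_error(model, mat)))

write_tsv(cbind(data.frame(module = seq_len(n_modules)),
                setNames(as.data.frame(model$codebook),
                         c("p_med", "i_med", "r_med"))),
          "results/som_codebook.tsv")
write_tsv(data.frame(transcript_id = names(model$assignment),
                     module = unname(model$assignment)),
          "results/som_assignment.tsv")
write_tsv(compute_umatrix(model)$pairs, "results/umatrix.tsv")

summaries <- summarize_modules(model$assignment, kept, n_modules)
asm <- assemble_clusters(summaries, model$assignment)
write_tsv(data.frame(
  label = names(asm$clusters),
  module_ids = vapply(asm$clusters, function(cl)
    paste(cl$module_ids, collapse = ","), character(1)),
  n_genes = vapply(asm$clusters, function(cl) cl$n_genes, integer(1))
), "results/clusters.tsv")
for (cl in asm$clusters) {
  message(sprintf("%s: modules {%s}, %d transcripts", cl$label,
                  paste(cl$module_ids, collapse = ","), cl$n_genes))
}
traj <- cluster_trajectory_report(asm$clusters, kept)
write_tsv(traj, "results/cluster_trajectories.tsv")
members <- do.call(rbind, lapply(asm$clusters, function(cl) {
  if (cl$n_genes == 0) return(NULL)
  data.frame(label = cl$label, transcript_id = cl$transcript_ids)
}))
write_tsv(members, "results/cluster_members.tsv")

truth <- read_tsv("results/simdata/truth.tsv")
recovery <- evaluate_recovery(asm$clusters, truth)
write_tsv(recovery, "results/recovery.tsv")
message("planted-class recovery:")
print(recovery)
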