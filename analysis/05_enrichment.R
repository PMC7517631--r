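#!/usr/bin/env Rscript
# Stage 5: gene-set over-representation per cluster (right-tail Fisher +
# BH within each cluster's family), against the measured-transcript
# universe.

library(somtraj)

sets <- read_gmt("results/simdata/sets.gmt")
profiles <- read_tsv("results/profiles.tsv")
universe <- profiles$transcript_id[profiles$retained]
members <- read_tsv("results/cluster_members.tsv")

clusters <- lapply(split(members$transcript_id, members$label),
                   function(tx) list(label = NA, module_ids = NA,
                                     transcript_ids = tx,
                                     n_genes = length(tx)))
for (lab in names(clusters)) clusters[[lab]]$label <- lab

enr <- enrich_clusters(clusters, sets, universe)
for (lab in names(enr)) {
  fn <- sprintf("results/enrichment_%s.tsv", lab)
  write_tsv(enr[[lab]], fn)
  top <- enr[[lab]][1, ]
  message(sprintf("%s: top set %s (k=%d/%d, adj p=%.3g), %d enriched at 0.05",
                  lab, top$set_name, top$k_overlap, top$m_set, top$adj_p,
                  sum(enr[[lab]]$enriched)))
}
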