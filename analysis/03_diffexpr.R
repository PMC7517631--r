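#!/usr/bin/env Rscript
# Stage 3: differential expression on the three condition comparisons,
# with the |log2 fold-change| >= 1 and p < 0.05 significance rule.

library(somtraj)

indir <- "results/simdata"
design <- read_design(file.path(indir, "design.tsv"))
cm <- quants_to_count_matrix(lapply(design$sample_id, function(sid) {
  read_quant_table(file.path(indir, paste0(sid, ".quant.sf")), sid)
}))

comparisons <- list(c("pre_ischemia", "ischemia"),
                    c("ischemia", "reperfusion"),
                    c("pre_ischemia", "reperfusion"))
sf <- size_factors(cm)
for (cmp in comparisons) {
  res <- nb_test(cm, design, group_a = cmp[1], group_b = cmp[2], sf = sf)
  degs <- select_degs(res)
  fn <- sprintf("results/de_%s_vs_%s.tsv", cmp[2], cmp[1])
  write_tsv(res[, c("feature_id", "mean_a", "mean_b", "log2_fc", "p_value",
                    "adj_p", "significant")], fn)
  message(sprintf("%s vs %s: %d DEGs (%d up, %d down) -> %s",
                  cmp[2], cmp[1], length(degs$up) + length(degs$down),
                  length(degs$up), length(degs$down), fn))
}
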