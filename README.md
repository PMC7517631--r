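# somtraj

Trajectory analysis of three-state ischemia–reperfusion transcriptomes with
a self-organizing map (SOM).

## The problem

Renal ischemia–reperfusion injury is profiled by paired biopsies of the
same patients at three states: pre-ischemia (baseline), ischemia, and
reperfusion. With a handful of patients per state, per-gene time-course
modelling is underpowered; the alternative implemented here summarizes each
transcript as a 3-point trajectory of condition medians and lets an
unsupervised map group transcripts with similar trajectories, then selects
the groups whose average behavior matches a condition-specific pattern.

The pipeline, each stage exposed as package functions:

1. **Normalization** — TPM per sample
   (`TPM_t = 10^6 (c_t/l_t) / Σ_u (c_u/l_u)` with count `c` and effective
   length `l`), log2 transform with zeros treated as undefined (no
   pseudocount), per-condition medians across patients, and removal of
   transcripts with an all-undefined condition or a maximum condition
   median below `log2(3)`.
2. **SOM clustering** — a batch-trained hexagonal 7 × 7 map on the
   (pre, ischemia, reperfusion) median-log2-TPM vectors. Each of the 49
   grid nodes ("modules") collects transcripts with similar trajectories.
3. **Module selection** — with `P̄, Ī, R̄` the module means of member TPM
   per condition, four rules pick condition-specific modules
   (threshold t = 1):
   * ischemia-up: `log2(Ī/P̄) ≥ t` and `log2(R̄/P̄) ≥ t` → Cluster 1
   * ischemia-down: `log2(Ī/P̄) ≤ −t` and `log2(R̄/P̄) ≤ −t` → Cluster 2
   * reperfusion-up: `log2(R̄/Ī) ≥ t` and `log2(R̄/P̄) ≥ t` → Cluster 3
   * reperfusion-down: `log2(R̄/Ī) ≤ −t` and `log2(R̄/P̄) ≤ −t` → Cluster 4
4. **Differential expression** — a simplified negative-binomial Wald test
   (median-of-ratios size factors, method-of-moments dispersion stabilized
   at the across-gene median), significance at `|log2 FC| ≥ 1` and
   `p < 0.05`.
5. **Enrichment** — per-cluster gene-set over-representation by the
   right-tail Fisher/hypergeometric test with Benjamini–Hochberg adjustment
   within each cluster's family of sets.

A negative-binomial simulator with planted trajectory classes and planted
gene sets (`simulate_counts()`, `simulate_genesets()`) makes every stage
testable without external data.

## Worked example

```r
library(somtraj)
report <- run_pipeline(default_config(outdir = "somtraj_out", seed = 1))
str(report$recovery$ischemia_up)
#> List of 2
#>  $ recall   : num 0.936
#>  $ precision: num 0.981
report$som$n_modules
#> [1] 49
report$enrichment$C1_ischemia_up$top_set
#> [1] "planted_ischemia_up"
```

This simulates the default study (5 patients × 3 conditions; 2000 flat
transcripts plus four 4-fold trajectory classes of 500), runs every stage,
and writes the stage tables under `somtraj_out/`: of the 500 transcripts
planted as ischemia-up, 93.6% end up in Cluster 1, 98.1% of Cluster 1 is
truly planted, and the planted gene set is the top-ranked enrichment of its
cluster. The same stages can be run step by step — the numbered scripts
under `analysis/` do exactly that and narrate each stage's findings into
`results/`.

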