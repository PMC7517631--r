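# Independent oracles, kept deliberately naive.

# Right-tail hypergeometric probability by exhaustive enumeration of the
# support, using plain binomial coefficients.
oracle_hyper_tail <- function(k, n_cluster, m_set, n_universe) {
  lo <- max(0, n_cluster + m_set - n_universe)
  hi <- min(n_cluster, m_set)
  support <- lo:hi
  probs <- choose(m_set, support) *
    choose(n_universe - m_set, n_cluster - support) /
    choose(n_universe, n_cluster)
  sum(probs[support >= k])
}

# BH step-up by literal sort-and-scan.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small deterministic count fixture: 4 transcripts x 6 samples,
# 2 patients x 3 conditions.
tiny_count_matrix <- function() {
  counts <- matrix(c(10, 20, 0, 5,
                     12, 18, 0, 6,
                     40, 20, 2, 5,
                     44, 22, 1, 6,
                     10, 80, 4, 5,
                     11, 76, 3, 7),
                   nrow = 4, ncol = 6,
                   dimnames = list(paste0("T", 1:4),
                                   c("P1_pre", "P2_pre", "P1_isch",
                                     "P2_isch", "P1_rep", "P2_rep")))
  count_matrix(counts, setNames(c(100, 200, 150, 300), paste0("T", 1:4)))
}

tiny_design <- function() {
  data.frame(
    sample_id = c("P1_pre", "P2_pre", "P1_isch", "P2_isch", "P1_rep",
                  "P2_rep"),
    patient_id = rep(c("P1", "P2"), 3),
    condition = rep(c("pre_ischemia", "ischemia", "reperfusion"), each = 2),
    stringsAsFactors = FALSE
  )
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
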