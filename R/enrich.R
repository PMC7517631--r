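#' Right-tail hypergeometric (one-sided Fisher) p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N = n_universe, K = m_set,
#' n = n_cluster)`: the probability of observing at least `k` gene-set
#' members in a draw of `n_cluster` genes from the universe. Evaluated via
#' the log-gamma-stable hypergeometric tail, so it is accurate for
#' universes up to 10^6 and beyond. Vectorized over `k`.
#'
#' @param k Observed overlap(s).
#' @param n_cluster Cluster size (within the universe).
#' @param m_set Gene-set size (within the universe).
#' @param n_universe Universe size.
#' @return P-value(s) in (0, 1].
#' @export
fisher_right_tail <- function(k, n_cluster, m_set, n_universe) {
  stopifnot(all(n_universe >= 0), all(n_cluster >= 0), all(m_set >= 0))
  if (any(n_cluster > n_universe) || any(m_set > n_universe)) {
    stop("margins exceed the universe size", call. = FALSE)
  }
  lo <- pmax(0, n_cluster + m_set - n_universe)
  if (any(k < lo) || any(k > pmin(n_cluster, m_set))) {
    stop("overlap k inconsistent with the margins", call. = FALSE)
  }
  stats::phyper(k - 1, m_set, n_universe - m_set, n_cluster,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order, each `>=` its input and
#'   `<= 1`.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation per cluster
#'
#' For each cluster and gene set, overlap counts are taken within the
#' universe, the right-tail Fisher p-value is computed, and BH adjustment
#' is applied within each cluster's family of sets. Genes outside the
#' universe are dropped with a warning.
#'
#' @param clusters Named list of cluster definitions
#'   ([assemble_clusters()]`$clusters`).
#' @param collection Named list of gene sets ([read_gmt()]).
#' @param universe Character vector of background gene identifiers.
#' @param alpha Enrichment call threshold on the adjusted p (default 0.05).
#' @return Named list (one per cluster) of data frames sorted by `adj_p`
#'   then `set_name`: `set_name`, `k_overlap`, `n_cluster`, `m_set`,
#'   `n_universe`, `p_value`, `adj_p`, `enriched`.
#' @export
enrich_clusters <- function(clusters, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  set_members <- lapply(collection, function(s) intersect(s$members, universe))
  set_names <- vapply(collection, function(s) s$set_name, character(1))
  out <- lapply(clusters, function(cl) {
    genes <- cl$transcript_ids
    outside <- setdiff(genes, universe)
    if (length(outside) > 0) {
      warning(sprintf("cluster %s: %d gene(s) outside the universe dropped",
                      cl$label, length(outside)), call. = FALSE)
      genes <- intersect(genes, universe)
    }
    k <- vapply(set_members, function(m) length(intersect(m, genes)),
                integer(1))
    m_set <- lengths(set_members)
    p <- fisher_right_tail(k, length(genes), m_set, length(universe))
    res <- data.frame(set_name = set_names, k_overlap = k,
                      n_cluster = length(genes), m_set = m_set,
                      n_universe = length(universe), p_value = p,
                      adj_p = bh_adjust(p), stringsAsFactors = FALSE)
    res$enriched <- res$adj_p < alpha
    res <- res[order(res$adj_p, res$set_name), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  names(out) <- names(clusters)
  out
}
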