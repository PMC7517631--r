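#' Transcripts-per-million normalization
#'
#' Per sample, each feature's read count is divided by its effective length
#' to give a read-rate, and rates are rescaled to sum to 10^6. A sample with
#' no reads at all is left all-zero with a warning.
#'
#' @param counts A [count_matrix()], or a plain numeric matrix (then
#'   `effective_lengths` is required).
#' @param effective_lengths Positive vector or matrix of effective lengths;
#'   ignored when `counts` is a `count_matrix`.
#' @return Numeric matrix of TPM with the input dimnames. Every column sums
#'   to 10^6 unless it is all-zero.
#' @export
compute_tpm <- function(counts, effective_lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    effective_lengths <- counts$effective_lengths
    counts <- counts$counts
  }
  stopifnot(!is.null(effective_lengths))
  rate <- counts / effective_lengths  # recycles a vector over columns
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("sample(s) with zero total counts left all-zero: %s",
                    paste(colnames(counts)[zero], collapse = ", ")),
            call. = FALSE)
    totals[zero] <- 1
  }
  sweep(rate, 2, totals, "/") * 1e6
}

#' Log2-transform TPM, marking zeros as undefined
#'
#' No pseudocount is added: a zero TPM becomes `NA` ("removed" rather than
#' shifted), so downstream medians are computed over the expressed samples
#' only.
#'
#' @param tpm Non-negative numeric matrix.
#' @return Matrix of `log2(tpm)` with `NA` where `tpm == 0`.
#' @export
log2_tpm <- function(tpm) {
  stopifnot(all(tpm >= 0, na.rm = TRUE))
  out <- suppressWarnings(log2(tpm))
  out[tpm == 0] <- NA_real_
  out
}

.condition_cols <- c(pre_ischemia = "p_med", ischemia = "i_med",
                     reperfusion = "r_med")

#' Per-condition median log2-TPM profiles
#'
#' For each transcript and condition, the median of the defined (non-`NA`)
#' log2 TPM values across that condition's samples. The median is `NA` only
#' when every sample in the condition is undefined. Even-count medians use
#' the midpoint convention.
#'
#' @param log2tpm Matrix from [log2_tpm()] with sample colnames.
#' @param design Design data frame (`sample_id`, `patient_id`, `condition`).
#' @return Data frame with columns `transcript_id`, `p_med`, `i_med`,
#'   `r_med` (pre-ischemia, ischemia, reperfusion).
#' @export
condition_medians <- function(log2tpm, design) {
  validate_design(design)
  missing_cols <- setdiff(design$sample_id, colnames(log2tpm))
  if (length(missing_cols) > 0) {
    stop(sprintf("design sample(s) absent from matrix: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(transcript_id = rownames(log2tpm),
                    stringsAsFactors = FALSE)
  for (cond in conditions()) {
    cols <- design$sample_id[design$condition == cond]
    if (length(cols) == 0) stop(sprintf("condition '%s' has no samples", cond),
                                call. = FALSE)
    sub <- log2tpm[, cols, drop = FALSE]
    med <- apply(sub, 1, stats::median, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    out[[.condition_cols[[cond]]]] <- unname(med)
  }
  out
}

#' Low-signal and zero-expression filtering of condition profiles
#'
#' Drops transcripts with any undefined condition median (a condition in
#' which every sample had zero TPM), then transcripts whose maximum
#' condition median falls below `min_log2` (default `log2(3)`, the
#' very-low-signal cutoff). The retained profiles are fully defined with at
#' least one condition at or above the cutoff.
#'
#' @param profiles Data frame from [condition_medians()].
#' @param min_log2 Signal threshold on the log2-TPM scale; default
#'   `log2(3)`.
#' @param aggregate `"max"` (default) compares the maximum condition median
#'   against the threshold, keeping transcripts induced in a single state;
#'   `"mean"` compares the mean.
#' @return The retained subset of `profiles` (row order preserved).
#' @export
filter_transcripts <- function(profiles, min_log2 = log2(3),
                               aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  vals <- as.matrix(profiles[, c("p_med", "i_med", "r_med")])
  defined <- rowSums(is.na(vals)) == 0
  stat <- if (aggregate == "max") {
    suppressWarnings(apply(vals, 1, max))
  } else {
    rowMeans(vals)
  }
  keep <- defined & !is.na(stat) & stat >= min_log2
  if (!any(keep)) {
    warning("no transcripts retained after filtering", call. = FALSE)
  }
  profiles[keep, , drop = FALSE]
}

#' Flag which profiles survive filtering (for reporting)
#'
#' @inheritParams filter_transcripts
#' @return Logical vector aligned with `profiles` rows.
#' @export
retained_flags <- function(profiles, min_log2 = log2(3),
                           aggregate = c("max", "mean")) {
  kept <- filter_transcripts(profiles, min_log2, aggregate)
  profiles$transcript_id %in% kept$transcript_id
}

#' Aggregate transcript counts to gene level
#'
#' Gene counts are the sums of member-transcript counts per sample. Gene
#' effective length is the count-weighted mean of member effective lengths
#' (weights = total counts across samples; unweighted mean when all member
#' counts are zero).
#'
#' @param cm A [count_matrix()] keyed by transcript.
#' @param tx2gene Named character map (transcript -> gene) from
#'   [read_tx2gene()].
#' @param unmapped What to do with transcripts absent from the map:
#'   `"error"` (default), `"keep"` (each becomes its own gene), or `"drop"`
#'   (removed with a warning).
#' @return A [count_matrix()] keyed by gene.
#' @export
aggregate_to_genes <- function(cm, tx2gene,
                               unmapped = c("error", "keep", "drop")) {
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(cm, "count_matrix"))
  tx <- rownames(cm$counts)
  gene <- unname(tx2gene[tx])
  absent <- is.na(gene)
  if (any(absent)) {
    if (unmapped == "error") {
      stop(sprintf("%d transcript(s) absent from the transcript-to-gene map (first: '%s')",
                   sum(absent), tx[absent][1]), call. = FALSE)
    } else if (unmapped == "keep") {
      gene[absent] <- tx[absent]
      warning(sprintf("%d unmapped transcript(s) kept as singleton genes",
                      sum(absent)), call. = FALSE)
    } else {
      warning(sprintf("%d unmapped transcript(s) dropped", sum(absent)),
              call. = FALSE)
      keep <- !absent
      cm <- count_matrix(cm$counts[keep, , drop = FALSE],
                         if (is.matrix(cm$effective_lengths))
                           cm$effective_lengths[keep, , drop = FALSE]
                         else cm$effective_lengths[keep])
      tx <- tx[keep]
      gene <- gene[keep]
    }
  }
  g <- factor(gene, levels = unique(gene))
  gcounts <- rowsum(cm$counts, g, reorder = FALSE)
  efflen <- cm$effective_lengths
  nmemb <- as.vector(table(g)[levels(g)])
  if (is.matrix(efflen)) {
    w <- cm$counts
    num <- rowsum(efflen * w, g, reorder = FALSE)
    den <- rowsum(w, g, reorder = FALSE)
    gefflen <- rowsum(efflen, g, reorder = FALSE) / nmemb  # unweighted fallback
    idx <- den > 0
    gefflen[idx] <- (num / den)[idx]
  } else {
    w <- rowSums(cm$counts)
    num <- rowsum(efflen * w, g, reorder = FALSE)[, 1]
    den <- rowsum(w, g, reorder = FALSE)[, 1]
    gefflen <- rowsum(efflen, g, reorder = FALSE)[, 1] / nmemb
    idx <- den > 0
    gefflen[idx] <- num[idx] / den[idx]
    names(gefflen) <- levels(g)
  }
  count_matrix(gcounts, gefflen)
}
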