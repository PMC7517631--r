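#' Median-of-ratios size factors
#'
#' For each sample, the median over features (restricted to features with a
#' positive geometric mean across all samples) of the ratio of that
#' feature's count to its geometric mean.
#'
#' @param cm A [count_matrix()] or a plain counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop(paste("no feature has positive counts in every sample;",
               "consider a pseudo-reference fallback"), call. = FALSE)
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo[use]))
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("non-positive size factor", call. = FALSE)
  }
  sf
}

.group_columns <- function(design, condition, sample_ids) {
  cols <- design$sample_id[design$condition == condition]
  cols <- cols[cols %in% sample_ids]
  if (length(cols) < 2) {
    stop(sprintf("condition '%s' needs at least 2 samples", condition),
         call. = FALSE)
  }
  cols
}

# Gene-wise method-of-moments NB dispersion from within-group variability,
# stabilized by flooring at the across-gene median of positive estimates.
.dispersion_mom <- function(ya, yb, floor = 1e-8) {
  mom <- function(y) {
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  aA <- mom(ya)
  aB <- mom(yb)
  w <- c(ncol(ya) - 1L, ncol(yb) - 1L)
  num <- ifelse(is.na(aA), 0, w[1] * pmax(aA, 0)) +
    ifelse(is.na(aB), 0, w[2] * pmax(aB, 0))
  den <- ifelse(is.na(aA), 0, w[1]) + ifelse(is.na(aB), 0, w[2])
  alpha <- ifelse(den > 0, num / den, NA_real_)
  pool <- alpha[!is.na(alpha) & alpha > 0]
  common <- if (length(pool) > 0) stats::median(pool) else floor
  out <- pmax(alpha, common, floor)
  out[is.na(out)] <- max(common, floor)
  out
}

#' Negative-binomial Wald test between two conditions
#'
#' A simplified two-group test on size-factor-normalized counts: per
#' feature, the log2 fold-change of group means (with a pseudo-mean of 0.5
#' added for the reported fold-change only), a method-of-moments NB
#' dispersion stabilized at the across-gene median, and a Wald statistic
#' from the NB variance model `var = mu + alpha * mu^2` referred to the
#' normal distribution. With `paired = TRUE`, within-patient log2 ratios
#' are tested with a one-sample t statistic instead.
#'
#' Significance follows the raw-p rule `|log2_fc| >= lfc_threshold` and
#' `p < p_threshold`; BH-adjusted p-values are reported alongside.
#'
#' @param cm A [count_matrix()] (gene- or transcript-level).
#' @param design Design data frame.
#' @param group_a,group_b Conditions to compare (fold-change is B over A).
#' @param paired Test within-patient log-ratios instead of group means.
#' @param lfc_threshold,p_threshold Significance cutoffs (defaults 1, 0.05).
#' @param sf Optional precomputed size factors.
#' @return Data frame with one row per feature: `feature_id`, `mean_a`,
#'   `mean_b`, `log2_fc`, `p_value`, `adj_p`, `significant`, `testable`.
#' @export
nb_test <- function(cm, design, group_a, group_b, paired = FALSE,
                    lfc_threshold = 1, p_threshold = 0.05, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  stopifnot(group_a %in% conditions(), group_b %in% conditions())
  counts <- cm$counts
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- sweep(counts, 2, sf, "/")
  cols_a <- .group_columns(design, group_a, colnames(counts))
  cols_b <- .group_columns(design, group_b, colnames(counts))
  ya <- norm[, cols_a, drop = FALSE]
  yb <- norm[, cols_b, drop = FALSE]
  ma <- rowMeans(ya)
  mb <- rowMeans(yb)
  eps <- 0.5
  lfc <- log2((mb + eps) / (ma + eps))
  testable <- !(ma == 0 & mb == 0)

  if (paired) {
    pat_a <- design$patient_id[match(cols_a, design$sample_id)]
    pat_b <- design$patient_id[match(cols_b, design$sample_id)]
    shared <- intersect(pat_a, pat_b)
    if (length(shared) < 2) {
      stop("paired test needs at least 2 patients present in both groups",
           call. = FALSE)
    }
    d <- log2((yb[, match(shared, pat_b), drop = FALSE] + eps) /
                (ya[, match(shared, pat_a), drop = FALSE] + eps))
    md <- rowMeans(d)
    sd_d <- apply(d, 1, stats::sd)
    se <- sd_d / sqrt(length(shared))
    tstat <- ifelse(se > 0, md / se, ifelse(md == 0, 0, Inf))
    p <- 2 * stats::pt(-abs(tstat), df = length(shared) - 1)
    lfc <- md
  } else {
    alpha <- .dispersion_mom(ya, yb)
    ma2 <- ifelse(ma > 0, ma, ma + eps)
    mb2 <- ifelse(mb > 0, mb, mb + eps)
    # delta-method variance of log2 group means under var = mu + alpha mu^2
    va <- (ma2 + alpha * ma2^2) / length(cols_a)
    vb <- (mb2 + alpha * mb2^2) / length(cols_b)
    se <- sqrt(va / ma2^2 + vb / mb2^2) / log(2)
    z <- log2(mb2 / ma2) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  p[!testable] <- 1
  lfc[!testable] <- 0
  res <- data.frame(
    feature_id = rownames(counts),
    mean_a = ma,
    mean_b = mb,
    log2_fc = lfc,
    p_value = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  res$significant <- abs(res$log2_fc) >= lfc_threshold &
    res$p_value < p_threshold
  res$testable <- testable
  rownames(res) <- NULL
  res
}

#' Partition test results into up- and down-regulated gene sets
#'
#' @param results Data frame from [nb_test()].
#' @param lfc_threshold,p_threshold Cutoffs (defaults 1, 0.05).
#' @return `list(up = ..., down = ...)` of feature ids; the sets are
#'   disjoint.
#' @export
select_degs <- function(results, lfc_threshold = 1, p_threshold = 0.05) {
  sig <- results$p_value < p_threshold
  list(
    up = results$feature_id[sig & results$log2_fc >= lfc_threshold],
    down = results$feature_id[sig & results$log2_fc <= -lfc_threshold]
  )
}
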