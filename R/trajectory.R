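CLUSTER_LABELS <- c(C1_ischemia_up = "C1_ischemia_up",
                    C2_ischemia_down = "C2_ischemia_down",
                    C3_reperfusion_up = "C3_reperfusion_up",
                    C4_reperfusion_down = "C4_reperfusion_down")

.linear_profiles <- function(profiles) {
  cbind(pre = 2^profiles$p_med, isch = 2^profiles$i_med,
        reper = 2^profiles$r_med)
}

#' Per-module condition means of member-transcript TPM
#'
#' For every module, the mean over member transcripts of linear-scale TPM
#' per condition (each transcript's condition value is its median log2 TPM
#' back-transformed with `2^x`). With `scale = "log2"` the mean is taken in
#' log2 space and back-transformed, i.e. a geometric mean. Empty modules
#' carry `NA` means.
#'
#' @param assignment Named integer vector (transcript -> module) from
#'   [assign_modules()].
#' @param profiles Filtered condition profiles ([filter_transcripts()]).
#' @param n_modules Total number of modules on the grid.
#' @param scale `"linear"` (default, arithmetic mean of TPM) or `"log2"`.
#' @return Data frame: `module_id`, `n_transcripts`, `p_bar`, `i_bar`,
#'   `r_bar`.
#' @export
summarize_modules <- function(assignment, profiles, n_modules = 49,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  idx <- match(names(assignment), profiles$transcript_id)
  if (anyNA(idx)) {
    stop("every assigned transcript must have a profile", call. = FALSE)
  }
  prof <- profiles[idx, , drop = FALSE]
  vals <- if (scale == "linear") {
    .linear_profiles(prof)
  } else {
    cbind(pre = prof$p_med, isch = prof$i_med, reper = prof$r_med)
  }
  out <- data.frame(module_id = seq_len(n_modules),
                    n_transcripts = tabulate(assignment, nbins = n_modules),
                    p_bar = NA_real_, i_bar = NA_real_, r_bar = NA_real_)
  part <- rowsum(vals, assignment)
  mods <- as.integer(rownames(part))
  means <- part / out$n_transcripts[mods]
  if (scale == "log2") means <- 2^means
  out$p_bar[mods] <- means[, "pre"]
  out$i_bar[mods] <- means[, "isch"]
  out$r_bar[mods] <- means[, "reper"]
  out
}

#' Condition-specific module selection rule
#'
#' Evaluates, per module, one of the four fold-change rules on module mean
#' TPM (`p_bar`, `i_bar`, `r_bar`):
#' \describe{
#'   \item{ischemia up}{`log2(i/p) >= t` and `log2(r/p) >= t`}
#'   \item{ischemia down}{`log2(i/p) <= -t` and `log2(r/p) <= -t`}
#'   \item{reperfusion up}{`log2(r/i) >= t` and `log2(r/p) >= t`}
#'   \item{reperfusion down}{`log2(r/i) <= -t` and `log2(r/p) <= -t`}
#' }
#' With `literal_table1 = TRUE` the down rules use `<= +t` instead of
#' `<= -t` (the rule as literally printed, which is satisfied by almost any
#' module; the mirrored form is the default).
#'
#' @param summaries Data frame from [summarize_modules()] (vectorized over
#'   rows).
#' @param effect `"ischemia"` or `"reperfusion"`.
#' @param direction `"up"` or `"down"`.
#' @param threshold Log2 fold-change threshold `t` (default 1).
#' @param literal_table1 Use the literally printed down rule. Default
#'   `FALSE`.
#' @return Logical vector over modules; `FALSE` (with a warning) for
#'   modules with undefined or zero means.
#' @export
apply_criterion <- function(summaries, effect = c("ischemia", "reperfusion"),
                            direction = c("up", "down"), threshold = 1,
                            literal_table1 = FALSE) {
  effect <- match.arg(effect)
  direction <- match.arg(direction)
  p <- summaries$p_bar
  i <- summaries$i_bar
  r <- summaries$r_bar
  ok <- !is.na(p) & !is.na(i) & !is.na(r)
  zero <- ok & (p <= 0 | i <= 0 | r <= 0)
  if (any(zero)) {
    warning(sprintf("%d module(s) excluded: zero mean in a ratio denominator",
                    sum(zero)), call. = FALSE)
  }
  usable <- ok & !zero
  first <- rep(NA_real_, length(p))   # effect-specific ratio
  second <- rep(NA_real_, length(p))  # net ratio vs pre-ischemia
  first[usable] <- if (effect == "ischemia") {
    log2(i[usable] / p[usable])
  } else {
    log2(r[usable] / i[usable])
  }
  second[usable] <- log2(r[usable] / p[usable])
  res <- rep(FALSE, length(p))
  if (direction == "up") {
    res[usable] <- first[usable] >= threshold & second[usable] >= threshold
  } else {
    lim <- if (literal_table1) threshold else -threshold
    res[usable] <- first[usable] <= lim & second[usable] <= lim
  }
  res
}

#' Assemble the four condition-specific clusters
#'
#' Each cluster is the union of the modules passing one selection rule and
#' their member transcripts. A module may pass both an ischemia and a
#' reperfusion rule; it is then reported in both clusters and listed in the
#' overlap table (disjointness is not enforced).
#'
#' @param summaries Data frame from [summarize_modules()].
#' @param assignment Named integer vector (transcript -> module).
#' @param threshold,literal_table1 Passed to [apply_criterion()].
#' @return List with `clusters` (named list of
#'   `list(label, module_ids, transcript_ids, n_genes)`) and `overlap`
#'   (data frame of modules selected by more than one rule).
#' @export
assemble_clusters <- function(summaries, assignment, threshold = 1,
                              literal_table1 = FALSE) {
  rules <- list(
    C1_ischemia_up = c("ischemia", "up"),
    C2_ischemia_down = c("ischemia", "down"),
    C3_reperfusion_up = c("reperfusion", "up"),
    C4_reperfusion_down = c("reperfusion", "down")
  )
  clusters <- lapply(names(rules), function(label) {
    sel <- apply_criterion(summaries, rules[[label]][1], rules[[label]][2],
                           threshold, literal_table1)
    mods <- summaries$module_id[sel]
    txs <- names(assignment)[assignment %in% mods]
    list(label = label, module_ids = mods, transcript_ids = txs,
         n_genes = length(txs))
  })
  names(clusters) <- names(rules)
  hit <- vapply(clusters,
                function(cl) summaries$module_id %in% cl$module_ids,
                logical(nrow(summaries)))
  hit <- matrix(hit, nrow = nrow(summaries))
  multi <- which(rowSums(hit) > 1)
  overlap <- data.frame(
    module_id = summaries$module_id[multi],
    labels = vapply(multi, function(i) {
      paste(names(rules)[hit[i, ]], collapse = ",")
    }, character(1))
  )
  list(clusters = clusters, overlap = overlap)
}

#' Relative mean trajectory per cluster
#'
#' Per cluster, the mean over member transcripts of linear-scale condition
#' values, rescaled so pre-ischemia equals 1. Empty clusters are omitted.
#'
#' @param clusters Named list of cluster definitions from
#'   [assemble_clusters()]`$clusters`.
#' @param profiles Filtered condition profiles.
#' @return Data frame: `label`, `n_genes`, `pre`, `isch`, `reper`.
#' @export
cluster_trajectory_report <- function(clusters, profiles) {
  lin <- .linear_profiles(profiles)
  rownames(lin) <- profiles$transcript_id
  rows <- lapply(clusters, function(cl) {
    if (cl$n_genes == 0) return(NULL)
    mu <- colMeans(lin[cl$transcript_ids, , drop = FALSE])
    data.frame(label = cl$label, n_genes = cl$n_genes,
               pre = 1, isch = mu[["isch"]] / mu[["pre"]],
               reper = mu[["reper"]] / mu[["pre"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
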