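#' Default planted trajectory classes
#'
#' Five classes emulating the study conditions: a large flat background and
#' four 4-fold condition-specific classes, each satisfying (on expectation)
#' the selection rule of the cluster it should recover into. Multipliers
#' are (pre, ischemia, reperfusion) scalings of the baseline abundance.
#'
#' @param n_flat Flat transcripts (default 2000).
#' @param n_class Transcripts per non-flat class (default 500).
#' @param fold Fold-change of the non-flat classes (default 4).
#' @return Data frame: `name`, `mult_pre`, `mult_isch`, `mult_reper`,
#'   `n_transcripts`.
#' @export
trajectory_classes <- function(n_flat = 2000, n_class = 500, fold = 4) {
  stopifnot(fold > 1)
  data.frame(
    name = c("flat", "ischemia_up", "ischemia_down", "reperfusion_up",
             "reperfusion_down"),
    mult_pre = c(1, 1, 1, 1, 1),
    mult_isch = c(1, fold, 1 / fold, 1, 1),
    mult_reper = c(1, fold, 1 / fold, fold, 1 / fold),
    n_transcripts = c(n_flat, rep(n_class, 4)),
    stringsAsFactors = FALSE
  )
}

#' Which cluster should recover each planted class
#'
#' @return Named character vector: class name -> cluster label.
#' @export
class_cluster_map <- function() {
  c(ischemia_up = "C1_ischemia_up", ischemia_down = "C2_ischemia_down",
    reperfusion_up = "C3_reperfusion_up",
    reperfusion_down = "C4_reperfusion_down")
}

#' Simulate a paired three-condition RNA-seq count matrix
#'
#' Per transcript, a log-normal baseline abundance; per condition, the
#' baseline scaled by the class multiplier; per patient and transcript, a
#' multiplicative log-normal effect shared across that patient's three
#' samples (the paired design). Within each sample, expected counts are
#' allocated proportionally to abundance x effective length and scaled to
#' the library size; observed counts are negative binomial with
#' `var = mu + dispersion * mu^2`. Deterministic given `seed`.
#'
#' @param classes Data frame from [trajectory_classes()].
#' @param n_patients Patients (default 5; 3 samples each).
#' @param baseline_log_mean,baseline_log_sd Natural-log parameters of the
#'   baseline abundance distribution (defaults `log(100)` and 1).
#' @param dispersion NB dispersion (default 0.1).
#' @param library_size Expected reads per sample (default 2e6).
#' @param efflen_range Uniform range of effective lengths in bases
#'   (default 200-5000), constant across samples.
#' @param patient_sd Log-normal sd of the per-patient, per-transcript
#'   effect (default 0.2; 0 disables it).
#' @param seed Integer seed.
#' @return List: `counts` (a [count_matrix()]), `design` (data frame),
#'   `truth` (data frame `transcript_id`, `class`).
#' @export
simulate_counts <- function(classes = trajectory_classes(), n_patients = 5,
                            baseline_log_mean = log(100),
                            baseline_log_sd = 1, dispersion = 0.1,
                            library_size = 2e6,
                            efflen_range = c(200, 5000), patient_sd = 0.2,
                            seed = 1) {
  stopifnot(nrow(classes) >= 1, all(classes$n_transcripts > 0),
            all(classes$mult_pre > 0), all(classes$mult_isch > 0),
            all(classes$mult_reper > 0), dispersion > 0)
  set.seed(seed)
  n <- sum(classes$n_transcripts)
  ids <- sprintf("TX%05d", seq_len(n))
  cls <- rep(classes$name, classes$n_transcripts)
  mult <- as.matrix(classes[rep(seq_len(nrow(classes)),
                                classes$n_transcripts),
                            c("mult_pre", "mult_isch", "mult_reper")])
  colnames(mult) <- conditions()
  baseline <- stats::rlnorm(n, baseline_log_mean, baseline_log_sd)
  efflen <- stats::runif(n, efflen_range[1], efflen_range[2])
  patient_ids <- sprintf("P%d", seq_len(n_patients))
  pe <- if (patient_sd > 0) {
    matrix(stats::rlnorm(n * n_patients, 0, patient_sd), n, n_patients)
  } else {
    matrix(1, n, n_patients)
  }
  design <- data.frame(
    sample_id = as.vector(outer(patient_ids, conditions(), paste, sep = "_")),
    patient_id = rep(patient_ids, times = 3),
    condition = rep(conditions(), each = n_patients),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0, n, nrow(design),
                   dimnames = list(ids, design$sample_id))
  for (j in seq_len(nrow(design))) {
    p <- match(design$patient_id[j], patient_ids)
    abundance <- baseline * mult[, design$condition[j]] * pe[, p]
    w <- abundance * efflen
    mu <- library_size * w / sum(w)
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  list(counts = count_matrix(counts, stats::setNames(efflen, ids)),
       design = design,
       truth = data.frame(transcript_id = ids, class = cls,
                          stringsAsFactors = FALSE))
}

#' Simulate gene-set collections with planted enrichment
#'
#' One planted set per non-flat class, containing `planted_fraction` of
#' the class's transcripts plus random out-of-class fillers
#' (`filler_fraction` of the planted count), and uniformly drawn decoy
#' sets. Deterministic given `seed`.
#'
#' @param truth Truth data frame from [simulate_counts()].
#' @param n_decoy_sets Number of decoy sets (default 20).
#' @param set_size_range Decoy set size range (default 50-200).
#' @param planted_fraction Fraction of each class planted into its set
#'   (default 0.8; must be in (0, 1\]).
#' @param filler_fraction Out-of-class fillers relative to planted members
#'   (default 0.25).
#' @param seed Integer seed.
#' @return List: `sets` (named list as from [read_gmt()]) and
#'   `set_truth` (data frame `set_name`, `class`, `cluster_label`; decoys
#'   carry `NA`).
#' @export
simulate_genesets <- function(truth, n_decoy_sets = 20,
                              set_size_range = c(50, 200),
                              planted_fraction = 0.8,
                              filler_fraction = 0.25, seed = 1) {
  if (planted_fraction <= 0 || planted_fraction > 1) {
    stop("planted_fraction must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  universe <- truth$transcript_id
  nonflat <- setdiff(unique(truth$class), "flat")
  sets <- list()
  rows <- list()
  for (cl in nonflat) {
    members <- truth$transcript_id[truth$class == cl]
    n_pl <- max(1, round(planted_fraction * length(members)))
    planted <- if (n_pl < length(members)) sample(members, n_pl) else members
    pool <- setdiff(universe, members)
    n_fill <- round(filler_fraction * n_pl)
    fillers <- if (n_fill > 0) sample(pool, min(n_fill, length(pool)))
               else character(0)
    nm <- paste0("planted_", cl)
    sets[[nm]] <- list(set_name = nm, description = paste("planted for", cl),
                       members = c(planted, fillers))
    rows[[nm]] <- data.frame(set_name = nm, class = cl,
                             cluster_label = unname(class_cluster_map()[cl]),
                             stringsAsFactors = FALSE)
  }
  if (n_decoy_sets > 0) {
    for (d in seq_len(n_decoy_sets)) {
      sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      nm <- sprintf("decoy_%03d", d)
      sets[[nm]] <- list(set_name = nm, description = "decoy",
                         members = sample(universe, sz))
      rows[[nm]] <- data.frame(set_name = nm, class = NA_character_,
                               cluster_label = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }
  list(sets = sets, set_truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Precision and recall of cluster recovery against the planted truth
#'
#' Recall of a class = fraction of its planted transcripts recovered by
#' its cluster; precision = fraction of the cluster's transcripts that are
#' planted members of that class (so flat transcripts inside a cluster
#' count as false positives). Precision is `NA` for an empty cluster.
#'
#' @param clusters Named list from [assemble_clusters()]`$clusters`.
#' @param truth Truth data frame from [simulate_counts()].
#' @return Data frame: `class`, `label`, `n_planted`, `n_cluster`,
#'   `recall`, `precision`.
#' @export
evaluate_recovery <- function(clusters, truth) {
  map <- class_cluster_map()
  rows <- lapply(names(map), function(cl) {
    planted <- truth$transcript_id[truth$class == cl]
    label <- map[[cl]]
    got <- if (label %in% names(clusters)) {
      clusters[[label]]$transcript_ids
    } else {
      character(0)
    }
    hits <- length(intersect(got, planted))
    data.frame(class = cl, label = label, n_planted = length(planted),
               n_cluster = length(got),
               recall = if (length(planted) > 0) hits / length(planted)
                        else NA_real_,
               precision = if (length(got) > 0) hits / length(got)
                           else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Per-sample quantification files (`<sample>.quant.sf`), `design.tsv`,
#' `truth.tsv` and, when gene sets are supplied, `sets.gmt` — exactly the
#' formats the readers in this package consume.
#'
#' @param sim List from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @param sets Optional gene-set list from [simulate_genesets()]`$sets`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- sim$counts$counts
  efflen <- sim$counts$effective_lengths
  tpm <- compute_tpm(sim$counts)
  for (s in colnames(counts)) {
    df <- data.frame(Name = rownames(counts),
                     Length = round(efflen) + 100,
                     EffectiveLength = efflen,
                     TPM = tpm[, s],
                     NumReads = counts[, s])
    write_tsv(df, file.path(dir, paste0(s, ".quant.sf")))
  }
  design_out <- data.frame(sample = sim$design$sample_id,
                           patient = sim$design$patient_id,
                           condition = sim$design$condition)
  write_tsv(design_out, file.path(dir, "design.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  if (!is.null(sets)) write_gmt(sets, file.path(dir, "sets.gmt"))
  invisible(dir)
}
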