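#' Default pipeline configuration
#'
#' A plain named list mirroring every tunable of the pipeline. Stage seeds
#' are derived from the single global `seed` by fixed additive offsets
#' (simulation +101, SOM initialization +211, gene sets +307), so one seed
#' determines every random draw.
#'
#' @param outdir Output directory for stage TSVs and the run report.
#' @param seed Global seed (default 1).
#' @return Named list of class `somtraj_config`.
#' @export
default_config <- function(outdir = "somtraj_out", seed = 1) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = TRUE,          # no input paths: generate the synthetic study
    quant_dir = NULL,         # else: directory of <sample>.quant.sf files
    design = NULL,
    tx2gene = NULL,
    gmt = NULL,
    min_log2 = log2(3),
    filter_aggregate = "max",
    som = list(rows = 7, cols = 7, epochs_ordering = 100,
               epochs_tuning = 50, epochs_polish = 10,
               radius_start = 3, radius_end = 1),
    selection = list(threshold = 1, literal_table1 = FALSE,
                     module_mean_scale = "linear"),
    de = list(lfc = 1, p = 0.05, paired = FALSE,
              comparisons = list(c("pre_ischemia", "ischemia"),
                                 c("ischemia", "reperfusion"),
                                 c("pre_ischemia", "reperfusion"))),
    enrichment = list(alpha = 0.05, universe = "measured")
  ), class = "somtraj_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [default_config()].
#'
#' @param path YAML file.
#' @return A `somtraj_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]) && k != "de") {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

.stage_seed <- function(seed, stage) {
  seed + c(simulate = 101L, som = 211L, genesets = 307L)[[stage]]
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes: input loading (or simulation) -> TPM normalization, log2
#' transform, condition medians and filtering -> differential expression on
#' the configured comparisons -> SOM clustering -> condition-specific
#' module selection into clusters -> gene-set enrichment. Every stage
#' writes its TSVs under `config$outdir`; a YAML run report records seeds,
#' parameters and row counts. Two runs with the same config and seed
#' produce byte-identical outputs.
#'
#' @param config A `somtraj_config` list ([default_config()]) or the path
#'   to a YAML file ([read_config()]).
#' @return The run report (named list), invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)

  ## ---- inputs ----
  truth <- NULL
  sets <- NULL
  if (isTRUE(config$simulate)) {
    sim <- simulate_counts(seed = .stage_seed(config$seed, "simulate"))
    gs <- simulate_genesets(sim$truth,
                            seed = .stage_seed(config$seed, "genesets"))
    cm <- sim$counts
    design <- sim$design
    truth <- sim$truth
    sets <- gs$sets
    report$input <- list(source = "simulated",
                         n_transcripts = nrow(cm$counts),
                         n_samples = ncol(cm$counts))
  } else {
    design <- read_design(config$design)
    quant_files <- file.path(config$quant_dir,
                             paste0(design$sample_id, ".quant.sf"))
    missing <- !file.exists(quant_files)
    if (any(missing)) {
      stop(sprintf("stage input: missing quantification file(s): %s",
                   paste(quant_files[missing], collapse = ", ")),
           call. = FALSE)
    }
    quants <- mapply(read_quant_table, quant_files, design$sample_id,
                     SIMPLIFY = FALSE)
    cm <- quants_to_count_matrix(quants)
    if (!is.null(config$gmt)) sets <- read_gmt(config$gmt)
    report$input <- list(source = config$quant_dir,
                         n_transcripts = nrow(cm$counts),
                         n_samples = ncol(cm$counts))
  }
  if (!is.null(config$tx2gene)) {
    map <- read_tx2gene(config$tx2gene)
    cm_de <- aggregate_to_genes(cm, map)
  } else {
    cm_de <- cm
  }

  ## ---- normalize ----
  tpm <- compute_tpm(cm)
  l2 <- log2_tpm(tpm)
  profiles <- condition_medians(l2, design)
  kept <- filter_transcripts(profiles, config$min_log2,
                             config$filter_aggregate)
  if (nrow(kept) == 0) {
    stop("normalize: no transcripts retained after filtering; nothing to cluster",
         call. = FALSE)
  }
  prof_out <- profiles
  prof_out$retained <- retained_flags(profiles, config$min_log2,
                                      config$filter_aggregate)
  write_tsv(prof_out, file.path(config$outdir, "profiles.tsv"))
  report$normalize <- list(n_input = nrow(profiles), n_retained = nrow(kept),
                           min_log2 = config$min_log2)

  ## ---- differential expression ----
  report$de <- list()
  for (cmp in config$de$comparisons) {
    res <- nb_test(cm_de, design, group_a = cmp[1], group_b = cmp[2],
                   paired = isTRUE(config$de$paired),
                   lfc_threshold = config$de$lfc, p_threshold = config$de$p)
    degs <- select_degs(res, config$de$lfc, config$de$p)
    fn <- sprintf("de_%s_vs_%s.tsv", cmp[2], cmp[1])
    write_tsv(res[, c("feature_id", "mean_a", "mean_b", "log2_fc",
                      "p_value", "adj_p", "significant")],
              file.path(config$outdir, fn))
    report$de[[paste(cmp[2], "vs", cmp[1])]] <-
      list(n_up = length(degs$up), n_down = length(degs$down),
           n_deg = length(degs$up) + length(degs$down))
  }

  ## ---- SOM ----
  mat <- as.matrix(kept[, c("p_med", "i_med", "r_med")])
  rownames(mat) <- kept$transcript_id
  scfg <- do.call(som_config,
                  c(config$som, list(seed = .stage_seed(config$seed, "som"))))
  model <- som_fit(mat, scfg)
  n_modules <- scfg$rows * scfg$cols
  cb <- as.data.frame(model$codebook)
  names(cb) <- c("p_med", "i_med", "r_med")
  cb <- cbind(module = seq_len(n_modules), cb)
  write_tsv(cb, file.path(config$outdir, "som_codebook.tsv"))
  write_tsv(data.frame(transcript_id = names(model$assignment),
                       module = unname(model$assignment)),
            file.path(config$outdir, "som_assignment.tsv"))
  um <- compute_umatrix(model)
  write_tsv(um$pairs, file.path(config$outdir, "umatrix.tsv"))
  report$som <- list(n_modules = n_modules,
                     n_empty = sum(tabulate(model$assignment, n_modules) == 0),
                     quantization_error = quantization_error(model, mat))

  ## ---- selection ----
  summaries <- summarize_modules(model$assignment, kept, n_modules,
                                 scale = config$selection$module_mean_scale)
  asm <- assemble_clusters(summaries, model$assignment,
                           threshold = config$selection$threshold,
                           literal_table1 = config$selection$literal_table1)
  clusters <- asm$clusters
  write_tsv(data.frame(
    label = names(clusters),
    module_ids = vapply(clusters, function(cl)
      paste(cl$module_ids, collapse = ","), character(1)),
    n_modules = vapply(clusters, function(cl)
      length(cl$module_ids), integer(1)),
    n_genes = vapply(clusters, function(cl) cl$n_genes, integer(1))
  ), file.path(config$outdir, "clusters.tsv"))
  members <- do.call(rbind, lapply(clusters, function(cl) {
    if (cl$n_genes == 0) return(NULL)
    data.frame(label = cl$label, transcript_id = cl$transcript_ids)
  }))
  if (is.null(members)) {
    members <- data.frame(label = character(0), transcript_id = character(0))
  }
  write_tsv(members, file.path(config$outdir, "cluster_members.tsv"))
  traj <- cluster_trajectory_report(clusters, kept)
  if (!is.null(traj)) {
    write_tsv(traj, file.path(config$outdir, "cluster_trajectories.tsv"))
  }
  if (nrow(asm$overlap) > 0) {
    write_tsv(asm$overlap, file.path(config$outdir, "cluster_overlap.tsv"))
  }
  report$clusters <- lapply(clusters, function(cl) {
    list(n_modules = length(cl$module_ids), n_genes = cl$n_genes)
  })
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(clusters, truth)
    write_tsv(recovery, file.path(config$outdir, "recovery.tsv"))
    report$recovery <- stats::setNames(
      lapply(seq_len(nrow(recovery)), function(i) {
        list(recall = recovery$recall[i], precision = recovery$precision[i])
      }), recovery$class)
  }

  ## ---- enrichment ----
  if (!is.null(sets)) {
    universe <- switch(config$enrichment$universe,
      measured = kept$transcript_id,
      collection = unique(unlist(lapply(sets, `[[`, "members"))),
      custom = config$enrichment$custom_universe,
      stop("unknown universe policy", call. = FALSE))
    enr <- enrich_clusters(clusters, sets, universe,
                           alpha = config$enrichment$alpha)
    report$enrichment <- list()
    for (label in names(enr)) {
      write_tsv(enr[[label]],
                file.path(config$outdir, sprintf("enrichment_%s.tsv", label)))
      top <- enr[[label]][1, , drop = FALSE]
      report$enrichment[[label]] <- list(
        n_enriched = sum(enr[[label]]$enriched),
        top_set = if (nrow(top) > 0) top$set_name else NA,
        top_adj_p = if (nrow(top) > 0) top$adj_p else NA)
    }
  }

  yaml::write_yaml(report, file.path(config$outdir, "report.yaml"))
  invisible(report)
}
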