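#' Default analysis parameters for the staged pipeline
#'
#' @param n_pcs principal components for the embedding.
#' @param knn,ka diffusion-operator neighborhood and adaptive-bandwidth
#'   sizes.
#' @param t_impute first-pass imputation time; `t_reimpute` the reduced
#'   time used after outlier removal.
#' @param m_representatives k-means summarization size for the
#'   approximate spectral clustering.
#' @param mad_c outlier multiplier, see [remove_outliers()].
#' @param alpha FDR threshold shared by the screen, DE, and motif calls.
#' @param lfc_threshold state-specificity fold-change threshold.
#' @param dynamic_min_lfc dynamic-expression range filter (log2).
#' @param scan_p PWM scan p-value threshold.
#' @param beta soft-threshold power for the similarity networks.
#' @param min_abs_r target-calling correlation threshold.
#' @param min_fpkm culture-expression knockdown filter.
#' @param null_quantile,n_permutations edge-threshold calibration.
#' @param n_tf_modules,n_gene_modules module counts per state network
#'   (`NULL` = one TF module per TF, five gene modules per TF plus one).
#' @param edge_threshold edge-calling rule passed to
#'   [build_state_network()] (`"bimodal"`, `"null"`, or a number).
#' @return Named list of parameters.
#' @export
pipeline_params <- function(n_pcs = 30, knn = 30, ka = 10, t_impute = 6,
                            t_reimpute = 1, m_representatives = 800,
                            mad_c = 3, alpha = 0.05, lfc_threshold = 0.25,
                            dynamic_min_lfc = 1, scan_p = 1e-4, beta = 6,
                            min_abs_r = 0.3, min_fpkm = 5,
                            null_quantile = 0.95, n_permutations = 200,
                            n_tf_modules = NULL, n_gene_modules = NULL,
                            edge_threshold = "null") {
  as.list(environment())
}

#' Run the full staged analysis on synthetic inputs
#'
#' Executes the pipeline end to end: simulate -> normalize/embed ->
#' diffusion-impute -> stage by approximate spectral clustering -> remove
#' outliers and re-impute at reduced diffusion time -> bulk specificity
#' screen and gene-set assembly -> moderated BK-vs-DK differential
#' expression -> TF and antioxidant trajectory clustering ->
#' super-enhancer motif enrichment and expression/enrichment concordance
#' -> BK and DK module networks -> TF prioritization. Every stochastic
#' stage is seeded from the root seed via named substreams, so a fixed
#' `(config, params)` pair reproduces all outputs exactly.
#'
#' @param config a [simulation_config()]; its `seed` is the root seed.
#' @param params a [pipeline_params()] list.
#' @param verbose print stage-level progress with surviving-set sizes.
#' @return A list with the intermediate artifacts (`stages`, `profile`,
#'   `screen`, `gene_sets`, `de`, `tf_clustering`, `antioxidant`,
#'   `enrichment`, `concordance`, `network_bk`, `network_dk`, `ranking`,
#'   ...) and a `manifest` recording configuration, seeds, set sizes and
#'   per-stage wall-clock seconds.
#' @export
run_pipeline <- function(config = simulation_config(),
                         params = pipeline_params(), verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  say <- function(...) if (verbose) message(...)
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  seed <- config$seed
  K <- config$n_stages
  bk_stages <- 1:3
  dk_stages <- (K - 3):(K - 1)
  traj_stages <- seq_len(K - 1) # the off-trajectory final stage is excluded

  sim <- simulate_all(config)
  say("simulate: ", nrow(sim$counts), " genes x ", ncol(sim$counts),
      " cells, ", length(sim$motifs), " motifs")
  tick("simulate")

  log_cpm <- normalize_log_cpm(sim$counts)
  emb_raw <- pca_embedding(log_cpm, params$n_pcs)
  cpm <- sweep(sim$counts, 2L, 1e6 / colSums(sim$counts), `*`)
  op <- build_diffusion_operator(emb_raw, params$knn, params$ka)
  ## stages are assigned on the embedding of the imputed expression
  emb <- pca_embedding(log2(impute_expression(cpm, op, params$t_impute) + 1),
                       params$n_pcs)
  stages <- approx_spectral_cluster(emb, K, params$m_representatives,
                                    seed = substream_seed(seed, "stage"))
  ## orient the stage axis with the state-labelled super-enhancer sets:
  ## TFs whose motifs are enriched in basal-state SEs must peak in the
  ## early stages (the principal axis fixes the ordering only up to sign)
  enr <- motif_enrichment(sim$se, sim$motifs, params$scan_p, params$alpha)
  bk_tfs <- intersect(enr$table$tf[enr$table$direction == "BK"],
                      rownames(cpm))
  dk_tfs <- intersect(enr$table$tf[enr$table$direction == "DK"],
                      rownames(cpm))
  if (length(bk_tfs) && length(dk_tfs)) {
    prof0 <- stage_profile(cpm[c(bk_tfs, dk_tfs), , drop = FALSE],
                           stages$labels)
    pk0 <- peak_stage(prof0)
    if (mean(pk0[bk_tfs]) > mean(pk0[dk_tfs])) {
      say("orientation: basal-enriched TFs peak late; reversing stage axis")
      stages$labels <- stats::setNames(K + 1L - stages$labels,
                                       names(stages$labels))
    }
  }
  mask <- remove_outliers(emb, stages, params$mad_c)
  cells <- names(mask)[mask]
  op2 <- build_diffusion_operator(emb_raw[cells, , drop = FALSE],
                                  params$knn, params$ka)
  imputed <- impute_expression(cpm[, cells, drop = FALSE], op2,
                               params$t_reimpute)
  expr <- log2(imputed + 1)
  labels <- stages$labels[cells]
  profile <- stage_profile(imputed, labels)
  say("stage: ", K, " stages, ", length(cells), "/", ncol(sim$counts),
      " cells retained after outlier removal")
  tick("stage")

  bulk_gene <- aggregate_features_to_genes(sim$bulk)
  screen <- celltype_specific_screen(bulk_gene, "keratinocyte",
                                     params$alpha)
  expressed <- scrna_expression_filter(sim$counts)
  hits <- intersect(screen$gene[screen$selected], expressed)
  tf_annotation <- names(sim$truth$gene_role)[
    sim$truth$gene_role %in% c("bk_tf", "dk_tf")]
  gene_sets <- assemble_gene_sets(hits, tf_annotation,
                                  curated_tfs = character(),
                                  universe = rownames(sim$counts))
  say("specificity: ", sum(screen$selected), " screen hits, ",
      length(gene_sets$keratinocyte_genes), " keratinocyte genes, ",
      length(gene_sets$keratinocyte_tfs), " keratinocyte TFs")
  tick("specificity")

  de_genes <- union(de_expressed_filter(sim$counts[, cells, drop = FALSE]),
                    intersect(gene_sets$keratinocyte_genes,
                              rownames(sim$counts)))
  state <- ifelse(labels %in% bk_stages, "BK",
                  ifelse(labels %in% dk_stages, "DK", NA))
  state_cells <- cells[!is.na(state)]
  de <- moderated_de(log_cpm[de_genes, state_cells, drop = FALSE],
                     stats::setNames(state[!is.na(state)], state_cells),
                     trend = TRUE, alpha = params$alpha,
                     lfc_threshold = params$lfc_threshold)
  say("de: ", sum(de$state_specific == "BK"), " BK-specific, ",
      sum(de$state_specific == "DK"), " DK-specific of ", nrow(de))
  tick("de")

  prof_traj <- stage_profile(imputed, labels, stage_subset = traj_stages)
  tfs_present <- intersect(gene_sets$keratinocyte_tfs, rownames(cpm))
  dyn_tfs <- intersect(dynamic_gene_filter(
    prof_traj$mean_expr[tfs_present, , drop = FALSE],
    params$dynamic_min_lfc), tfs_present)
  tf_clustering <- cluster_trajectories(prof_traj, dyn_tfs, n_clusters = 2)
  pk <- peak_stage(prof_traj, dyn_tfs)
  branch_means <- tapply(pk[names(tf_clustering$gene_labels)],
                         tf_clustering$gene_labels, mean)
  bk_branch_id <- as.integer(names(branch_means)[which.min(branch_means)])
  branch <- ifelse(tf_clustering$gene_labels == bk_branch_id, "BK", "DK")
  names(branch) <- names(tf_clustering$gene_labels)

  aox <- names(sim$truth$gene_role)[
    grepl("^antioxidant", sim$truth$gene_role)]
  aox <- intersect(intersect(aox, expressed), rownames(prof_traj$mean_expr))
  antioxidant <- NULL
  dyn_aox <- dynamic_gene_filter(
    prof_traj$mean_expr[aox, , drop = FALSE], params$dynamic_min_lfc)
  if (length(dyn_aox) >= 3) {
    aox_cl <- cluster_trajectories(prof_traj, dyn_aox, n_clusters = 3)
    aox_pk <- peak_stage(prof_traj, dyn_aox)
    cl_peak <- tapply(aox_pk[names(aox_cl$gene_labels)],
                      aox_cl$gene_labels, mean)
    basal_cl <- as.integer(names(cl_peak)[which.min(cl_peak)])
    antioxidant <- c(cluster_size_enrichment(aox_cl, basal_cl),
                     list(clustering = aox_cl, basal_cluster = basal_cl))
  }
  say("trajectories: ", length(dyn_tfs), " dynamic TFs in 2 branches; ",
      length(dyn_aox), " dynamic antioxidant genes")
  tick("trajectories")

  concordance <- tryCatch(
    concordance_test(branch, enr$table, restrict_to_significant = TRUE,
                     alpha = params$alpha),
    error = function(e) list(p = NA_real_, error = conditionMessage(e)))
  say("motifs: ", sum(enr$table$direction == "BK"), " BK-enriched, ",
      sum(enr$table$direction == "DK"), " DK-enriched of ",
      nrow(enr$table), "; concordance p = ",
      signif(concordance$p, 3))
  tick("motifs")

  networks <- lapply(c(BK = "BK", DK = "DK"), function(st)
    tryCatch(build_state_network(st, expr, stages$labels[cells],
                                 enr$table, de, gene_sets,
                                 beta = params$beta,
                                 n_tf_modules = params$n_tf_modules,
                                 n_gene_modules = params$n_gene_modules,
                                 threshold = params$edge_threshold,
                                 null_quantile = params$null_quantile,
                                 n_permutations = params$n_permutations,
                                 seed = substream_seed(seed,
                                                       paste0("net", st))),
             error = function(e) list(error = conditionMessage(e))))
  say("network: BK ", if (is.null(networks$BK$error))
    nrow(networks$BK$edges) else networks$BK$error, " edges; DK ",
    if (is.null(networks$DK$error)) nrow(networks$DK$edges) else
      networks$DK$error, " edges")
  tick("network")

  traj_cells <- cells[labels %in% traj_stages]
  cand <- intersect(gene_sets$candidate_tfs, rownames(expr))
  cand_genes <- intersect(gene_sets$keratinocyte_genes, de$gene)
  scores <- lapply(cand, function(tf) {
    tg <- identify_targets(expr, tf, cand_genes, traj_cells,
                           params$min_abs_r)
    differentiation_score(tf, tg, de)
  })
  culture_fpkm <- rowMeans(2^profile$mean_expr[
    tfs_present, as.character(bk_stages), drop = FALSE] - 1)
  ranking <- rank_candidates(scores, culture_fpkm, params$min_fpkm)
  say("prioritize: ", nrow(ranking), " ranked candidates; top = ",
      if (nrow(ranking)) ranking$tf[1] else "none")
  tick("prioritize")

  manifest <- list(config = unclass(config), params = params,
                   root_seed = seed,
                   n_cells_retained = length(cells),
                   n_screen_hits = sum(screen$selected),
                   n_keratinocyte_genes =
                     length(gene_sets$keratinocyte_genes),
                   n_de_bk = sum(de$state_specific == "BK"),
                   n_de_dk = sum(de$state_specific == "DK"),
                   n_dynamic_tfs = length(dyn_tfs),
                   n_motifs_bk = sum(enr$table$direction == "BK"),
                   n_motifs_dk = sum(enr$table$direction == "DK"),
                   timing_sec = as.list(timing))

  list(sim = sim, embedding = emb, operator = op, stages = stages,
       retained = mask, expr = expr, profile = profile,
       profile_traj = prof_traj, screen = screen, gene_sets = gene_sets,
       de = de, tf_clustering = tf_clustering, tf_branch = branch,
       antioxidant = antioxidant, enrichment = enr,
       concordance = concordance, network_bk = networks$BK,
       network_dk = networks$DK, scores = scores, ranking = ranking,
       manifest = manifest)
}
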