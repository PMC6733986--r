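#' Signed soft-thresholded TF-gene expression similarity
#'
#' `s(i, j) = sign(r_ij) * |r_ij|^beta` where `r` is the Pearson
#' correlation between TF `i` and gene `j` over the selected cells. The
#' sign-preserving power emphasizes strong (anti)correlations while
#' keeping the activating/repressive direction.
#'
#' @param expr genes x cells log-transformed imputed expression.
#' @param tfs,genes row identifiers for the TF and gene sides.
#' @param cells cell ids restricting the correlation (>= 10 required).
#' @param beta soft-threshold power (default 6; `beta = 1` gives the raw
#'   correlation matrix).
#' @return A `similarity_matrix`: list with `s` (TF x gene), `beta`,
#'   `cells`.
#' @export
signed_similarity <- function(expr, tfs, genes, cells = colnames(expr),
                              beta = 6) {
  if (length(cells) < 10) stop("need at least 10 cells", call. = FALSE)
  xt <- expr[tfs, cells, drop = FALSE]
  xg <- expr[genes, cells, drop = FALSE]
  sdt <- apply(xt, 1L, stats::sd)
  sdg <- apply(xg, 1L, stats::sd)
  bad <- c(tfs[sdt == 0], genes[sdg == 0])
  if (length(bad))
    stop("zero-variance vectors over the selected cells: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  r <- stats::cor(t(xt), t(xg))
  s <- sign(r) * abs(r)^beta
  structure(list(s = s, beta = beta, cells = cells),
            class = "similarity_matrix")
}

#' Cluster TFs into expression modules
#'
#' Agglomerative clustering (average linkage) on `1 - Pearson` distance
#' between TF per-cell expression vectors over the selected cells.
#'
#' @param expr genes x cells log-transformed imputed expression.
#' @param tfs TF row identifiers.
#' @param cells cell ids restricting the correlation.
#' @param n_modules number of modules (<= number of TFs).
#' @return Named integer vector TF -> module id, hclust tree in the
#'   `linkage` attribute.
#' @export
cluster_tf_modules <- function(expr, tfs, cells = colnames(expr),
                               n_modules) {
  if (n_modules > length(tfs))
    stop("n_modules must be <= number of TFs", call. = FALSE)
  if (length(tfs) == 1L)
    return(structure(stats::setNames(1L, tfs), linkage = NULL))
  hc <- .cor_hclust(expr[tfs, cells, drop = FALSE])
  out <- stats::cutree(hc, k = n_modules)
  attr(out, "linkage") <- hc
  out
}

#' Cluster genes into modules by their TF-correlation profiles
#'
#' Each gene is represented by its row of the signed similarity matrix
#' across TFs; distance is `1 - Pearson` between these profiles, average
#' linkage. Genes with a constant profile cannot enter the correlation
#' distance and are assigned to the nearest module centroid by Euclidean
#' distance instead (flagged in the `fallback` attribute).
#'
#' @param sim a [signed_similarity()] result.
#' @param n_modules number of gene modules.
#' @return Named integer vector gene -> module id.
#' @export
cluster_gene_modules <- function(sim, n_modules) {
  stopifnot(inherits(sim, "similarity_matrix"))
  prof <- t(sim$s) # genes x TFs
  if (n_modules > nrow(prof))
    stop("n_modules must be <= number of genes", call. = FALSE)
  sdv <- apply(prof, 1L, stats::sd)
  const <- sdv == 0
  hc <- .cor_hclust(prof[!const, , drop = FALSE])
  labels <- stats::cutree(hc, k = n_modules)
  if (any(const)) {
    cent <- do.call(rbind, lapply(seq_len(n_modules), function(m)
      colMeans(prof[names(labels)[labels == m], , drop = FALSE])))
    extra <- vapply(rownames(prof)[const], function(g)
      which.min(colSums((t(cent) - prof[g, ])^2)), integer(1))
    labels <- c(labels, extra)
  }
  out <- labels[rownames(prof)]
  names(out) <- rownames(prof)
  attr(out, "fallback") <- rownames(prof)[const]
  attr(out, "linkage") <- hc
  out
}

#' Call signed module-level regulatory edges
#'
#' For every (TF module, gene module) pair, the mean signed similarity
#' over all constituent TF-gene pairs; an edge is emitted when its
#' absolute mean exceeds `threshold`, signed activation/inhibition by the
#' mean's sign.
#'
#' @param sim a [signed_similarity()] result.
#' @param tf_modules,gene_modules named module assignments (see
#'   [cluster_tf_modules()], [cluster_gene_modules()]).
#' @param threshold minimum absolute mean similarity (strict).
#' @return data.frame with tf_module, gene_module, mean_s, strength, sign
#'   for every emitted edge; the full pair table in attribute `all_pairs`.
#' @export
module_edges <- function(sim, tf_modules, gene_modules, threshold) {
  stopifnot(inherits(sim, "similarity_matrix"))
  s <- sim$s[names(tf_modules), names(gene_modules), drop = FALSE]
  pairs <- expand.grid(tf_module = sort(unique(tf_modules)),
                       gene_module = sort(unique(gene_modules)))
  pairs$mean_s <- mapply(function(a, b)
    mean(s[tf_modules == a, gene_modules == b, drop = FALSE]),
    pairs$tf_module, pairs$gene_module)
  pairs$strength <- abs(pairs$mean_s)
  pairs$sign <- ifelse(pairs$mean_s > 0, "activation", "inhibition")
  edges <- pairs[pairs$strength > threshold, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- pairs
  edges
}

#' Permutation-null edge threshold
#'
#' Permutes the gene -> module assignment, recomputes all absolute mean
#' block similarities, pools them over permutations, and returns the
#' requested quantile of the pooled null.
#'
#' @param sim a [signed_similarity()] result.
#' @param tf_modules,gene_modules module assignments.
#' @param n_permutations number of gene-label permutations (>= 100).
#' @param q_quantile quantile of the pooled null (default 0.95).
#' @param seed integer seed.
#' @return Numeric threshold.
#' @export
edge_threshold_from_null <- function(sim, tf_modules, gene_modules,
                                     n_permutations = 200,
                                     q_quantile = 0.95, seed = 1L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  with_seed(substream_seed(seed, "edge-null"), {
    pool <- unlist(lapply(seq_len(n_permutations), function(i) {
      gm <- stats::setNames(sample(gene_modules), names(gene_modules))
      e <- module_edges(sim, tf_modules, gm, threshold = -1)
      attr(e, "all_pairs")$strength
    }))
  })
  stats::quantile(pool, q_quantile, names = FALSE)
}

#' Bimodal split threshold on module-pair mean similarities
#'
#' The distribution of absolute block-mean similarities over all (TF
#' module, gene module) pairs separates coherent regulatory blocks from
#' background blocks. Block means below `floor` (typically the
#' permutation-null noise level, see [edge_threshold_from_null()]) are
#' set aside first; among the remaining blocks the threshold is the exact
#' 1-D two-class split minimizing within-class variance (Otsu's
#' criterion), placed midway across the gap between the classes.
#'
#' @param sim a [signed_similarity()] result.
#' @param tf_modules,gene_modules module assignments.
#' @param floor lower bound below which blocks count as noise (default 0).
#' @return Numeric threshold (never below `floor`).
#' @export
edge_threshold_bimodal <- function(sim, tf_modules, gene_modules,
                                   floor = 0) {
  e <- module_edges(sim, tf_modules, gene_modules, threshold = -1)
  v <- sort(attr(e, "all_pairs")$strength)
  v <- v[v > floor]
  n <- length(v)
  if (n < 3) return(floor)
  best <- Inf
  cut <- 1L
  for (k in seq_len(n - 1L)) {
    lo <- if (k >= 2) (k - 1) * stats::var(v[seq_len(k)]) else 0
    hi <- if (n - k >= 2) (n - k - 1) * stats::var(v[(k + 1):n]) else 0
    ss <- lo + hi
    if (ss < best) { best <- ss; cut <- k }
  }
  max(floor, (v[cut] + v[cut + 1L]) / 2)
}

#' Build the module-level regulatory network for one state
#'
#' Wires the upstream artifacts together for a state: the BK network
#' correlates over cells in stages 1-4, uses TFs whose motifs are
#' BK-enriched, and candidate genes not down-regulated in BK (i.e.
#' excluding DK-specific genes); the DK network mirrors this with stages
#' 4..K-1, DK-enriched TFs, and exclusion of BK-specific genes. Rows with
#' zero variance over the selected cells are dropped with a message, the
#' signed soft-thresholded similarity is clustered into TF and gene
#' modules, and edges are called against a fixed or permutation-null
#' threshold.
#'
#' @param state `"BK"` or `"DK"`.
#' @param expr genes x cells log2 imputed cpm.
#' @param stages a `stage_assignment` over the columns of `expr`.
#' @param enrichment motif enrichment table (tf, direction, ...), see
#'   [motif_enrichment()].
#' @param de moderated DE table, see [moderated_de()].
#' @param gene_sets a [assemble_gene_sets()] result.
#' @param beta soft-threshold power (default 6).
#' @param n_tf_modules,n_gene_modules module counts (defaults: one module
#'   per TF, and 2 modules per TF plus one).
#' @param threshold fixed edge threshold; `"null"` (default) calibrates it
#'   with [edge_threshold_from_null()] at `null_quantile`, `"bimodal"` with
#'   it with [edge_threshold_bimodal()], `"null"` with
#'   [edge_threshold_from_null()] at `null_quantile`.
#' @param null_quantile quantile for the permutation-null threshold.
#' @param n_permutations permutations for the null threshold.
#' @param seed integer seed.
#' @return List with `state`, `similarity`, `tf_modules`, `gene_modules`,
#'   `edges`, `threshold`, `cells`.
#' @export
build_state_network <- function(state = c("BK", "DK"), expr, stages,
                                enrichment, de, gene_sets, beta = 6,
                                n_tf_modules = NULL, n_gene_modules = NULL,
                                threshold = "null", null_quantile = 0.95,
                                n_permutations = 200, seed = 1L) {
  state <- match.arg(state)
  stopifnot(inherits(gene_sets, "gene_sets"))
  labels <- if (inherits(stages, "stage_assignment")) stages$labels else
    stages
  K <- max(labels)
  stage_range <- if (state == "BK") 1:4 else 4:(K - 1)
  other <- if (state == "BK") "DK" else "BK"
  cells <- names(labels)[labels %in% stage_range]
  cells <- intersect(cells, colnames(expr))
  tfs <- enrichment$tf[enrichment$direction == state]
  tfs <- intersect(tfs, rownames(expr))
  if (!length(tfs))
    stop("no TFs with motifs enriched in ", state, " super-enhancers",
         call. = FALSE)
  excluded <- de$gene[de$state_specific == other]
  genes <- setdiff(intersect(gene_sets$keratinocyte_genes, rownames(expr)),
                   excluded)
  ## the TF side is correlated against targets other than itself
  sub <- expr[union(tfs, genes), cells, drop = FALSE]
  sdv <- apply(sub, 1L, stats::sd)
  if (any(sdv == 0)) {
    message(sum(sdv == 0), " zero-variance row(s) dropped over stages ",
            paste(range(stage_range), collapse = "-"))
    tfs <- tfs[sdv[tfs] > 0]
    genes <- genes[sdv[genes] > 0]
  }
  if (is.null(n_tf_modules)) n_tf_modules <- length(tfs)
  if (is.null(n_gene_modules))
    n_gene_modules <- min(5L * length(tfs) + 1L, length(genes))
  sim <- signed_similarity(expr, tfs, genes, cells, beta)
  tfm <- cluster_tf_modules(expr, tfs, cells, n_tf_modules)
  gm <- cluster_gene_modules(sim, n_gene_modules)
  if (is.character(threshold)) {
    kind <- match.arg(threshold, c("bimodal", "null"))
    threshold <- edge_threshold_from_null(sim, tfm, gm, n_permutations,
                                          null_quantile, seed)
    if (kind == "bimodal")
      threshold <- edge_threshold_bimodal(sim, tfm, gm, floor = threshold)
  }
  edges <- module_edges(sim, tfm, gm, threshold)
  list(state = state, similarity = sim, tf_modules = tfm,
       gene_modules = gm, edges = edges, threshold = threshold,
       cells = cells, stage_range = stage_range)
}

#' Pairwise recovery of planted TF-target structure by a module network
#'
#' Expands the module-level edges to the (TF, target gene) pairs they
#' cover and scores them against the planted signed TF-target truth:
#' precision is the fraction of covered pairs that are planted pairs with
#' the matching sign, recall the fraction of planted pairs (restricted to
#' TFs and target-role genes present in the network) covered with the
#' matching sign. Pairs whose gene side is itself a TF are ignored.
#'
#' @param network a [build_state_network()] result.
#' @param truth a `planted_truth` with `tf_target_sign` and `gene_role`.
#' @return List with `precision`, `recall`, `n_true`, `n_predicted`.
#' @export
evaluate_network_recovery <- function(network, truth) {
  tfm <- network$tf_modules
  gm <- network$gene_modules
  target_genes <- names(gm)[truth$gene_role[names(gm)] == "target"]
  tts <- truth$tf_target_sign
  truth_pairs <- tts[tts$tf %in% names(tfm) & tts$gene %in% target_genes, ]
  key <- function(tf, gene) paste(tf, gene, sep = "\r")
  truth_sign <- stats::setNames(truth_pairs$sign,
                                key(truth_pairs$tf, truth_pairs$gene))
  pred_tf <- character(); pred_gene <- character(); pred_sign <- integer()
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    tt <- names(tfm)[tfm == ed$tf_module[i]]
    gg <- intersect(names(gm)[gm == ed$gene_module[i]], target_genes)
    if (!length(gg) || !length(tt)) next
    grid <- expand.grid(tf = tt, gene = gg, stringsAsFactors = FALSE)
    pred_tf <- c(pred_tf, grid$tf)
    pred_gene <- c(pred_gene, grid$gene)
    pred_sign <- c(pred_sign,
                   rep(if (ed$sign[i] == "activation") 1L else -1L,
                       nrow(grid)))
  }
  pk <- key(pred_tf, pred_gene)
  correct <- !is.na(truth_sign[pk]) & truth_sign[pk] == pred_sign
  list(precision = if (length(pk)) mean(correct) else NA_real_,
       recall = if (length(truth_sign)) sum(correct) / length(truth_sign)
       else NA_real_,
       n_true = length(truth_sign), n_predicted = length(pk))
}
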