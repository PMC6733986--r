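#' Filter genes for dynamic expression across stages
#'
#' Keeps genes whose stage-wise mean log2 expression spans at least
#' `min_range_log2fc` between its highest and lowest stage.
#'
#' @param profile a [stage_profile()] (or its `mean_expr` matrix).
#' @param min_range_log2fc minimum max-minus-min log2 range (default 1).
#' @return Character vector of dynamic gene ids.
#' @export
dynamic_gene_filter <- function(profile, min_range_log2fc = 1) {
  me <- if (inherits(profile, "stage_profile")) profile$mean_expr else profile
  rng <- apply(me, 1L, max) - apply(me, 1L, min)
  rownames(me)[rng >= min_range_log2fc]
}

## shared hierarchical clustering engine on Pearson correlation distance
## between the rows of `mat`; rows are sorted lexicographically first so
## hclust tie-breaking is deterministic in the identifiers, not the input
## order
.cor_hclust <- function(mat, linkage = "average") {
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  sdv <- apply(mat, 1L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance trajectories must be filtered first: ",
         paste(utils::head(rownames(mat)[sdv == 0], 5), collapse = ", "),
         call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = linkage)
}

#' Hierarchically cluster stage trajectories
#'
#' Distance between two genes is `1 - Pearson(trajectory_g, trajectory_h)`
#' on the stage-wise mean log2 expression rows; agglomeration uses average
#' linkage by default. Gene order is made deterministic by lexicographic
#' sorting before clustering.
#'
#' @param profile a [stage_profile()] (or a gene x stage matrix).
#' @param genes genes to cluster (default all rows); must be at least
#'   `n_clusters` and contain no zero-variance trajectories.
#' @param n_clusters number of clusters to cut the tree into.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return A `trajectory_clustering`: list with `gene_labels` (named
#'   integer vector), `linkage` (the hclust tree), `n_clusters`,
#'   `distance_kind = "pearson-correlation-distance"`.
#' @export
cluster_trajectories <- function(profile, genes = NULL, n_clusters,
                                 linkage = "average") {
  me <- if (inherits(profile, "stage_profile")) profile$mean_expr else profile
  if (!is.null(genes)) me <- me[genes, , drop = FALSE]
  if (nrow(me) < n_clusters)
    stop("need at least n_clusters genes", call. = FALSE)
  hc <- .cor_hclust(me, linkage)
  labels <- stats::cutree(hc, k = n_clusters)
  structure(list(gene_labels = labels, linkage = hc,
                 n_clusters = n_clusters,
                 distance_kind = "pearson-correlation-distance"),
            class = "trajectory_clustering")
}

#' Stage of peak expression
#'
#' Argmax over stages of the mean log2 expression; ties resolve to the
#' lowest stage and are flagged in the `tie` attribute.
#'
#' @param profile a [stage_profile()] (or gene x stage matrix).
#' @param genes gene id(s); default all rows.
#' @return Named integer vector of stage indices (stage column labels).
#' @export
peak_stage <- function(profile, genes = NULL) {
  me <- if (inherits(profile, "stage_profile")) profile$mean_expr else profile
  if (!is.null(genes)) me <- me[genes, , drop = FALSE]
  idx <- apply(me, 1L, which.max)
  tie <- apply(me, 1L, function(r) sum(r == max(r)) > 1L)
  stages <- as.integer(colnames(me))
  if (anyNA(stages)) stages <- seq_len(ncol(me))
  out <- stats::setNames(stages[idx], rownames(me))
  attr(out, "tie") <- rownames(me)[tie]
  out
}

#' Exact binomial test for cluster-size enrichment
#'
#' Under an equal-probability null, the probability that a cluster of `k`
#' of `n` genes is at least as large as observed is the exact binomial
#' upper tail `P(X >= k | n, 1/n_clusters)` computed by direct summation.
#'
#' @param clustering a [cluster_trajectories()] result (or a label vector).
#' @param cluster_id the cluster whose size is tested.
#' @param n_clusters number of clusters defining the null probability
#'   (default taken from `clustering`; must be >= 2).
#' @return List with `k`, `n`, `p`.
#' @export
cluster_size_enrichment <- function(clustering, cluster_id,
                                    n_clusters = NULL) {
  labels <- if (inherits(clustering, "trajectory_clustering"))
    clustering$gene_labels else clustering
  if (is.null(n_clusters))
    n_clusters <- if (inherits(clustering, "trajectory_clustering"))
      clustering$n_clusters else length(unique(labels))
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (!cluster_id %in% labels)
    stop("cluster ", cluster_id, " does not exist", call. = FALSE)
  k <- sum(labels == cluster_id)
  n <- length(labels)
  p <- sum(stats::dbinom(k:n, n, 1 / n_clusters))
  list(k = k, n = n, p = min(1, p))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a query gene set against each
#' annotation set within a background universe, BH-corrected. Generic
#' stand-in for web-service GO queries.
#'
#' @param query character vector of genes of interest.
#' @param sets named list of annotation gene sets (e.g. [read_gmt()]).
#' @param background background universe; query must be contained in it.
#' @return data.frame with set, overlap, set_size, query_size, p, q.
#' @export
set_enrichment <- function(query, sets, background) {
  query <- intersect(query, background)
  if (!length(query)) stop("query is empty within background", call. = FALSE)
  n_bg <- length(background)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), n_bg - length(s), length(query),
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(query), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out
}
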