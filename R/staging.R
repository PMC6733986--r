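#' Log counts-per-million normalization
#'
#' Computes `log2(1e6 * count / column_sum + pseudocount)` per entry, the
#' log-cpm transform applied to non-imputed counts ahead of embedding and
#' differential expression.
#'
#' @param counts genes x cells non-negative matrix with dimnames.
#' @param pseudocount positive real added inside the log (default 1).
#' @return A genes x cells numeric matrix.
#' @export
normalize_log_cpm <- function(counts, pseudocount = 1) {
  .check_count_matrix(counts)
  stopifnot(pseudocount > 0)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("degenerate input: cell(s) with zero total counts: ",
         paste(colnames(counts)[cs == 0], collapse = ", "), call. = FALSE)
  log2(sweep(counts, 2L, 1e6 / cs, `*`) + pseudocount)
}

#' Principal-component embedding of cells
#'
#' Low-dimensional representation of cells feeding the distance-based
#' diffusion operator and the spectral clustering. Rows are cells.
#'
#' @param log_expr genes x cells matrix (typically [normalize_log_cpm()]).
#' @param n_pcs number of components (default 30).
#' @return cells x `n_pcs` score matrix with cell rownames.
#' @export
pca_embedding <- function(log_expr, n_pcs = 30) {
  n_pcs <- min(n_pcs, nrow(log_expr) - 1L, ncol(log_expr) - 1L)
  pc <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(emb) <- colnames(log_expr)
  emb
}

#' Build a cell-cell Markov diffusion operator
#'
#' Adaptive Gaussian kernel on the k-nearest-neighbor graph:
#' `a(i,j) = exp(-(d(i,j)/sigma_i)^2)` for `j` among `i`'s `k_neighbors`
#' nearest neighbors (self included with affinity 1), where `sigma_i` is
#' the distance to `i`'s `ka_adaptive`-th neighbor. The affinity matrix is
#' symmetrized as `(A + t(A))/2` and row-normalized to a Markov matrix.
#' Duplicated points making `sigma_i = 0` fall back to the global median
#' positive distance.
#'
#' @param embedding cells x d matrix (d >= 2), cell rownames.
#' @param k_neighbors neighborhood size (< number of cells).
#' @param ka_adaptive adaptive-bandwidth neighbor index (<= k_neighbors).
#' @return A `diffusion_operator`: list with `matrix` (sparse row-stochastic
#'   cells x cells), `k_neighbors`, `ka_adaptive`.
#' @export
build_diffusion_operator <- function(embedding, k_neighbors = 30,
                                     ka_adaptive = 10) {
  n <- nrow(embedding)
  if (ncol(embedding) < 2) stop("embedding must have d >= 2", call. = FALSE)
  if (k_neighbors >= n)
    stop("k_neighbors must be smaller than the number of cells",
         call. = FALSE)
  if (ka_adaptive > k_neighbors)
    stop("ka_adaptive must be <= k_neighbors", call. = FALSE)
  d <- as.matrix(stats::dist(embedding))
  med <- stats::median(d[d > 0])
  ii <- jj <- integer(n * (k_neighbors + 1L))
  xx <- numeric(n * (k_neighbors + 1L))
  pos <- 0L
  for (i in seq_len(n)) {
    o <- order(d[i, ])
    o <- o[o != i][seq_len(k_neighbors)]
    sigma <- d[i, o[ka_adaptive]]
    if (sigma == 0) sigma <- med
    idx <- pos + seq_len(k_neighbors + 1L)
    ii[idx] <- i
    jj[idx] <- c(i, o)
    xx[idx] <- c(1, exp(-(d[i, o] / sigma)^2))
    pos <- pos + k_neighbors + 1L
  }
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  a <- (a + Matrix::t(a)) / 2
  m <- a / Matrix::rowSums(a)
  dimnames(m) <- list(rownames(embedding), rownames(embedding))
  structure(list(matrix = m, k_neighbors = k_neighbors,
                 ka_adaptive = ka_adaptive),
            class = "diffusion_operator")
}

#' Diffusion imputation of expression values
#'
#' Replaces each cell's expression by the `t`-step diffusion average over
#' the cell-cell Markov operator: `imputed = expr %*% t(M)^t`. `t = 0`
#' returns the input exactly; larger `t` smooths more strongly.
#'
#' @param expr genes x cells matrix on the scale to be imputed (cpm here).
#' @param op a [build_diffusion_operator()] result over the same cells.
#' @param t non-negative integer diffusion time.
#' @return genes x cells imputed matrix.
#' @export
impute_expression <- function(expr, op, t) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (t < 0) stop("imputation time t must be non-negative", call. = FALSE)
  if (ncol(expr) != nrow(op$matrix))
    stop("operator was built over a different cell set", call. = FALSE)
  if (t == 0) return(expr)
  tm <- Matrix::t(op$matrix)
  out <- expr
  for (i in seq_len(t)) out <- out %*% tm
  out <- as.matrix(out)
  dimnames(out) <- dimnames(expr)
  out
}

## connected components of a nonnegative symmetric affinity via BFS
.components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## normalized spectral clustering of points whose affinity matrix is given
.spectral_partition <- function(w, K, seed) {
  dg <- rowSums(w)
  dg[dg == 0] <- 1
  s <- sweep(sweep(w, 1L, sqrt(dg), `/`), 2L, sqrt(dg), `/`)
  ev <- eigen((s + t(s)) / 2, symmetric = TRUE)
  u <- ev$vectors[, seq_len(K), drop = FALSE]
  nr <- sqrt(rowSums(u^2))
  nr[nr == 0] <- 1
  u <- u / nr
  with_seed(seed, stats::kmeans(u, centers = K, nstart = 10L,
                                iter.max = 100L))$cluster
}

#' Assign cells to stages by k-means-based approximate spectral clustering
#'
#' (1) k-means with `m_representatives` centers summarizes the cells;
#' (2) Gaussian affinity among the centers (bandwidth = median pairwise
#' center distance); (3) symmetric normalized Laplacian; (4) rows of the
#' top-K eigenvector matrix normalized to unit length; (5) k-means into K
#' clusters on that spectral embedding; (6) every cell inherits its nearest
#' center's cluster. Labels are renumbered 1..K by increasing cluster mean
#' along the first principal axis, so "stage 1" is reproducible. If the
#' center affinity graph is disconnected (kernel underflow between distant
#' groups), each component is clustered separately with a warning.
#'
#' @param embedding cells x d matrix (e.g. [pca_embedding()]).
#' @param K number of stages.
#' @param m_representatives number of k-means summarization centers
#'   (`K <= m <= n_cells`; `m = n` reduces to plain normalized spectral
#'   clustering of all cells).
#' @param seed integer seed for the k-means substreams.
#' @return A `stage_assignment`: list with `labels` (named integer vector
#'   in 1..K), `K`, `representative_index` (cell -> center index).
#' @export
approx_spectral_cluster <- function(embedding, K, m_representatives = 800,
                                    seed = 1L) {
  n <- nrow(embedding)
  m <- min(m_representatives, n)
  if (K > m) stop("need K <= m_representatives <= n_cells", call. = FALSE)
  if (m < n) {
    km <- with_seed(substream_seed(seed, "representatives"),
                    suppressWarnings(stats::kmeans(
                      embedding, centers = m, nstart = 5L, iter.max = 100L)))
    centers <- km$centers
    rep_index <- km$cluster
  } else {
    centers <- embedding
    rep_index <- seq_len(n)
  }
  d <- as.matrix(stats::dist(centers))
  sigma <- stats::median(d[upper.tri(d)])
  w <- exp(-d^2 / (2 * sigma^2))
  comp <- .components(w * (w > 1e-300))
  if (max(comp) == 1L) {
    cl_centers <- .spectral_partition(w, K, substream_seed(seed, "spectral"))
  } else {
    warning("affinity graph has ", max(comp),
            " disconnected components; clustering each separately")
    sizes <- tabulate(comp)
    kk <- pmax(1L, round(K * sizes / sum(sizes)))
    while (sum(kk) > K) kk[which.max(kk)] <- kk[which.max(kk)] - 1L
    while (sum(kk) < K) kk[which.max(sizes - kk)] <-
        kk[which.max(sizes - kk)] + 1L
    cl_centers <- integer(nrow(w))
    off <- 0L
    for (cc in seq_len(max(comp))) {
      idx <- which(comp == cc)
      cl_centers[idx] <- if (kk[cc] == 1L || length(idx) <= kk[cc])
        off + pmin(seq_along(idx), kk[cc])
      else off + .spectral_partition(w[idx, idx, drop = FALSE], kk[cc],
                                     substream_seed(seed,
                                                    paste0("spectral", cc)))
      off <- off + kk[cc]
    }
  }
  labels <- cl_centers[rep_index]
  ## renumber so stage means increase along the first embedding axis
  means <- tapply(embedding[, 1L], labels, mean)
  remap <- integer(max(labels))
  remap[as.integer(names(sort(means)))] <- seq_along(means)
  labels <- remap[labels]
  names(labels) <- rownames(embedding)
  structure(list(labels = labels, K = max(labels),
                 representative_index = stats::setNames(rep_index,
                                                        rownames(embedding))),
            class = "stage_assignment")
}

#' Flag within-stage outlier cells
#'
#' For each stage, cells whose Euclidean distance to the stage centroid
#' exceeds `median + c_mad * MAD` (strict inequality) are flagged out.
#' Stages smaller than 5 cells are skipped with a warning; a stage losing
#' more than half its cells is an error.
#'
#' @param embedding cells x d matrix.
#' @param stages a `stage_assignment` covering the same cells.
#' @param c_mad multiplier on the (scaled) median absolute deviation;
#'   `Inf` removes nothing.
#' @return Named logical vector, `TRUE` for retained cells.
#' @export
remove_outliers <- function(embedding, stages, c_mad = 3) {
  stopifnot(inherits(stages, "stage_assignment"))
  labels <- stages$labels[rownames(embedding)]
  if (anyNA(labels)) stop("stages must cover all cells", call. = FALSE)
  keep <- rep(TRUE, nrow(embedding))
  names(keep) <- rownames(embedding)
  if (!is.finite(c_mad)) return(keep)
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    if (length(idx) < 5L) {
      warning("stage ", s, " has fewer than 5 cells; outlier removal skipped")
      next
    }
    x <- embedding[idx, , drop = FALSE]
    ctr <- colMeans(x)
    dd <- sqrt(rowSums(sweep(x, 2L, ctr)^2))
    thr <- stats::median(dd) + c_mad * stats::mad(dd)
    out <- dd > thr
    if (sum(out) > length(idx) / 2)
      stop("outlier rule would remove more than half of stage ", s,
           call. = FALSE)
    keep[idx[out]] <- FALSE
  }
  keep
}

#' Stage-wise mean expression profiles
#'
#' `mean_expr(g, s) = log2(mean over cells in stage s of imputed cpm + 1)`;
#' `normalized` is the per-gene z-score of that row across the included
#' stages (constant genes map to all-zero rows and are flagged in the
#' `constant` attribute; min-max scaling available via `normalize`).
#'
#' @param imputed genes x cells non-negative imputed cpm matrix.
#' @param stages a `stage_assignment` (or named integer vector) for the
#'   columns of `imputed`.
#' @param stage_subset stages to include, default all observed.
#' @param normalize `"zscore"` (default) or `"minmax"`.
#' @return A `stage_profile`: list with `mean_expr`, `normalized`
#'   (gene x stage matrices, columns named by stage) and `stages`.
#' @export
stage_profile <- function(imputed, stages, stage_subset = NULL,
                          normalize = c("zscore", "minmax")) {
  normalize <- match.arg(normalize)
  labels <- if (inherits(stages, "stage_assignment")) stages$labels else stages
  labels <- labels[colnames(imputed)]
  if (anyNA(labels)) stop("stages must cover all cells", call. = FALSE)
  if (any(imputed < 0)) stop("imputed values must be non-negative",
                             call. = FALSE)
  if (is.null(stage_subset)) stage_subset <- sort(unique(labels))
  missing <- setdiff(stage_subset, labels)
  if (length(missing))
    stop("empty stage(s) in subset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  me <- matrix(vapply(stage_subset, function(s)
    log2(rowMeans(imputed[, labels == s, drop = FALSE]) + 1),
    numeric(nrow(imputed))), nrow = nrow(imputed))
  dimnames(me) <- list(rownames(imputed), as.character(stage_subset))
  nz <- if (normalize == "zscore") .row_zscore(me) else .row_minmax(me)
  structure(list(mean_expr = me, normalized = nz, stages = stage_subset,
                 constant = attr(nz, "constant")),
            class = "stage_profile")
}
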