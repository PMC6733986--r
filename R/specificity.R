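#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The p-value is computed by exact
#' enumeration over all rank assignments when the combined sample size is
#' at most 12 and there are no ties, and otherwise by the normal
#' approximation with tie correction and continuity correction. The U
#' statistic counts pairs where `x` exceeds `y` (ties count 1/2), so
#' `alternative = "greater"` tests whether `x` is stochastically larger.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative one of `"two_sided"`, `"greater"`, `"less"`.
#' @return List with `u` (the U statistic for `x`), `p`, and `exact`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1, length(y) >= 1, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- c(x, y)
  r <- rank(z)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(z)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(u = u, p = 1, exact = FALSE))
  }
  ties <- anyDuplicated(z) > 0L
  if (N <= 12L && !ties) {
    sets <- utils::combn(N, n1)
    us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p_ge <- mean(us >= u - tol)
    p_le <- mean(us <= u + tol)
    p <- switch(alternative, greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    return(list(u = u, p = p, exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(z)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 <= 0) return(list(u = u, p = 1, exact = FALSE))
  sig <- sqrt(sig2)
  p <- switch(alternative,
              greater = stats::pnorm((u - mu - 0.5) / sig, lower.tail = FALSE),
              less = stats::pnorm((u - mu + 0.5) / sig),
              two_sided = {
                cc <- if (u == mu) 0 else sign(u - mu) * 0.5
                min(1, 2 * stats::pnorm(-abs(u - mu - cc) / sig))
              })
  list(u = u, p = min(1, max(0, p)), exact = FALSE)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' `q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j`, clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (no NA).
#' @return Vector of q-values, order-preserving in `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values are not allowed", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
}

#' Sum feature-level expression to gene level
#'
#' Each gene's row is the sum of the rows of the features annotated to it
#' (CAGE-peak style aggregation); unmapped features are dropped with a
#' message.
#'
#' @param bulk a `bulk_expression` object with a `feature_to_gene` map.
#' @return A gene-level `bulk_expression` (identity feature map).
#' @export
aggregate_features_to_genes <- function(bulk) {
  stopifnot(inherits(bulk, "bulk_expression"))
  f2g <- bulk$feature_to_gene
  if (is.null(f2g) || !length(f2g))
    stop("feature_to_gene map is required", call. = FALSE)
  f2g <- f2g[rownames(bulk$values)]
  drop <- is.na(f2g)
  if (any(drop))
    message(sum(drop), " unmapped feature(s) dropped")
  v <- bulk$values[!drop, , drop = FALSE]
  g <- f2g[!drop]
  agg <- rowsum(v, group = g)
  structure(list(values = agg, sample_group = bulk$sample_group,
                 feature_to_gene = stats::setNames(rownames(agg),
                                                   rownames(agg))),
            class = "bulk_expression")
}

#' Screen a bulk atlas for target-cell-type-specific genes
#'
#' Per gene, a two-sided Mann-Whitney U test of the target-group samples
#' against all remaining samples, BH-corrected across genes; a gene is
#' selected when `q < alpha` and its mean expression is higher in the
#' target group. Samples listed in `exclude_samples` are removed before
#' testing. Constant genes get p = 1.
#'
#' @param bulk_gene gene-level `bulk_expression`
#'   (see [aggregate_features_to_genes()]).
#' @param target_group cell-type label of the target samples (>= 2
#'   samples required).
#' @param alpha FDR threshold (default 0.05).
#' @param exclude_samples sample ids dropped before the screen.
#' @return data.frame with gene, u, p, q, direction, selected.
#' @export
celltype_specific_screen <- function(bulk_gene, target_group = "keratinocyte",
                                     alpha = 0.05,
                                     exclude_samples = character()) {
  stopifnot(inherits(bulk_gene, "bulk_expression"))
  keep <- setdiff(colnames(bulk_gene$values), exclude_samples)
  v <- bulk_gene$values[, keep, drop = FALSE]
  grp <- bulk_gene$sample_group[keep]
  tgt <- grp == target_group
  if (sum(tgt) < 2L)
    stop("target group needs at least 2 samples", call. = FALSE)
  res <- t(apply(v, 1L, function(row) {
    if (length(unique(row)) == 1L) return(c(u = sum(tgt) * sum(!tgt) / 2,
                                            p = 1))
    w <- suppressWarnings(mann_whitney_u(row[tgt], row[!tgt], "two_sided"))
    c(u = w$u, p = w$p)
  }))
  up <- rowMeans(v[, tgt, drop = FALSE]) > rowMeans(v[, !tgt, drop = FALSE])
  q <- bh_fdr(res[, "p"])
  data.frame(gene = rownames(v), u = res[, "u"], p = res[, "p"], q = q,
             direction = ifelse(up, "up_in_target", "down_in_target"),
             selected = q < alpha & up, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Minimum single-cell expression filter (fractional)
#'
#' Keeps genes with at least `min_umis` raw UMIs in at least
#' `ceiling(min_cell_fraction * n_cells)` cells.
#'
#' @param counts genes x cells raw count matrix.
#' @param min_umis minimum UMI count per qualifying cell (default 1).
#' @param min_cell_fraction minimum fraction of cells (default 0.01).
#' @return Character vector of retained gene ids.
#' @export
scrna_expression_filter <- function(counts, min_umis = 1,
                                    min_cell_fraction = 0.01) {
  .check_count_matrix(counts)
  need <- ceiling(min_cell_fraction * ncol(counts))
  rownames(counts)[rowSums(counts >= min_umis) >= need]
}

#' Minimum single-cell expression filter (absolute)
#'
#' Keeps genes with at least `min_umis` UMIs in at least `min_cells`
#' cells; the expressed-gene filter ahead of differential expression.
#'
#' @param counts genes x cells raw count matrix.
#' @param min_umis minimum UMI count per qualifying cell (default 3).
#' @param min_cells minimum number of qualifying cells (default 20).
#' @return Character vector of retained gene ids.
#' @export
de_expressed_filter <- function(counts, min_umis = 3, min_cells = 20) {
  .check_count_matrix(counts)
  rownames(counts)[rowSums(counts >= min_umis) >= min_cells]
}

#' Assemble the analysis gene sets
#'
#' Splits the specificity-screen hits into TFs and other genes using an
#' annotation list, appends manually added TFs, and forms the derived
#' sets: `keratinocyte_tfs` = `fantom_tfs` union `curated_tfs`,
#' `candidate_tfs` = `fantom_tfs` minus `curated_tfs`, and
#' `keratinocyte_genes` = `keratinocyte_tfs` union `fantom_genes`.
#'
#' @param screen_hits genes selected by the bulk specificity screen.
#' @param tf_annotation character vector of all annotated TF symbols.
#' @param curated_tfs literature-curated regulator set.
#' @param manual_additions TFs appended to the screen TFs (flagged in the
#'   `manual` attribute of `fantom_tfs`).
#' @param universe optional gene universe (e.g. count-matrix rownames);
#'   additions absent from it are kept with a warning.
#' @return A `gene_sets` list: fantom_genes, fantom_tfs, curated_tfs,
#'   keratinocyte_tfs, candidate_tfs, keratinocyte_genes.
#' @export
assemble_gene_sets <- function(screen_hits, tf_annotation, curated_tfs,
                               manual_additions = character(),
                               universe = NULL) {
  if (!is.null(universe)) {
    absent <- setdiff(manual_additions, universe)
    if (length(absent))
      warning("manual addition(s) absent from expression universe: ",
              paste(absent, collapse = ", "))
  }
  fantom_tfs <- union(intersect(screen_hits, tf_annotation),
                      manual_additions)
  attr(fantom_tfs, "manual") <- manual_additions
  fantom_genes <- setdiff(screen_hits, tf_annotation)
  keratinocyte_tfs <- union(fantom_tfs, curated_tfs)
  structure(list(fantom_genes = fantom_genes, fantom_tfs = fantom_tfs,
                 curated_tfs = curated_tfs,
                 keratinocyte_tfs = keratinocyte_tfs,
                 candidate_tfs = setdiff(fantom_tfs, curated_tfs),
                 keratinocyte_genes = union(keratinocyte_tfs, fantom_genes)),
            class = "gene_sets")
}

## Solve trigamma(y) = x by Newton iteration (monotone decreasing).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated two-group differential expression (limma-trend style)
#'
#' Per gene, the log fold change is the DK-minus-BK difference of group
#' means of `log2(cpm + 1)`; the pooled residual variance (n - 2 df) is
#' squeezed towards an empirical-Bayes prior whose degrees of freedom and
#' scale are estimated by moment-matching the distribution of the log
#' sample variances (digamma/trigamma equations). With `trend = TRUE` the
#' prior scale follows a lowess fit of the log variances against mean
#' log-expression. The moderated t statistic uses the posterior variance
#' on `d0 + n - 2` degrees of freedom; q-values are BH across genes, and a
#' gene is called state-specific when `q < alpha` and the moderated fold
#' change exceeds `lfc_threshold` in magnitude (DK if positive, BK if
#' negative).
#'
#' @param log_cpm genes x cells matrix of `log2(cpm + 1)` of non-imputed
#'   counts, pre-filtered by [de_expressed_filter()].
#' @param state named vector over cells with values `"BK"` / `"DK"` (both
#'   states need >= 2 cells).
#' @param trend fit an intensity-dependent prior variance (default TRUE).
#' @param alpha FDR threshold for state-specificity calls.
#' @param lfc_threshold minimum absolute moderated log2 fold change for
#'   state-specificity calls (default 0.25).
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom d0 (0 recovers the ordinary t-test exactly).
#' @return data.frame with gene, logfc, amean, t_mod, df_total, p_value,
#'   q_value, state_specific; prior estimates in attributes `d0`, `s02`.
#' @export
moderated_de <- function(log_cpm, state, trend = TRUE, alpha = 0.05,
                         lfc_threshold = 0.25, prior_df = NULL) {
  state <- state[colnames(log_cpm)]
  if (anyNA(state) || !all(state %in% c("BK", "DK")))
    stop("state must map every cell to 'BK' or 'DK'", call. = FALSE)
  n1 <- sum(state == "BK"); n2 <- sum(state == "DK")
  if (n1 < 2 || n2 < 2)
    stop("each state needs at least 2 cells", call. = FALSE)
  xb <- log_cpm[, state == "BK", drop = FALSE]
  xd <- log_cpm[, state == "DK", drop = FALSE]
  mb <- rowMeans(xb); md <- rowMeans(xd)
  logfc <- md - mb
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * apply(xb, 1L, stats::var) +
           (n2 - 1) * apply(xd, 1L, stats::var)) / df
  amean <- rowMeans(log_cpm)

  ok <- s2 > 0
  zlog <- log(s2[ok])
  e <- zlog - digamma(df / 2) + log(df / 2)
  if (trend && sum(ok) >= 10) {
    lo <- stats::lowess(amean[ok], e, f = 0.5)
    efit <- stats::approx(lo$x, lo$y, xout = amean, rule = 2, ties = mean)$y
    evar <- stats::var(e - efit[ok])
  } else {
    efit <- rep(mean(e), length(s2))
    evar <- stats::var(e)
  }
  evar <- evar - trigamma(df / 2)
  if (is.null(prior_df)) {
    if (is.na(evar) || evar <= 0) {
      warning("log-variances nearly constant; prior df infinite, ",
              "using pooled prior variance")
      d0 <- Inf
    } else d0 <- 2 * .trigamma_inverse(evar)
  } else d0 <- prior_df
  s02 <- if (is.finite(d0) && d0 > 0)
    exp(efit + digamma(d0 / 2) - log(d0 / 2)) else exp(efit)

  st2 <- if (!is.finite(d0)) s02
  else if (d0 == 0) s2 # unmoderated limit
  else (d0 * s02 + df * s2) / (d0 + df)
  df_total <- if (is.finite(d0)) d0 + df else Inf
  tstat <- logfc / sqrt(st2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df_total)
  q <- bh_fdr(p)
  call <- ifelse(q < alpha & logfc > lfc_threshold, "DK",
                 ifelse(q < alpha & logfc < -lfc_threshold, "BK", "none"))
  out <- data.frame(gene = rownames(log_cpm), logfc = logfc, amean = amean,
                    t_mod = tstat, df_total = df_total, p_value = p,
                    q_value = q, state_specific = call, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}
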