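#' Identify signed regulatory targets of a TF by expression correlation
#'
#' Candidate genes whose absolute Pearson correlation with the TF over
#' the selected cells (the on-trajectory stages 1..K-1 in the pipeline)
#' reaches `min_abs_r`, each carrying the correlation's sign (positive =
#' activation).
#'
#' @param expr genes x cells log-transformed imputed expression.
#' @param tf TF row identifier (must vary over the cells).
#' @param candidate_genes genes to test; the TF itself is excluded.
#' @param cells cell ids restricting the correlation.
#' @param min_abs_r minimum |r| (default 0.3).
#' @return data.frame with gene, r, sign.
#' @export
identify_targets <- function(expr, tf, candidate_genes,
                             cells = colnames(expr), min_abs_r = 0.3) {
  candidate_genes <- setdiff(intersect(candidate_genes, rownames(expr)), tf)
  x <- expr[tf, cells]
  if (stats::sd(x) == 0)
    stop("TF ", tf, " has zero variance over the selected cells",
         call. = FALSE)
  xg <- expr[candidate_genes, cells, drop = FALSE]
  sdv <- apply(xg, 1L, stats::sd)
  r <- rep(0, length(candidate_genes))
  r[sdv > 0] <- as.vector(stats::cor(x, t(xg[sdv > 0, , drop = FALSE])))
  keep <- abs(r) >= min_abs_r
  data.frame(gene = candidate_genes[keep], r = r[keep],
             sign = ifelse(r[keep] > 0, 1L, -1L), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differentiation-promoting score of a TF
#'
#' Sum over the TF's signed targets of `sign(r) * logfc(DK - BK)`: a
#' strongly negative score nominates a basal-state (progenitor) promoter,
#' a positive score a differentiation promoter. The target audit list is
#' returned so the score is reproducible from it.
#'
#' @param tf TF identifier.
#' @param targets signed target list from [identify_targets()].
#' @param de moderated DE table (see [moderated_de()]) supplying `logfc`
#'   for every target.
#' @return List with `tf`, `score`, `n_targets`, `targets` (audit
#'   data.frame with gene, r, sign, logfc), `empty` flag.
#' @export
differentiation_score <- function(tf, targets, de) {
  if (nrow(targets) == 0L)
    return(list(tf = tf, score = 0, n_targets = 0L,
                targets = cbind(targets, logfc = numeric(0)), empty = TRUE))
  lfc <- stats::setNames(de$logfc, de$gene)[targets$gene]
  if (anyNA(lfc))
    stop("missing DE log fold change for: ",
         paste(targets$gene[is.na(lfc)], collapse = ", "), call. = FALSE)
  aud <- cbind(targets, logfc = unname(lfc))
  list(tf = tf, score = sum(aud$sign * aud$logfc),
       n_targets = nrow(aud), targets = aud, empty = FALSE)
}

#' Rank knockdown candidates by differentiation-promoting score
#'
#' TFs expressed below `min_fpkm` in undifferentiated keratinocyte
#' cultures are filtered out (strict `<`, so exactly `min_fpkm` is
#' retained); the remainder is sorted ascending by score, most
#' basal-promoting first, with ties broken by target count then
#' lexicographic TF id. TFs absent from the culture table fail the filter
#' with a warning.
#'
#' @param scores list of [differentiation_score()] results (or a
#'   data.frame with tf, score, n_targets).
#' @param culture_expr named numeric vector TF -> FPKM.
#' @param min_fpkm minimum culture expression (default 5).
#' @return data.frame with tf, score, n_targets, fpkm, sorted; the
#'   filtered-out TFs in attribute `filtered_out`.
#' @export
rank_candidates <- function(scores, culture_expr, min_fpkm = 5) {
  tab <- if (is.data.frame(scores)) scores else
    do.call(rbind, lapply(scores, function(s)
      data.frame(tf = s$tf, score = s$score, n_targets = s$n_targets,
                 stringsAsFactors = FALSE)))
  fpkm <- culture_expr[tab$tf]
  missing <- tab$tf[is.na(fpkm)]
  if (length(missing))
    warning("TF(s) absent from culture expression table fail the filter: ",
            paste(missing, collapse = ", "))
  keep <- !is.na(fpkm) & fpkm >= min_fpkm
  out <- tab[keep, , drop = FALSE]
  out$fpkm <- unname(fpkm[keep])
  if (nrow(out) == 0L) {
    warning("all TFs were filtered out")
  } else {
    out <- out[order(out$score, out$n_targets, out$tf), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "filtered_out") <- tab$tf[!keep]
  out
}
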