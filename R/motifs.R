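#' Position weight matrix constructor
#'
#' @param name motif / TF identifier.
#' @param counts 4 x L matrix of position counts or probabilities, rows
#'   A, C, G, T (L >= 4).
#' @param background length-4 background base distribution (sums to 1).
#' @param pseudocount positive pseudocount added to counts before
#'   converting to probabilities.
#' @return A `pwm` object.
#' @export
pwm <- function(name, counts, background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)",
                               call. = FALSE)
  if (ncol(counts) < 4L) stop("motif length must be >= 4", call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  structure(list(name = name, counts = counts,
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T")),
                 pseudocount = pseudocount), class = "pwm")
}

## column-stochastic probability form (columns sum to 1)
.pwm_probs <- function(p) {
  stopifnot(inherits(p, "pwm"))
  cs <- colSums(p$counts)
  probs <- if (all(abs(cs - 1) < 1e-9)) p$counts else
    sweep(p$counts + p$pseudocount, 2L, cs + 4 * p$pseudocount, `/`)
  probs
}

.pwm_consensus <- function(p) {
  probs <- .pwm_probs(p)
  paste(rownames(probs)[apply(probs, 2L, which.max)], collapse = "")
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

## Integerized log-odds matrix and the exact null distribution of window
## scores under the background, by dynamic programming (per-position
## convolution over the integer-rounded score distribution).
.pwm_score_model <- function(p, precision = 100L) {
  probs <- .pwm_probs(p)
  lo <- log2(probs / p$background)
  ilo <- round(lo * precision)
  L <- ncol(ilo)
  cur <- 1 # distribution of the partial score; starts as point mass at 0
  cur_min <- 0L
  for (j in seq_len(L)) {
    vals <- ilo[, j]
    new_min <- cur_min + min(vals)
    new_max <- cur_min + length(cur) - 1L + max(vals)
    new <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      sh <- cur_min + vals[b] - new_min
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * p$background[b]
    }
    cur <- new
    cur_min <- new_min
  }
  list(ilo = ilo, precision = precision, score_min = cur_min,
       null_probs = cur) # null_probs[i] = P(score == score_min + i - 1)
}

## smallest integer score s with P(S >= s) <= pval
.pwm_threshold <- function(model, pval) {
  tail_p <- rev(cumsum(rev(model$null_probs)))
  idx <- which(tail_p <= pval + 1e-15)
  if (!length(idx)) return(model$score_min + length(model$null_probs))
  model$score_min + idx[1L] - 1L
}

.encode_dna <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(code) && any(chars[is.na(code)] != "N"))
    stop("invalid sequence characters: ",
         paste(unique(chars[is.na(code) & chars != "N"]), collapse = ", "),
         call. = FALSE)
  code # NA encodes N
}

## integer window scores on the forward orientation of `code`
.scan_scores <- function(code, ilo) {
  L <- ncol(ilo)
  np <- length(code) - L + 1L
  if (np < 1L) return(integer())
  s <- integer(np)
  for (l in seq_len(L)) {
    v <- ilo[, l][code[l:(l + np - 1L)]]
    v[is.na(v)] <- 0L # N positions contribute background log-odds 0
    s <- s + v
  }
  s
}

#' Count motif occurrences in a sequence
#'
#' Scores every window on both strands with the integer-rounded log-odds
#' of the PWM against its background; a window is a hit when its score
#' meets the score threshold whose exact per-position null p-value (from
#' the dynamic-programming score distribution under the background) is at
#' most `score_threshold_pvalue`. Overlapping hits all count; N bases
#' contribute log-odds 0.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwm a [pwm()] object.
#' @param score_threshold_pvalue per-position null p-value in (0, 0.01]
#'   (default 1e-4).
#' @return Integer occurrence count (0 when the sequence is shorter than
#'   the motif).
#' @export
scan_pwm <- function(sequence, pwm, score_threshold_pvalue = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  if (score_threshold_pvalue <= 0 || score_threshold_pvalue > 0.01)
    stop("score_threshold_pvalue must lie in (0, 0.01]", call. = FALSE)
  model <- .pwm_score_model(pwm)
  thr <- .pwm_threshold(model, score_threshold_pvalue)
  code <- .encode_dna(sequence)
  if (length(code) < ncol(model$ilo)) return(0L)
  rc_code <- rev(5L - code) # A<->T, C<->G on the reverse strand
  sum(.scan_scores(code, model$ilo) >= thr) +
    sum(.scan_scores(rc_code, model$ilo) >= thr)
}

#' Length-scaled motif occurrence counts per region
#'
#' `count(region) * 1000 / (end - start)`: occurrences per kilobase.
#'
#' @param se an `se_region_set` with sequences.
#' @param pwm a [pwm()] object.
#' @param score_threshold_pvalue scan threshold, see [scan_pwm()].
#' @return Named numeric vector over region ids.
#' @export
scaled_counts <- function(se, pwm, score_threshold_pvalue = 1e-4) {
  stopifnot(inherits(se, "se_region_set"))
  model <- .pwm_score_model(pwm)
  thr <- .pwm_threshold(model, score_threshold_pvalue)
  counts <- vapply(se$regions$id, function(id) {
    code <- .encode_dna(se$sequences[[id]])
    if (length(code) < ncol(model$ilo)) return(0L)
    rc <- rev(5L - code)
    sum(.scan_scores(code, model$ilo) >= thr) +
      sum(.scan_scores(rc, model$ilo) >= thr)
  }, integer(1))
  stats::setNames(counts * 1000 / (se$regions$end - se$regions$start),
                  se$regions$id)
}

#' Differential motif enrichment between two SE states
#'
#' Two-sided Mann-Whitney U test comparing length-scaled occurrence
#' counts in BK regions against DK regions; the signed magnitude is the
#' rank-biserial effect `2 * AUC(BK over DK) - 1` (positive =
#' BK-enriched). BH correction across TFs is applied by the caller (see
#' [motif_enrichment()]).
#'
#' @param counts_bk,counts_dk per-region scaled counts for the two states.
#' @return List with `u`, `p`, `signed_magnitude`.
#' @export
differential_enrichment <- function(counts_bk, counts_dk) {
  if (length(counts_bk) < 5 || length(counts_dk) < 5)
    warning("fewer than 5 regions in a state; test is weakly powered")
  if (all(c(counts_bk, counts_dk) == 0))
    return(list(u = length(counts_bk) * length(counts_dk) / 2, p = 1,
                signed_magnitude = 0))
  w <- suppressWarnings(mann_whitney_u(counts_bk, counts_dk, "two_sided"))
  auc <- w$u / (length(counts_bk) * length(counts_dk))
  list(u = w$u, p = w$p, signed_magnitude = 2 * auc - 1)
}

#' Per-TF differential motif enrichment across two SE states
#'
#' Scans every motif over all regions, compares scaled counts between the
#' BK- and DK-state regions, BH-corrects across motifs, and assigns each
#' motif a direction (`BK` when significantly BK-enriched, `DK` when
#' DK-enriched, `none` otherwise) and a rank-biserial signed magnitude.
#'
#' @param se an `se_region_set` whose `regions$state` is `"BK"`/`"DK"`
#'   (or `"A"`/`"B"`, mapped to BK/DK).
#' @param motifs named list of [pwm()] objects.
#' @param score_threshold_pvalue scan threshold, see [scan_pwm()].
#' @param alpha FDR threshold for calling a direction (default 0.05).
#' @return List with `table` (data.frame tf, u, p, q, direction,
#'   signed_magnitude) and `scaled_counts` (region x motif matrix kept for
#'   audit).
#' @export
motif_enrichment <- function(se, motifs, score_threshold_pvalue = 1e-4,
                             alpha = 0.05) {
  stopifnot(inherits(se, "se_region_set"))
  state <- se$regions$state
  state[state == "A"] <- "BK"
  state[state == "B"] <- "DK"
  if (!all(state %in% c("BK", "DK")))
    stop("regions must be labelled with two states", call. = FALSE)
  cnt <- vapply(motifs, function(m)
    scaled_counts(se, m, score_threshold_pvalue),
    numeric(nrow(se$regions)))
  rownames(cnt) <- se$regions$id
  res <- lapply(names(motifs), function(nm) {
    de <- differential_enrichment(cnt[state == "BK", nm],
                                  cnt[state == "DK", nm])
    data.frame(tf = nm, u = de$u, p = de$p,
               signed_magnitude = de$signed_magnitude,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- bh_fdr(tab$p)
  tab$direction <- ifelse(tab$q >= alpha, "none",
                          ifelse(tab$signed_magnitude > 0, "BK", "DK"))
  list(table = tab[, c("tf", "u", "p", "q", "direction",
                       "signed_magnitude")],
       scaled_counts = cnt)
}

#' Concordance of TF expression branch and SE motif enrichment
#'
#' One-sided Mann-Whitney U test that the TFs of the BK expression branch
#' have stochastically larger signed motif-enrichment magnitudes (towards
#' BK super-enhancers) than the TFs of the DK branch.
#'
#' @param branch named vector over TFs with values `"BK"`/`"DK"` (the two
#'   expression-trajectory branches).
#' @param enrichment the `table` from [motif_enrichment()] (columns tf,
#'   signed_magnitude, q).
#' @param restrict_to_significant keep only TFs with `q < alpha`
#'   (default TRUE).
#' @param alpha FDR threshold used by the restriction.
#' @return List with `p`, `u`, `n_bk`, `n_dk`.
#' @export
concordance_test <- function(branch, enrichment,
                             restrict_to_significant = TRUE, alpha = 0.05) {
  tab <- enrichment[enrichment$tf %in% names(branch), , drop = FALSE]
  if (restrict_to_significant) tab <- tab[tab$q < alpha, , drop = FALSE]
  mag <- stats::setNames(tab$signed_magnitude, tab$tf)
  bk <- mag[names(mag)[branch[names(mag)] == "BK"]]
  dk <- mag[names(mag)[branch[names(mag)] == "DK"]]
  for (nmv in list(c("BK", length(bk)), c("DK", length(dk))))
    if (as.integer(nmv[2]) < 2)
      stop("branch ", nmv[1], " has fewer than 2 TFs after restriction",
           call. = FALSE)
  w <- suppressWarnings(mann_whitney_u(bk, dk, "greater"))
  list(p = w$p, u = w$u, n_bk = length(bk), n_dk = length(dk))
}
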