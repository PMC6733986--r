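#' Simulation configuration for the synthetic keratinocyte data generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_stage_counts()], [simulate_bulk_celltype_matrix()],
#' [simulate_se_regions()] and [simulate_all()]. The defaults describe the
#' study conditions the pipeline is exercised under: ~3,000 cells and 1,500
#' genes across 8 discrete differentiation stages, 10 keratinocyte-specific
#' transcription factors (half peaking in the basal stages, half in the
#' differentiated stages) each driving a planted set of signed targets, a
#' 495-sample bulk cell-type atlas with a 3-sample target group, and two
#' super-enhancer region sets with a three-fold planted motif-density
#' contrast.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (must accommodate all planted roles).
#' @param n_stages number of discrete differentiation stages K (>= 6;
#'   stage K is an off-trajectory "channel"-like state, stage 4 mitotic-like).
#' @param n_tfs number of planted transcription factors (split basal/
#'   differentiated).
#' @param targets_per_tf planted regulatory targets per TF.
#' @param n_specific_genes additional planted cell-type-specific genes
#'   (upregulated in the bulk target group but not tied to a TF).
#' @param antioxidant_sizes integer vector of planted antioxidant class
#'   sizes; class 1 peaks basally, later classes peak progressively later.
#' @param library_size_mean mean UMIs per cell.
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param dropout_rate probability an observed count is zeroed
#'   independently of its value.
#' @param latent_noise_sd standard deviation (log2 units) of the per-cell
#'   noise on TF latent activities and target log-means.
#' @param n_bulk_samples,n_target_samples bulk atlas size and target-group
#'   size (`n_target_samples < n_bulk_samples`).
#' @param bulk_effect_lfc log2 elevation of planted specific genes in the
#'   bulk target group (0 plants nothing).
#' @param n_se_per_state super-enhancer regions per state.
#' @param se_length_range integer pair, region length range in bp.
#' @param se_base_density baseline planted motif density (occurrences/kb).
#' @param planted_density_ratio density multiplier in a motif's enriched
#'   state (state A for basal TFs, state B for differentiated TFs).
#' @param n_null_motifs motifs planted at the baseline density in both
#'   states (direction "none").
#' @param motif_length consensus length of generated motifs (bp).
#' @param gc_content GC fraction of the i.i.d. background sequence.
#' @param seed root seed; all outputs are reproducible in `(config, seed)`.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_cells = 3000, n_genes = 1500, n_stages = 8,
                              n_tfs = 10, targets_per_tf = 20,
                              n_specific_genes = 150,
                              antioxidant_sizes = c(20, 6, 6),
                              library_size_mean = 5000, nb_dispersion = 0.1,
                              dropout_rate = 0.3, latent_noise_sd = 0.8,
                              n_bulk_samples = 495, n_target_samples = 3,
                              bulk_effect_lfc = 4,
                              n_se_per_state = 50,
                              se_length_range = c(1000L, 3000L),
                              se_base_density = 0.5,
                              planted_density_ratio = 3,
                              n_null_motifs = 5, motif_length = 8,
                              gc_content = 0.5, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_stages = as.integer(n_stages), n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              n_specific_genes = as.integer(n_specific_genes),
              antioxidant_sizes = as.integer(antioxidant_sizes),
              library_size_mean = library_size_mean,
              nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
              latent_noise_sd = latent_noise_sd,
              n_bulk_samples = as.integer(n_bulk_samples),
              n_target_samples = as.integer(n_target_samples),
              bulk_effect_lfc = bulk_effect_lfc,
              n_se_per_state = as.integer(n_se_per_state),
              se_length_range = as.integer(se_length_range),
              se_base_density = se_base_density,
              planted_density_ratio = planted_density_ratio,
              n_null_motifs = as.integer(n_null_motifs),
              motif_length = as.integer(motif_length),
              gc_content = gc_content, seed = as.integer(seed))
  pos <- c("n_cells", "n_genes", "n_stages", "n_tfs", "targets_per_tf",
           "library_size_mean", "nb_dispersion", "n_bulk_samples",
           "n_target_samples", "n_se_per_state", "se_base_density",
           "planted_density_ratio", "motif_length")
  for (f in pos) if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
    stop("configuration error: '", f, "' must be positive", call. = FALSE)
  if (cfg$n_stages < 6)
    stop("configuration error: need at least 6 stages", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop("configuration error: dropout_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$latent_noise_sd < 0)
    stop("configuration error: latent_noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_target_samples >= cfg$n_bulk_samples)
    stop("configuration error: n_target_samples must be < n_bulk_samples",
         call. = FALSE)
  if (length(cfg$se_length_range) != 2L ||
      cfg$se_length_range[1] > cfg$se_length_range[2])
    stop("configuration error: se_length_range must be an increasing pair",
         call. = FALSE)
  if (cfg$se_length_range[1] < cfg$motif_length)
    stop("configuration error: minimum SE length must be >= motif length",
         call. = FALSE)
  n_planted <- cfg$n_tfs * (1L + cfg$targets_per_tf) + cfg$n_specific_genes +
    sum(cfg$antioxidant_sizes)
  if (n_planted > cfg$n_genes)
    stop("configuration error: planted roles (", n_planted,
         " genes) exceed n_genes", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

## Smooth unimodal log2-scale stage trajectory.
.bump <- function(stages, center, width, base, amp) {
  base + amp * exp(-(stages - center)^2 / (2 * width^2))
}

## Deterministically lay out gene identities, roles, log2 stage profiles and
## TF->target wiring from (config, seed). Shared by all simulate_* entry
## points so their planted truths agree.
.plant_roles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$n_stages
  n_bk <- ceiling(config$n_tfs / 2)
  n_dk <- config$n_tfs - n_bk
  tf_ids <- sprintf("TF%02d", seq_len(config$n_tfs))
  tf_class <- rep(c("bk_tf", "dk_tf"), c(n_bk, n_dk))
  target_ids <- as.vector(vapply(tf_ids, function(tf)
    sprintf("TG_%s_%02d", tf, seq_len(config$targets_per_tf)),
    character(config$targets_per_tf)))
  spec_ids <- if (config$n_specific_genes > 0)
    sprintf("SG%04d", seq_len(config$n_specific_genes)) else character()
  aox_ids <- if (sum(config$antioxidant_sizes) > 0)
    sprintf("AX%03d", seq_len(sum(config$antioxidant_sizes))) else character()
  n_bg <- config$n_genes - config$n_tfs -
    length(target_ids) - length(spec_ids) - length(aox_ids)
  bg_ids <- sprintf("BG%04d", seq_len(n_bg))
  gene_ids <- c(tf_ids, target_ids, spec_ids, aox_ids, bg_ids)

  role <- c(stats::setNames(tf_class, tf_ids),
            stats::setNames(rep("target", length(target_ids)), target_ids),
            stats::setNames(rep("specific_gene", length(spec_ids)), spec_ids),
            stats::setNames(rep(sprintf("antioxidant_class%d",
                                        rep(seq_along(config$antioxidant_sizes),
                                            config$antioxidant_sizes)),
                                length.out = length(aox_ids)), aox_ids),
            stats::setNames(rep("background", n_bg), bg_ids))

  tf_target_sign <- data.frame(
    tf = rep(tf_ids, each = config$targets_per_tf),
    gene = target_ids, stringsAsFactors = FALSE)

  stages <- seq_len(K)
  with_seed(substream_seed(config$seed, "roles"), {
    tf_target_sign$sign <- sample(c(1L, -1L), nrow(tf_target_sign),
                                  replace = TRUE, prob = c(0.7, 0.3))
    prof <- matrix(0, config$n_genes, K, dimnames = list(gene_ids, NULL))
    bk_center <- function(n) stats::runif(n, 1.5, 2.5)
    dk_center <- function(n) stats::runif(n, K - 2.5, K - 1.5)
    ## TF peaks are staggered across their state's stage window (regulator
    ## turnover is sequential): evenly spaced centers plus jitter
    bk_grid <- seq(1, 3.5, length.out = max(n_bk, 2))[seq_len(n_bk)]
    dk_grid <- seq(K - 3.5, K - 1, length.out = max(n_dk, 2))[seq_len(n_dk)]
    tf_centers <- c(bk_grid, dk_grid) + stats::runif(config$n_tfs, -0.2, 0.2)
    for (i in seq_along(tf_ids)) {
      prof[tf_ids[i], ] <- .bump(stages, tf_centers[i],
                                 stats::runif(1, 0.9, 1.4),
                                 stats::runif(1, 1, 2),
                                 stats::runif(1, 1.5, 2.2))
    }
    ## targets track their TF's centered latent activity with the planted
    ## sign; the per-cell coupling is applied at count time
    coupling <- 1.5
    target_base <- stats::runif(length(target_ids), 2, 4)
    for (r in seq_len(nrow(tf_target_sign))) {
      z <- prof[tf_target_sign$tf[r], ]
      prof[tf_target_sign$gene[r], ] <-
        target_base[r] + coupling * tf_target_sign$sign[r] * (z - mean(z))
    }
    ## a marker-like minority of ordinary genes carries sharp, strong
    ## stage-specific trajectories (as epidermal markers do); the rest are
    ## broader and weaker
    for (g in c(spec_ids, bg_ids)) {
      marker <- stats::runif(1) < 0.45
      prof[g, ] <- .bump(stages, stats::runif(1, 1, K),
                         if (marker) stats::runif(1, 0.6, 1.0) else
                           stats::runif(1, 0.9, 1.8),
                         stats::runif(1, 1, 3),
                         if (marker) stats::runif(1, 3.5, 5.5) else
                           stats::runif(1, 1, 2.5))
    }
    if (length(aox_ids)) {
      cls <- rep(seq_along(config$antioxidant_sizes), config$antioxidant_sizes)
      mid_center <- function(n) stats::runif(n, K / 2, K / 2 + 1)
      for (i in seq_along(aox_ids)) {
        ctr <- switch(cls[i], bk_center(1), mid_center(1), dk_center(1))
        if (is.null(ctr)) ctr <- dk_center(1)
        prof[aox_ids[i], ] <- .bump(stages, ctr, stats::runif(1, 0.9, 1.4),
                                    stats::runif(1, 1, 3),
                                    stats::runif(1, 1.5, 2.5))
      }
    }
  })

  bk_stages <- 1:3
  dk_stages <- (K - 3):(K - 1)
  truth <- list(
    gene_role = role,
    tf_target_sign = tf_target_sign,
    target_lfc = rowMeans(prof[, dk_stages, drop = FALSE]) -
      rowMeans(prof[, bk_stages, drop = FALSE]),
    log2_profile = prof,
    coupling = 2.5,
    bk_stages = bk_stages, dk_stages = dk_stages,
    bulk_upregulated = if (config$bulk_effect_lfc != 0)
      c(tf_ids, target_ids, spec_ids) else character(),
    tf_enrichment_direction = stats::setNames(
      c(ifelse(tf_class == "bk_tf", "A", "B"),
        rep("none", config$n_null_motifs)),
      c(tf_ids, sprintf("NULL%02d", seq_len(config$n_null_motifs)))))
  class(truth) <- "planted_truth"
  truth
}

#' Simulate a staged single-cell UMI count matrix with planted truth
#'
#' Cells are assigned evenly across the K stages; every gene carries a
#' smooth unimodal log2 stage trajectory (basal TFs peak in stages 1-3,
#' differentiated TFs in the late pre-channel stages). Each planted target's
#' per-cell log2 mean couples to its TF's noisy latent activity with the
#' planted sign, inducing per-cell TF-target correlation of that sign.
#' Counts are negative-binomial around per-cell library-size-scaled means
#' and then zeroed independently with probability `dropout_rate`.
#'
#' @param config a [simulation_config()].
#' @return A list with `counts` (genes x cells integer matrix) and `truth`
#'   (`planted_truth` with `cell_stage`, `cell_library_size`, roles,
#'   profiles and TF-target signs).
#' @export
simulate_stage_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- .plant_roles(config)
  K <- config$n_stages
  n <- config$n_cells
  cell_ids <- sprintf("cell%05d", seq_len(n))
  gene_ids <- rownames(truth$log2_profile)
  tf_rows <- names(truth$gene_role)[truth$gene_role %in% c("bk_tf", "dk_tf")]

  with_seed(substream_seed(config$seed, "cells"), {
    stage <- sample(rep_len(seq_len(K), n))
    ## mild lognormal library-size variation around the configured mean
    cv <- 0.3
    sdlog <- sqrt(log(1 + cv^2))
    libsize <- stats::rlnorm(n, log(config$library_size_mean) - sdlog^2 / 2,
                             sdlog)
  })

  prof <- truth$log2_profile
  x <- prof[, stage, drop = FALSE] # log2 propensity, genes x cells
  dimnames(x) <- list(gene_ids, cell_ids)

  with_seed(substream_seed(config$seed, "latent"), {
    if (config$latent_noise_sd > 0) {
      ## TF latent activities pick up per-cell noise; each target tracks its
      ## TF's realized latent (standardized by the TF's stage profile), plus
      ## its own noise
      eps_tf <- matrix(stats::rnorm(length(tf_rows) * n, 0,
                                    config$latent_noise_sd),
                       length(tf_rows), n, dimnames = list(tf_rows, NULL))
      x[tf_rows, ] <- x[tf_rows, ] + eps_tf
      tts <- truth$tf_target_sign
      for (tf in unique(tts$tf)) {
        mu_tf <- mean(prof[tf, ])
        dev <- x[tf, ] - mu_tf # realized centered latent, incl. cell noise
        rows <- tts[tts$tf == tf, ]
        base <- prof[rows$gene, , drop = FALSE][, stage, drop = FALSE] -
          truth$coupling * rows$sign %o% (prof[tf, stage] - mu_tf)
        x[rows$gene, ] <- base + truth$coupling * rows$sign %o% dev +
          matrix(stats::rnorm(nrow(rows) * n, 0,
                              config$latent_noise_sd / 2),
                 nrow(rows), n)
      }
    }
  })

  w <- 2^x
  rate <- sweep(w, 2L, libsize / colSums(w), `*`)
  with_seed(substream_seed(config$seed, "counts"), {
    counts <- if (config$nb_dispersion > 0)
      stats::rnbinom(length(rate), mu = rate, size = 1 / config$nb_dispersion)
    else stats::rpois(length(rate), rate)
    if (config$dropout_rate > 0)
      counts <- counts *
        (stats::runif(length(counts)) >= config$dropout_rate)
  })
  counts <- matrix(as.integer(counts), nrow(rate), ncol(rate),
                   dimnames = dimnames(rate))

  truth$cell_stage <- stats::setNames(stage, cell_ids)
  truth$cell_library_size <- stats::setNames(libsize, cell_ids)
  list(counts = counts, truth = truth)
}

#' Simulate a bulk cell-type expression atlas with a small target group
#'
#' Emulates a CAGE-style cell-type atlas: each gene's expression is spread
#' over one to three transcription-start-site features, samples carry
#' lognormal noise around gene baselines, and the planted
#' keratinocyte-specific genes (the TFs, their targets and the standalone
#' specific genes) are elevated by `bulk_effect_lfc` log2 units in the
#' `n_target_samples`-sample target group. `bulk_effect_lfc = 0` plants
#' nothing, giving a null screen.
#'
#' @param config a [simulation_config()].
#' @return A list with `bulk` (a `bulk_expression` object: `values`
#'   features x samples, `sample_group`, `feature_to_gene`) and `truth`.
#' @export
simulate_bulk_celltype_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- .plant_roles(config)
  gene_ids <- rownames(truth$log2_profile)
  n_s <- config$n_bulk_samples
  sample_ids <- sprintf("S%04d", seq_len(n_s))
  grp <- c(rep("keratinocyte", config$n_target_samples),
           sprintf("celltype%02d",
                   rep_len(seq_len(40), n_s - config$n_target_samples)))
  names(grp) <- sample_ids

  with_seed(substream_seed(config$seed, "bulk"), {
    base <- stats::rnorm(length(gene_ids), 3, 1)
    xg <- matrix(base, length(gene_ids), n_s) +
      matrix(stats::rnorm(length(gene_ids) * n_s, 0, 0.7),
             length(gene_ids), n_s)
    up <- truth$bulk_upregulated
    if (length(up))
      xg[match(up, gene_ids), grp == "keratinocyte"] <-
        xg[match(up, gene_ids), grp == "keratinocyte"] + config$bulk_effect_lfc
    v <- 2^xg
    ## split each gene across 1-3 CAGE-peak-like features
    n_peaks <- sample(1:3, length(gene_ids), replace = TRUE)
    f2g <- rep(gene_ids, n_peaks)
    wts <- stats::runif(length(f2g), 0.2, 1)
  })
  wts <- wts / ave(wts, f2g, FUN = sum)
  values <- v[match(f2g, gene_ids), , drop = FALSE] * wts
  feature_ids <- paste0("p", seq_along(f2g), "@", f2g)
  dimnames(values) <- list(feature_ids, sample_ids)
  bulk <- structure(list(values = values, sample_group = grp,
                         feature_to_gene = stats::setNames(f2g, feature_ids)),
                    class = "bulk_expression")
  list(bulk = bulk, truth = truth)
}

#' Generate synthetic TF motifs
#'
#' One position-frequency matrix per planted TF plus `n_null_motifs`
#' unenriched motifs; each has a random consensus of length `motif_length`
#' with 85% weight on the consensus base per position.
#'
#' @param config a [simulation_config()].
#' @return A named list of [pwm()] objects.
#' @export
simulate_motifs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- .plant_roles(config)
  nms <- names(truth$tf_enrichment_direction)
  with_seed(substream_seed(config$seed, "motifs"), {
    lapply(stats::setNames(nms, nms), function(nm) {
      cons <- sample(c("A", "C", "G", "T"), config$motif_length,
                     replace = TRUE)
      counts <- matrix(5, 4, config$motif_length,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
      counts[cbind(match(cons, rownames(counts)), seq_along(cons))] <- 85
      pwm(nm, counts)
    })
  })
}

#' Simulate two state-labelled super-enhancer region sets with sequences
#'
#' Regions get i.i.d. background sequence at the configured GC content;
#' motif consensus occurrences are planted as a Poisson process whose rate
#' per kb is `se_base_density`, multiplied by `planted_density_ratio` in a
#' motif's enriched state (state A for basal TFs, B for differentiated TFs,
#' neither for null motifs). Occurrences are placed without overlap on a
#' uniformly random strand; BED coordinates are 0-based half-open and each
#' region is its own contig, so sequence length equals `end - start`.
#'
#' @param config a [simulation_config()].
#' @param motifs named list of [pwm()] objects; defaults to
#'   [simulate_motifs()] under the same config.
#' @return A list with `se` (an `se_region_set`: `regions` data frame with
#'   chrom/start/end/id/state and `sequences`), `motifs`, and `truth` whose
#'   `se_occurrences` records every planted site (region, motif, 0-based
#'   start, strand).
#' @export
simulate_se_regions <- function(config, motifs = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(motifs)) motifs <- simulate_motifs(config)
  truth <- .plant_roles(config)
  L <- config$motif_length
  for (m in motifs) if (ncol(m$counts) > config$se_length_range[1])
    stop("configuration error: motif longer than minimum region length",
         call. = FALSE)
  dir <- truth$tf_enrichment_direction
  states <- c("A", "B")
  n_r <- config$n_se_per_state
  ids <- c(sprintf("seA_%03d", seq_len(n_r)), sprintf("seB_%03d", seq_len(n_r)))
  state <- rep(states, each = n_r)
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  with_seed(substream_seed(config$seed, "se"), {
    len_candidates <- seq(config$se_length_range[1],
                          config$se_length_range[2])
    lens <- len_candidates[sample.int(length(len_candidates), 2L * n_r,
                                      replace = TRUE)]
    seqs <- vapply(lens, function(l)
      paste(sample(names(base_probs), l, replace = TRUE, prob = base_probs),
            collapse = ""), character(1))
    occ <- vector("list", 2L * n_r)
    for (i in seq_along(ids)) {
      len <- lens[i]
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      free <- rep(TRUE, len)
      rec <- list()
      for (nm in names(motifs)) {
        rate <- config$se_base_density *
          if (dir[[nm]] == state[i]) config$planted_density_ratio else 1
        n_occ <- stats::rpois(1, rate * len / 1000)
        if (n_occ == 0) next
        cons <- .pwm_consensus(motifs[[nm]])
        for (k in seq_len(n_occ)) {
          cf <- c(0, cumsum(!free))
          np <- len - L + 1L
          ok <- which(cf[seq_len(np) + L] - cf[seq_len(np)] == 0)
          if (!length(ok)) break # region saturated; drop remaining sites
          p <- if (length(ok) == 1L) ok else sample(ok, 1L)
          strand <- sample(c("+", "-"), 1L)
          site <- if (strand == "+") cons else .revcomp(cons)
          chars[p:(p + L - 1)] <- strsplit(site, "", fixed = TRUE)[[1]]
          free[p:(p + L - 1)] <- FALSE
          rec[[length(rec) + 1L]] <-
            data.frame(region = ids[i], motif = nm, start = p - 1L,
                       strand = strand, stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      occ[[i]] <- if (length(rec)) do.call(rbind, rec) else NULL
    }
  })

  regions <- data.frame(chrom = ids, start = 0L, end = lens, id = ids,
                        state = state, stringsAsFactors = FALSE)
  se <- structure(list(regions = regions,
                       sequences = stats::setNames(seqs, ids)),
                  class = "se_region_set")
  truth$se_occurrences <- do.call(rbind, occ[!vapply(occ, is.null, logical(1))])
  list(se = se, motifs = motifs, truth = truth)
}

#' Simulate every pipeline input under one root seed
#'
#' @param config a [simulation_config()].
#' @return A list with `counts`, `bulk`, `se`, `motifs`, `config` and a
#'   merged `truth`.
#' @export
simulate_all <- function(config = simulation_config()) {
  sc <- simulate_stage_counts(config)
  bk <- simulate_bulk_celltype_matrix(config)
  se <- simulate_se_regions(config)
  truth <- sc$truth
  truth$se_occurrences <- se$truth$se_occurrences
  list(counts = sc$counts, bulk = bk$bulk, se = se$se, motifs = se$motifs,
       truth = truth, config = config)
}
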