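## Small simulation configuration used across test files; reduced sizes keep
## the suite fast while preserving every planted structure.
small_config <- function(seed = 7, ...) {
  args <- list(n_cells = 400, n_genes = 300, n_stages = 8, n_tfs = 6,
               targets_per_tf = 8, n_specific_genes = 30,
               antioxidant_sizes = c(8, 3, 3), n_bulk_samples = 60,
               n_target_samples = 3, n_se_per_state = 20, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

## cache one small simulation per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_all(small_config())
    cache
  }
})

## cache one small end-to-end pipeline run per session
pipeline_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(suppressMessages(
        run_pipeline(small_config(), verbose = FALSE)))
    cache
  }
})

## isotropic Gaussian blobs with known labels, cells in rows
make_blobs <- function(n_per = 50, k = 4, d = 5, sep = 10, sd = 1,
                       seed = 42) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d) * sep
    x <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[i, ],
            `+`)))
  })
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

## random count matrix fixture
random_counts <- function(genes = 50, cells = 20, seed = 11, lambda = 5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(genes * cells, lambda), genes, cells)
  })
  dimnames(m) <- list(sprintf("g%03d", seq_len(genes)),
                      sprintf("c%03d", seq_len(cells)))
  m
}

expect_same_partition <- function(a, b) {
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
}

## independent window-scoring oracle sharing only the stated conventions:
## integer-rounded log2 odds, both strands, N scores 0, threshold from the
## exact null score distribution
oracle_scan <- function(sequence, p, pval = 1e-4) {
  probs <- sweep(p$counts + p$pseudocount, 2,
                 colSums(p$counts) + 4 * p$pseudocount, `/`)
  lo <- round(log2(probs / 0.25) * 100)
  L <- ncol(lo)
  ## exhaustive null distribution over all 4^L words
  words <- expand.grid(rep(list(1:4), L))
  scores <- apply(words, 1, function(w) sum(lo[cbind(w, seq_len(L))]))
  tail_p <- vapply(sort(unique(scores)), function(s) mean(scores >= s),
                   numeric(1))
  thr <- sort(unique(scores))[which(tail_p <= pval)[1]]
  if (is.na(thr)) thr <- max(scores) + 1
  count_strand <- function(chars) {
    n <- length(chars)
    if (n < L) return(0L)
    hits <- 0L
    for (i in seq_len(n - L + 1)) {
      sc <- 0
      for (l in seq_len(L)) {
        b <- match(chars[i + l - 1], c("A", "C", "G", "T"))
        sc <- sc + if (is.na(b)) 0 else lo[b, l]
      }
      if (sc >= thr) hits <- hits + 1L
    }
    hits
  }
  fw <- strsplit(toupper(sequence), "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[fw])
  count_strand(fw) + count_strand(rc)
}

test_pwm <- function(consensus, weight = 85) {
  counts <- matrix(5, 4, nchar(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], rownames(counts))
  counts[cbind(idx, seq_along(idx))] <- weight
  pwm("test", counts)
}

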