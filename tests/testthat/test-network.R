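make_expr <- function(genes, cells, seed = 70) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(genes * cells), genes, cells)
  })
  dimnames(m) <- list(sprintf("g%03d", seq_len(genes)),
                      sprintf("c%03d", seq_len(cells)))
  m
}

test_that("signed similarity matches its closed form and brute force", {
  x <- make_expr(28, 40)
  tfs <- rownames(x)[1:8]
  genes <- rownames(x)[9:28]
  sim <- signed_similarity(x, tfs, genes, beta = 6)
  ## brute force elementwise
  for (i in c(1, 5)) for (j in c(2, 17)) {
    a <- x[tfs[i], ]; b <- x[genes[j], ]
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(sim$s[tfs[i], genes[j]], sign(r) * abs(r)^6,
                 tolerance = 1e-12)
  }
  expect_true(all(abs(sim$s) <= 1))
  ## beta = 1 is the raw correlation matrix, exactly
  sim1 <- signed_similarity(x, tfs, genes, beta = 1)
  expect_equal(sim1$s, stats::cor(t(x[tfs, ]), t(x[genes, ])),
               tolerance = 1e-15)
  ## perfect correlation is a fixed point for any beta
  y <- rbind(tf = 1:20, tgt = 2 * (1:20) + 5)
  colnames(y) <- sprintf("c%02d", 1:20)
  expect_equal(signed_similarity(y, "tf", "tgt",
                                 beta = 7)$s[1, 1], 1)
  ## closed form: r = -0.5, beta = 2 -> -0.25
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  ## construct b with correlation exactly -0.5 to a
  za <- (a - mean(a)) / sqrt(sum((a - mean(a))^2))
  zperp <- resid(lm(rnorm(10) ~ za))
  zperp <- zperp / sqrt(sum(zperp^2))
  b <- -0.5 * za + sqrt(1 - 0.25) * zperp
  m2 <- rbind(tf = a, tgt = b)
  colnames(m2) <- sprintf("c%02d", 1:10)
  expect_equal(signed_similarity(m2, "tf", "tgt", beta = 2)$s[1, 1],
               -0.25, tolerance = 1e-10)
  bad <- x; bad[3, ] <- 1
  expect_error(signed_similarity(bad, tfs, genes), "zero-variance")
  expect_error(signed_similarity(x, tfs, genes, cells = colnames(x)[1:5]),
               "at least 10")
})

test_that("gene-module clustering groups duplicated and splits negated profiles", {
  s <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("TF%d", 1:5), sprintf("g%02d", 1:12)))
  s[, "g02"] <- s[, "g01"]
  s[, "g03"] <- -s[, "g01"]
  sim <- structure(list(s = s, beta = 6, cells = NULL),
                   class = "similarity_matrix")
  gm <- cluster_gene_modules(sim, 6)
  expect_equal(gm[["g01"]], gm[["g02"]])
  gm2 <- cluster_gene_modules(sim, 2)
  expect_false(gm2[["g01"]] == gm2[["g03"]])
  ## constant profile falls back to Euclidean assignment with a flag
  s2 <- s; s2[, "g04"] <- 0.5
  simc <- structure(list(s = s2, beta = 6, cells = NULL),
                    class = "similarity_matrix")
  gmc <- cluster_gene_modules(simc, 4)
  expect_true("g04" %in% attr(gmc, "fallback"))
  expect_true(!is.na(gmc[["g04"]]))
})

test_that("gene modules recover a planted similarity block structure", {
  withr::with_seed(71, {
    tfs <- sprintf("TF%d", 1:5)
    genes <- as.vector(sapply(1:5, function(i) sprintf("t%d_%02d", i, 1:20)))
    truth_mod <- rep(1:5, each = 20)
    s <- matrix(rnorm(5 * 100, sd = 0.03), 5, 100,
                dimnames = list(tfs, genes))
    for (i in 1:5) s[i, truth_mod == i] <- 0.5 + rnorm(20, sd = 0.05)
  })
  sim <- structure(list(s = s, beta = 6, cells = NULL),
                   class = "similarity_matrix")
  gm <- cluster_gene_modules(sim, 5)
  expect_gte(mclust::adjustedRandIndex(gm[genes], truth_mod), 0.9)
})

test_that("module edge calling equals a brute-force double loop", {
  withr::with_seed(72, {
    s <- matrix(runif(6 * 30, -1, 1), 6, 30,
                dimnames = list(sprintf("TF%d", 1:6), sprintf("g%02d", 1:30)))
    tfm <- stats::setNames(sample(1:3, 6, TRUE), rownames(s))
    gm <- stats::setNames(sample(1:5, 30, TRUE), colnames(s))
  })
  sim <- structure(list(s = s, beta = 6, cells = NULL),
                   class = "similarity_matrix")
  edges <- module_edges(sim, tfm, gm, threshold = 0.1)
  ap <- attr(edges, "all_pairs")
  for (a in unique(tfm)) for (b in unique(gm)) {
    acc <- 0; nn <- 0
    for (i in names(tfm)[tfm == a]) for (j in names(gm)[gm == b]) {
      acc <- acc + s[i, j]; nn <- nn + 1
    }
    expect_equal(ap$mean_s[ap$tf_module == a & ap$gene_module == b],
                 acc / nn, tolerance = 1e-12)
  }
  expect_true(all(edges$strength > 0.1))
  expect_true(all((edges$mean_s > 0) == (edges$sign == "activation")))

  ## single-pair module with s = 0.8 and threshold 0.5: one activation edge
  s1 <- matrix(0.8, 1, 1, dimnames = list("TF1", "g1"))
  sim1 <- structure(list(s = s1, beta = 6, cells = NULL),
                    class = "similarity_matrix")
  e1 <- module_edges(sim1, c(TF1 = 1L), c(g1 = 1L), 0.5)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$strength, 0.8)
  expect_equal(e1$sign, "activation")

  ## planted block matrix: exactly the planted edges at threshold 0.3
  sb <- matrix(0, 3, 9, dimnames = list(paste0("TF", 1:3), paste0("g", 1:9)))
  gmb <- stats::setNames(rep(1:3, each = 3), colnames(sb))
  for (i in 1:3) sb[i, gmb == i] <- 0.6
  simb <- structure(list(s = sb, beta = 6, cells = NULL),
                    class = "similarity_matrix")
  eb <- module_edges(simb, stats::setNames(1:3, rownames(sb)), gmb, 0.3)
  expect_equal(nrow(eb), 3L)
  expect_true(all(eb$tf_module == eb$gene_module))
})

test_that("permutation-null threshold behaves at its limits", {
  zeros <- structure(list(s = matrix(0, 4, 20,
                                     dimnames = list(paste0("TF", 1:4),
                                                     paste0("g", 1:20))),
                          beta = 6, cells = NULL),
                     class = "similarity_matrix")
  tfm <- stats::setNames(rep(1:2, 2), paste0("TF", 1:4))
  gm <- stats::setNames(rep(1:4, 5), paste0("g", 1:20))
  expect_equal(edge_threshold_from_null(zeros, tfm, gm, 100, 0.95, 1), 0)
  expect_error(edge_threshold_from_null(zeros, tfm, gm, 10, 0.95, 1),
               ">= 100")
  withr::with_seed(73, {
    s <- matrix(runif(4 * 20, -1, 1), 4, 20,
                dimnames = list(paste0("TF", 1:4), paste0("g", 1:20)))
  })
  sim <- structure(list(s = s, beta = 6, cells = NULL),
                   class = "similarity_matrix")
  thr_max <- edge_threshold_from_null(sim, tfm, gm, 100, 1.0, 1)
  thr_95 <- edge_threshold_from_null(sim, tfm, gm, 100, 0.95, 1)
  expect_gte(thr_max, thr_95)
  ## pooled null distribution is stable across seeds at large n
  t_a <- edge_threshold_from_null(sim, tfm, gm, 500, 0.95, 1)
  t_b <- edge_threshold_from_null(sim, tfm, gm, 500, 0.95, 2)
  expect_lt(abs(t_a - t_b) / max(t_a, 1e-9), 0.1)
})

test_that("bimodal threshold splits a gapped block distribution", {
  ## construct block means with a clear gap: own blocks ~0.5, rest ~0.05
  s <- matrix(0.02, 4, 40, dimnames = list(paste0("TF", 1:4),
                                           sprintf("g%02d", 1:40)))
  gm <- stats::setNames(rep(1:8, each = 5), colnames(s))
  for (i in 1:4) s[i, gm == i] <- 0.5
  sim <- structure(list(s = s, beta = 6, cells = NULL),
                   class = "similarity_matrix")
  tfm <- stats::setNames(1:4, rownames(s))
  thr <- edge_threshold_bimodal(sim, tfm, gm)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.5)
  edges <- module_edges(sim, tfm, gm, thr)
  expect_equal(nrow(edges), 4L)
})

test_that("state networks respect the DE-based gene exclusion", {
  res <- pipeline_small()
  net <- res$network_bk
  de <- res$de
  dk_specific <- de$gene[de$state_specific == "DK"]
  expect_length(intersect(names(net$gene_modules), dk_specific), 0)
  ## pre-filtering the gene sets by hand yields the identical network
  gs2 <- res$gene_sets
  gs2$keratinocyte_genes <- setdiff(gs2$keratinocyte_genes, dk_specific)
  cells <- names(res$retained)[res$retained]
  net2 <- build_state_network("BK", res$expr, res$stages$labels[cells],
                              res$enrichment$table, de, gs2,
                              seed = substream_seed(
                                res$manifest$root_seed, "netBK"))
  expect_identical(net$edges, net2$edges)
  expect_identical(net$gene_modules, net2$gene_modules)
  ## stage windows: BK uses stages 1-4, DK uses 4..K-1
  expect_identical(net$stage_range, 1:4)
  expect_identical(res$network_dk$stage_range, 4:7)
})
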