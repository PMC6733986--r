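test_that("Mann-Whitney U matches exact enumeration on the textbook case", {
  w <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(w$u, 0)
  expect_equal(w$p, 2 / 6)
  expect_true(w$exact)
  ## direction: y shifted above x
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), "less")$p, 1 / 6)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), "greater")$p, 1)
})

test_that("identical samples give p = 1 with a warning", {
  expect_warning(w <- mann_whitney_u(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(w$p, 1)
  ## identical multisets (but not constant) are symmetric: p = 1 with ties
  w2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w2$p, 1)
})

test_that("small-sample p-values agree with exact enumeration (property)", {
  withr::with_seed(33, {
    for (i in 1:40) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      x <- round(runif(n), 6); y <- round(runif(m), 6) # ties a.s. absent
      for (alt in c("two_sided", "greater", "less")) {
        mine <- mann_whitney_u(x, y, alt)
        ref <- stats::wilcox.test(x, y, alternative = sub("_", ".", alt),
                                  exact = TRUE)
        expect_true(mine$exact)
        expect_equal(mine$u, unname(ref$statistic))
        expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("large-sample p-values match the tie-corrected normal reference", {
  withr::with_seed(34, {
    for (i in 1:20) {
      x <- sample(1:8, 25, replace = TRUE) # plenty of ties
      y <- sample(2:9, 30, replace = TRUE)
      for (alt in c("two_sided", "greater", "less")) {
        mine <- mann_whitney_u(x, y, alt)
        ref <- suppressWarnings(
          stats::wilcox.test(x, y, alternative = sub("_", ".", alt),
                             exact = FALSE, correct = TRUE))
        expect_false(mine$exact)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("BH step-up matches hand computation and the reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(35, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
  expect_error(bh_fdr(c(0.1, NA)), "NA")
})

test_that("feature aggregation sums peaks per gene", {
  v <- matrix(c(3, 5, 2, 1, 7, 4), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  bulk <- structure(list(values = v,
                         sample_group = c(s1 = "a", s2 = "b"),
                         feature_to_gene = c(p1 = "g1", p2 = "g1",
                                             p3 = "g2")),
                    class = "bulk_expression")
  agg <- aggregate_features_to_genes(bulk)
  expect_equal(agg$values["g1", ], c(s1 = 8, s2 = 8))
  expect_equal(agg$values["g2", ], c(s1 = 2, s2 = 4))

  ## identity map leaves the matrix unchanged (up to row order)
  bulk$feature_to_gene <- c(p1 = "p1", p2 = "p2", p3 = "p3")
  expect_equal(aggregate_features_to_genes(bulk)$values[rownames(v), ], v)

  ## random fixture against a brute-force group-by sum
  withr::with_seed(36, {
    v2 <- matrix(rexp(100 * 4), 100, 4,
                 dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:4)))
    map <- stats::setNames(sample(sprintf("g%02d", 1:25), 100, TRUE),
                           rownames(v2))
  })
  b2 <- structure(list(values = v2, sample_group = NULL,
                       feature_to_gene = map), class = "bulk_expression")
  agg2 <- aggregate_features_to_genes(b2)
  for (g in unique(map))
    expect_equal(agg2$values[g, ],
                 colSums(v2[names(map)[map == g], , drop = FALSE]),
                 tolerance = 1e-12)
})

test_that("the specificity screen respects the direction rule", {
  withr::with_seed(37, {
    v <- matrix(rnorm(50 * 30, 10), 50, 30,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("s%02d", 1:30)))
  })
  v["g01", 1:3] <- v["g01", 1:3] + 50     # up in target
  v["g02", 4:30] <- v["g02", 4:30] + 50   # up in the rest
  grp <- stats::setNames(c(rep("keratinocyte", 3), rep("other", 27)),
                         colnames(v))
  bulk <- structure(list(values = v, sample_group = grp,
                         feature_to_gene = stats::setNames(rownames(v),
                                                           rownames(v))),
                    class = "bulk_expression")
  res <- celltype_specific_screen(bulk, "keratinocyte", alpha = 0.4)
  expect_true(res$selected[res$gene == "g01"])
  expect_false(res$selected[res$gene == "g02"]) # never, regardless of p
  expect_equal(res$direction[res$gene == "g02"], "down_in_target")
  const <- bulk
  const$values["g03", ] <- 7
  expect_equal(celltype_specific_screen(const,
                                        "keratinocyte")$p[res$gene == "g03"],
               1)
  expect_error(celltype_specific_screen(bulk, "missing"), "at least 2")
})

test_that("sample exclusion removes samples before the screen", {
  sim <- small_sim()
  g <- aggregate_features_to_genes(sim$bulk)
  res_all <- celltype_specific_screen(g, "keratinocyte")
  drop <- names(g$sample_group)[g$sample_group != "keratinocyte"][1:5]
  res_ex <- celltype_specific_screen(g, "keratinocyte",
                                     exclude_samples = drop)
  expect_false(identical(res_all$u, res_ex$u))
})

test_that("UMI filters apply their boundary rules exactly", {
  counts <- matrix(0L, 3, 1000,
                   dimnames = list(c("zero", "edge", "below"),
                                   sprintf("c%04d", 1:1000)))
  counts["edge", 1:10] <- 1L    # 1 UMI in exactly 1% of 1000 cells
  counts["below", 1:9] <- 5L
  kept <- scrna_expression_filter(counts, min_umis = 1,
                                  min_cell_fraction = 0.01)
  expect_identical(kept, "edge")

  d <- matrix(0L, 2, 30, dimnames = list(c("in20", "in19"),
                                         sprintf("c%02d", 1:30)))
  d["in20", 1:20] <- 3L
  d["in19", 1:19] <- 3L
  expect_identical(de_expressed_filter(d, 3, 20), "in20")

  ## brute force on a random fixture
  rc <- random_counts(40, 200, seed = 38, lambda = 0.3)
  kept2 <- scrna_expression_filter(rc, 2, 0.05)
  oracle <- rownames(rc)[sapply(seq_len(nrow(rc)), function(i)
    sum(rc[i, ] >= 2) >= ceiling(0.05 * 200))]
  expect_identical(kept2, oracle)
})

test_that("gene-set assembly obeys the declared set identities", {
  tf_ann <- sprintf("TF%02d", 1:20)
  hits <- c(sprintf("TF%02d", 1:8), sprintf("G%02d", 1:40))
  curated <- c(sprintf("TF%02d", 5:12), "TFX1")
  gs <- assemble_gene_sets(hits, tf_ann, curated,
                           manual_additions = c("TF19", "TF20"))
  expect_setequal(gs$fantom_tfs, c(sprintf("TF%02d", 1:8), "TF19", "TF20"))
  expect_setequal(gs$fantom_genes, sprintf("G%02d", 1:40))
  expect_setequal(gs$keratinocyte_tfs, union(gs$fantom_tfs, curated))
  expect_setequal(gs$candidate_tfs, setdiff(gs$fantom_tfs, curated))
  expect_length(intersect(gs$candidate_tfs, gs$curated_tfs), 0)
  expect_setequal(gs$keratinocyte_genes,
                  union(gs$keratinocyte_tfs, gs$fantom_genes))
  ## empty curated set: candidates equal the screen TFs
  gs2 <- assemble_gene_sets(hits, tf_ann, character())
  expect_setequal(gs2$candidate_tfs, gs2$fantom_tfs)
  expect_warning(assemble_gene_sets(hits, tf_ann, character(),
                                    manual_additions = "NOPE",
                                    universe = hits), "absent")
})

test_that("moderated DE reduces to the ordinary t-test at zero prior df", {
  withr::with_seed(40, {
    x <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%02d", 1:20)))
  })
  state <- stats::setNames(rep(c("BK", "DK"), each = 10), colnames(x))
  de <- moderated_de(x, state, trend = FALSE, prior_df = 0)
  for (i in c(1, 50, 100)) {
    tt <- stats::t.test(x[i, state == "DK"], x[i, state == "BK"],
                        var.equal = TRUE)
    expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("posterior variances satisfy the shrinkage sandwich", {
  withr::with_seed(41, {
    x <- matrix(rnorm(300 * 30, sd = rep(runif(300, 0.5, 2), 30)), 300, 30,
                dimnames = list(sprintf("g%03d", 1:300),
                                sprintf("c%02d", 1:30)))
  })
  state <- stats::setNames(rep(c("BK", "DK"), each = 15), colnames(x))
  de <- moderated_de(x, state, trend = FALSE)
  d0 <- attr(de, "d0")
  s02 <- attr(de, "s02")
  expect_true(is.finite(d0) && d0 > 0)
  n1 <- 15; n2 <- 15; df <- n1 + n2 - 2
  s2 <- (13 * apply(x[, 1:15], 1, var) + 13 * apply(x[, 16:30], 1, var)) / df
  st2 <- (d0 * s02 + df * s2) / (d0 + df)
  lo <- pmin(s2, s02); hi <- pmax(s2, s02)
  expect_true(all(st2 >= lo - 1e-12 & st2 <= hi + 1e-12))
})

test_that("moderated DE agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  withr::with_seed(42, {
    x <- matrix(rnorm(400 * 24, sd = rep(runif(400, 0.5, 1.5), 24)),
                400, 24, dimnames = list(sprintf("g%03d", 1:400),
                                         sprintf("c%02d", 1:24)))
    x[1:40, 13:24] <- x[1:40, 13:24] + 1
  })
  state <- stats::setNames(rep(c("BK", "DK"), each = 12), colnames(x))
  de <- moderated_de(x, state, trend = FALSE)
  design <- cbind(1, state == "DK")
  fit <- limma::eBayes(limma::lmFit(x, design), trend = FALSE)
  expect_equal(de$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 0.02)
  ## state calls respect the fold-change and FDR rule
  expect_true(all(abs(de$logfc[de$state_specific != "none"]) > 0.25))
  expect_true(all(de$q_value[de$state_specific != "none"] < 0.05))
})

test_that("moderated DE recovers planted fold changes with small bias", {
  withr::with_seed(43, {
    lfc <- c(rep(2, 30), rep(-2, 30), rep(0, 140))
    x <- matrix(rnorm(200 * 300), 200, 300) +
      cbind(matrix(0, 200, 150), matrix(lfc, 200, 150))
  })
  dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:300))
  state <- stats::setNames(rep(c("BK", "DK"), each = 150), colnames(x))
  de <- moderated_de(x, state, trend = FALSE)
  expect_lt(max(abs(de$logfc - lfc)), 0.5)
  expect_lt(abs(mean(de$logfc - lfc)), 0.05)
  expect_error(moderated_de(x, state[1:2]), "every cell")
})
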