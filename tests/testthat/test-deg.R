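toy_counts <- function(mat, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(mat)))
  matrix(as.integer(mat), nrow(mat), ncol(mat),
         dimnames = list(genes, samples))
}

test_that("prefilter applies the sample-total and gene-mean thresholds", {
  set.seed(1)
  base <- matrix(rpois(30, 100000), 10, 3)
  m <- toy_counts(round(sweep(base, 2, c(250000, 150000, 300000) /
                                colSums(base), "*")))
  meta <- data.frame(sample_id = colnames(m), compound_id = "c",
                     concentration = c(0, 0, 1e-6), replicate = 1:3)
  pf <- prefilter(m, meta)
  expect_false("s2" %in% colnames(pf$counts))
  expect_true(all(c("s1", "s3") %in% colnames(pf$counts)))
  expect_true("s2" %in% pf$report$id)

  # gene with mean 1.33 over three surviving samples is removed
  m2 <- toy_counts(rbind(c(1, 1, 2), matrix(100000L, 3, 3)))
  meta2 <- data.frame(sample_id = colnames(m2), compound_id = "c",
                      concentration = 0, replicate = 1:3)
  pf2 <- prefilter(m2, meta2)
  expect_false("g1" %in% rownames(pf2$counts))
  # nothing to remove leaves the matrix untouched
  m3 <- toy_counts(matrix(100000L, 3, 3))
  pf3 <- prefilter(m3, meta2)
  expect_identical(pf3$counts, m3)
  expect_equal(nrow(pf3$report), 0)
  expect_error(prefilter(toy_counts(matrix(1L, 2, 2)),
                         data.frame(sample_id = c("s1", "s2"))),
               "AllSamplesRemoved")
})

test_that("size factors implement median-of-ratios", {
  # identical columns: all factors 1
  m <- toy_counts(matrix(rep(c(10L, 50L, 200L), 3), 3, 3))
  expect_equal(unname(size_factors(m)), rep(1, 3))

  # doubling a column doubles its factor
  m2 <- toy_counts(cbind(c(10L, 100L, 4L), c(20L, 200L, 8L)))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # worked 3-gene example: factors proportional to (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  expect_error(size_factors(toy_counts(rbind(c(0L, 5L), c(3L, 0L)))),
               "NoReferenceGenes")
})

test_that("size factors agree with the reference implementation", {
  cfg <- count_sim_config(n_genes = 300, de_fraction = 0.05, seed = 21)
  sim <- generate_counts(cfg)
  ours <- size_factors(sim$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("normalization is idempotent", {
  cfg <- count_sim_config(n_genes = 300, de_fraction = 0, seed = 4)
  sim <- generate_counts(cfg)
  sf <- size_factors(sim$counts)
  norm <- sweep(sim$counts, 2, sf, "/")
  # re-deriving factors from the normalized matrix leaves no per-sample
  # structure: all second-round factors collapse to a single constant (the
  # geometric mean of the first-round factors, since factors are by design
  # not rescaled), so normalization is idempotent up to that scalar
  ref <- rowSums(norm > 0) == ncol(norm)
  loggeo <- rowMeans(log(norm[ref, ]))
  sf2 <- apply(log(norm[ref, ]), 2, function(x)
    exp(median(x - loggeo)))
  expect_equal(unname(sf2), rep(exp(mean(log(sf))), ncol(norm)),
               tolerance = 1e-10)
  expect_lt(max(sf2) / min(sf2) - 1, 1e-10)
})

test_that("Benjamini-Hochberg matches the brute-force step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(1, 1, 1)), c(1, 1, 1))
  set.seed(5)
  for (n in c(1, 2, 5, 12)) {
    p <- round(runif(n), 3)
    expect_equal(benjamini_hochberg(p), bh_brute_force(p))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical treated and control groups give null results", {
  cfg <- count_sim_config(n_genes = 150, de_fraction = 0, seed = 2)
  sim <- generate_counts(cfg)
  counts <- sim$counts
  ctrl <- sim$meta$concentration == 0
  # copy the control columns in as the 'treated' group
  counts[, sim$meta$concentration == max(cfg$concentrations)] <-
    counts[, ctrl]
  tab <- test_differential_expression(counts, sim$meta, "compound",
                                      max(cfg$concentrations))
  expect_true(all(tab$log2fc == 0))
  expect_true(all(tab$p == 1))
  expect_true(all(tab$padj >= tab$p))
})

test_that("a strongly planted gene is detected with an accurate log2FC", {
  cfg <- count_sim_config(n_genes = 1500, de_fraction = 0.01,
                          max_log2fc = 2, dispersion = 0.05, seed = 8,
                          de_ec50 = 13e-6 / 64, baseline_meanlog = 6,
                          baseline_sdlog = 0.3)
  sim <- generate_counts(cfg)
  top <- max(cfg$concentrations)
  tt <- sim$truth[sim$truth$concentration == top, ]
  # pick a planted gene with baseline mean near 500
  cand <- tt$gene_id[abs(tt$true_log2fc) > 1.9]
  g <- cand[which.min(abs(sim$baseline[cand] - 500))]
  tab <- test_differential_expression(sim$counts, sim$meta, "compound", top)
  row <- tab[tab$gene_id == g, ]
  expect_lt(abs(abs(row$log2fc) - 2), 0.5)
  expect_lt(row$padj, 0.05)
})

test_that("permuting labels on null data keeps p values uniform", {
  cfg <- count_sim_config(n_genes = 2000, de_fraction = 0,
                          dispersion = 0.05, seed = 31)
  sim <- generate_counts(cfg)
  meta <- sim$meta
  top <- max(cfg$concentrations)
  # permute treated/control labels among the six involved samples
  set.seed(31)
  involved <- which(meta$concentration %in% c(0, top))
  shuffled <- sample(meta$concentration[involved])
  meta$concentration[involved] <- shuffled
  tab <- test_differential_expression(sim$counts, meta, "compound", top)
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DEG recall increases with the planted effect size", {
  recall <- vapply(c(0.5, 1, 2), function(fc) {
    cfg <- count_sim_config(n_genes = 1000, de_fraction = 0.04,
                            max_log2fc = fc, dispersion = 0.05, seed = 3,
                            de_ec50 = 13e-6 / 16, baseline_meanlog = 5.5,
                            baseline_sdlog = 1)
    sim <- generate_counts(cfg)
    top <- max(cfg$concentrations)
    tt <- sim$truth[sim$truth$concentration == top, ]
    de_true <- tt$gene_id[abs(tt$true_log2fc) > 0]
    pf <- prefilter(sim$counts, sim$meta, min_sample_total = 0)
    deg <- call_degs(test_differential_expression(pf$counts, pf$meta,
                                                  "compound", top))
    mean(de_true %in% deg$genes)
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], recall[1])
})

test_that("DEG calling applies the fold-change and FDR rules", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    mean_control = 100, mean_treated = 100,
                    log2fc = c(0.7, 0.30, -0.8, 1.2),
                    p = c(0.001, 0.001, 0.2, 0.03),
                    padj = c(0.04, 0.04, 0.4, 0.051))
  # padj 0.04 with 0.7 log2fc is a DEG; 0.30 fails the 1.5-fold rule
  res <- call_degs(tab)
  expect_equal(res$genes, "a")
  expect_equal(res$n_up, 1)
  expect_equal(res$n_deg, 1)
  # the FDR-only variant admits b as well
  res2 <- call_degs(tab, rule = "fdr_only")
  expect_setequal(res2$genes, c("a", "b"))
  # empty table
  expect_equal(call_degs(tab[0, ])$n_deg, 0)
})

test_that("insufficient replication is rejected", {
  cfg <- count_sim_config(n_genes = 50, n_replicates = 1,
                          de_fraction = 0, seed = 1)
  sim <- generate_counts(cfg)
  expect_error(test_differential_expression(sim$counts, sim$meta,
                                            "compound",
                                            max(cfg$concentrations)),
               "InsufficientReplicates")
})
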