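test_that("symmetric equal correlations give equal unit weights", {
  r <- matrix(0.5, 3, 3)
  diag(r) <- 1
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  w <- weight_vector(r)
  expect_equal(unname(w$w_norm), c(1, 1, 1), tolerance = 1e-12)
})

test_that("weights agree with a direct dense eigensolver on random input", {
  # includes the hand-specified 3x3 case plus random sizes 3-20
  set.seed(99)
  sizes <- sample(3:20, 8, replace = TRUE)
  cases <- c(list(matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3, 3)),
             lapply(1:8, function(k) random_corr(sizes[k], seed = 100 + k)))
  for (r in cases) {
    w <- weight_vector(r)
    A <- abs(r)
    diag(A) <- 0
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    oracle <- length(v) * v / sum(v)
    expect_equal(unname(w$w_norm), oracle, tolerance = 1e-10)
    # fixed-point residual of the eigen equation
    resid <- max(abs(w$eigenvalue * w$w_raw - A %*% w$w_raw))
    expect_lt(resid, 1e-8)
    expect_equal(mean(w$w_norm), 1, tolerance = 1e-9)
    expect_true(all(w$w_norm >= 0))
  }
})

test_that("degenerate and undersized weight inputs are refused", {
  r0 <- diag(3)
  dimnames(r0) <- list(letters[1:3], letters[1:3])
  expect_error(weight_vector(r0), "degenerate")
  expect_error(weight_vector(matrix(1, 2, 2)), "symmetric|fewer")
  rna <- random_corr(4, seed = 1)
  rna[1, 2] <- rna[2, 1] <- NA
  # removing g01 and g02 would leave 2 genes
  rna[3, 4] <- rna[4, 3] <- NA
  expect_error(weight_vector(rna), "fewer than 3")
})

test_that("genes with undefined correlations are dropped before weighting", {
  r <- random_corr(6, seed = 2)
  r[5, ] <- r[, 5] <- NA
  w <- weight_vector(r)
  expect_identical(w$genes, rownames(r)[-5])
  expect_length(w$w_norm, 5)
})

test_that("L1 statistic arithmetic and its invariances hold", {
  expect_equal(gsnca_statistic(wv_stub(c(1, 1, 1)),
                               wv_stub(c(1.2, 0.9, 0.9))), 0.4)
  expect_equal(gsnca_statistic(wv_stub(c(1, 1, 1)), wv_stub(c(1, 1, 1))), 0)
  # invariant under a common gene reordering
  w1 <- c(1.3, 0.8, 0.9)
  w2 <- c(0.7, 1.2, 1.1)
  ord <- c(3, 1, 2)
  expect_equal(gsnca_statistic(wv_stub(w1), wv_stub(w2)),
               gsnca_statistic(wv_stub(w1[ord], genes = sprintf("h%d", 1:3)),
                               wv_stub(w2[ord], genes = sprintf("h%d", 1:3))))
  expect_error(gsnca_statistic(wv_stub(c(1, 1, 1)),
                               wv_stub(c(1, 1, 1),
                                       genes = c("x", "y", "z"))),
               "different gene lists")
})

test_that("dispersion statistic matches its closed form and bounds", {
  r1 <- random_corr(5, seed = 3)
  expect_equal(gsca_statistic(r1, r1), 0)
  d <- r1 - random_corr(5, seed = 4)
  expect_equal(gsca_statistic(r1, random_corr(5, seed = 4)),
               sqrt(mean(d[upper.tri(d)]^2)))
  # extreme case: all differences of magnitude 2
  ra <- matrix(1, 4, 4)
  rb <- -ra
  diag(ra) <- diag(rb) <- 1
  expect_equal(gsca_statistic(ra, rb), 2)
  # spec worked example: exactly two pairs differ by +/-0.2
  r2 <- r1
  r2[1, 2] <- r2[2, 1] <- r1[1, 2] - 0.2
  r2[1, 3] <- r2[3, 1] <- r1[1, 3] + 0.2
  mask <- r1
  mask[] <- NA
  mask[1, 2] <- mask[2, 1] <- r1[1, 2]
  mask[1, 3] <- mask[3, 1] <- r1[1, 3]
  mask2 <- mask
  mask2[1, 2] <- mask2[2, 1] <- r2[1, 2]
  mask2[1, 3] <- mask2[3, 1] <- r2[1, 3]
  expect_equal(gsca_statistic(mask, mask2), 0.2)
})

test_that("cell balancing downsamples deterministically to the minority", {
  cm <- toy_cm(180, 10, seed = 5,
               condition = rep(c("case", "ctrl"), c(100, 80)))
  b1 <- balance_cells(cm, seed = 42)
  b2 <- balance_cells(cm, seed = 42)
  expect_identical(b1$cell_ids, b2$cell_ids)
  expect_equal(as.integer(table(b1$condition)), c(80L, 80L))
  expect_true(all(b1$cell_ids %in% cm$cell_ids))
  # equal sizes: identity
  cme <- toy_cm(40, 10, seed = 6, condition = rep(c("a", "b"), 20))
  expect_identical(balance_cells(cme, seed = 1)$cell_ids, cme$cell_ids)
  # too-small condition
  cms <- toy_cm(30, 10, seed = 7, condition = rep(c("a", "b"), c(25, 5)))
  expect_error(balance_cells(cms, seed = 1), "< 10")
})

test_that("duplicated-condition input yields exactly zero statistics", {
  base <- toy_cm(80, 12, seed = 11)
  X <- rbind(base$counts, base$counts)
  cm <- count_matrix(X, cell_ids = c(paste0(base$cell_ids, "_1"),
                                     paste0(base$cell_ids, "_2")),
                     gene_ids = base$gene_ids,
                     condition = rep(c("a", "b"), each = 80))
  for (m in c("gsncascr", "gsnca_pearson", "gsca")) {
    res <- permutation_test(cm, base$gene_ids[1:8], method = m,
                            n_perm = 10, seed = 1,
                            pvalue_mode = "empirical")
    expect_equal(res$statistic, 0)
  }
})

test_that("permutation test is deterministic and validates n_perm", {
  cm <- toy_cm_null(80, 10, seed = 12)
  expect_error(permutation_test(cm, cm$gene_ids[1:5], n_perm = 5),
               "n_perm")
  r1 <- permutation_test(cm, cm$gene_ids[1:5], n_perm = 20, seed = 9)
  r2 <- permutation_test(cm, cm$gene_ids[1:5], n_perm = 20, seed = 9)
  expect_identical(r1, r2)
  expect_gt(r1$pvalue, 0)
  expect_lte(r1$pvalue, 1)
})

test_that("normal and empirical p-values agree when the null looks normal", {
  cm <- toy_cm_null(120, 8, seed = 13)
  genes <- cm$gene_ids[1:6]
  rn <- permutation_test(cm, genes, method = "gsnca_pearson", n_perm = 2000,
                         seed = 3, pvalue_mode = "normal_approx")
  re <- permutation_test(cm, genes, method = "gsnca_pearson", n_perm = 2000,
                         seed = 3, pvalue_mode = "empirical")
  if (!is.na(rn$shapiro_p) && rn$shapiro_p > 0.05) {
    expect_lt(abs(rn$pvalue - re$pvalue), 0.02)
  }
  expect_equal(rn$statistic, re$statistic)
})

test_that("pathway scans adjust p-values, order rows and log skipped sets", {
  cm <- toy_cm_null(100, 30, seed = 14)
  sets <- gene_set_collection(list(
    sA = cm$gene_ids[1:8], sB = cm$gene_ids[9:20],
    tiny = c(cm$gene_ids[21], "absent1", "absent2"),
    sC = cm$gene_ids[15:26]))
  scan <- run_pathway_scan(cm, sets, method = "gsnca_pearson", n_perm = 50,
                           seed = 2)
  expect_equal(nrow(scan), 3)
  expect_named(attr(scan, "skipped"), "tiny")
  expect_false(is.unsorted(scan$pvalue))
  expect_equal(scan$pvalue_adj, p.adjust(scan$pvalue, "BH"),
               tolerance = 1e-12)
  expect_true(all(scan$pvalue_adj >= scan$pvalue))
  # deterministic rerun
  scan2 <- run_pathway_scan(cm, sets, method = "gsnca_pearson", n_perm = 50,
                            seed = 2)
  expect_identical(as.data.frame(scan), as.data.frame(scan2))
})

test_that("positive pathways stand out from their permutation null more than negative", {
  # the raw L1 statistic scales with set size and structure, so pathways are
  # compared on the permutation z-score, the scale the test actually ranks on
  spec <- simulation_spec(n_genes = 120, n_cells_per_condition = 1500,
                          n_correlated_pairs = 40,
                          pathway_sizes = 40L, seed = 21)
  sim <- simulate_counts(spec)
  sets <- build_pathways(sim$truth, 40L,
                         list(c(0L, 1L, 2L, 12L, 16L, 20L)),
                         all_genes = sim$truth$gene_ids, seed = 3)
  cm <- count_matrix(rbind(sim$cm_corr$counts, sim$cm_indep$counts),
                     cell_ids = c(sim$cm_corr$cell_ids,
                                  sim$cm_indep$cell_ids),
                     gene_ids = sim$cm_corr$gene_ids,
                     condition = rep(c("a", "b"), each = 1500))
  depths <- estimate_depths(cm)
  z <- vapply(seq_along(sets), function(k) {
    res <- permutation_test(cm, sets[[k]], method = "gsncascr",
                            n_perm = 100, seed = 70 + k, depths = depths,
                            pathway = names(sets)[k])
    (res$statistic - res$perm_mean) / res$perm_sd
  }, numeric(1))
  lab <- attr(sets, "truth_label")
  expect_gt(median(z[lab == "positive"]), median(z[lab == "negative"]))
})
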