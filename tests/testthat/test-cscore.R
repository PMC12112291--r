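test_that("depths are per-cell totals and zero-total cells are refused", {
  cm <- count_matrix(matrix(c(1, 2, 3, 0, 0, 4), 2, 3, byrow = TRUE),
                     cell_ids = c("u", "v"), gene_ids = c("a", "b", "c"))
  expect_equal(unname(estimate_depths(cm)), c(6, 4))
  cm0 <- count_matrix(matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE),
                      cell_ids = c("u", "v"), gene_ids = c("a", "b"))
  expect_error(estimate_depths(cm0), "v")
})

test_that("compiled IRLS engine matches the pure-R reference", {
  cm <- toy_cm(300, 15, seed = 9)
  X <- cm$counts
  s <- rowSums(X)
  a <- diffcoexpr:::.cscore_irls_cpp(X, s, 10L, 1e-6)
  b <- diffcoexpr:::.cscore_irls_r(X, s, 10L, 1e-6)
  expect_equal(a$mu, unname(b$mu), tolerance = 1e-10)
  expect_equal(a$sig, unname(b$sig), tolerance = 1e-10)
  expect_equal(unname(a$num), unname(b$num), tolerance = 1e-8)
  expect_equal(unname(a$den), unname(b$den), tolerance = 1e-8)
  expect_identical(a$n_iter, b$n_iter)
  expect_identical(a$converged, b$converged)
})

test_that("estimates are exchangeable under cell reordering", {
  cm <- toy_cm(200, 10, seed = 4)
  fit1 <- fit_cscore(cm)
  perm <- sample(seq_len(200))
  fit2 <- fit_cscore(subset_cells(cm, cells = perm))
  expect_equal(fit1$mu, fit2$mu, tolerance = 1e-12)
  expect_equal(fit1$sigma_diag, fit2$sigma_diag, tolerance = 1e-12)
  expect_equal(fit1$rho, fit2$rho, tolerance = 1e-10)
})

test_that("rescaling depths rescales mu and sigma but leaves r and T fixed", {
  cm <- toy_cm(300, 8, seed = 5)
  s <- estimate_depths(cm)
  f1 <- fit_cscore(cm, depths = s)
  f2 <- fit_cscore(cm, depths = 10 * s)
  # agreement up to the IRLS stopping tolerance (absolute, hence scale-bound)
  expect_equal(unname(f2$mu), unname(f1$mu) / 10, tolerance = 1e-5)
  expect_equal(unname(f2$sigma_diag), unname(f1$sigma_diag) / 100,
               tolerance = 1e-5)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-5)
  expect_equal(f2$tstat, f1$tstat, tolerance = 1e-5)
})

test_that("constant-depth pure-Poisson data drives overdispersion to zero", {
  set.seed(21)
  n <- 5000
  X <- matrix(rpois(n * 20, 2), n, 20)
  cm <- count_matrix(X, cell_ids = sprintf("c%04d", 1:n),
                     gene_ids = sprintf("g%02d", 1:20))
  fit <- fit_cscore(cm, depths = rep(1000, n))
  expect_true(median(fit$sigma_diag) <= 0.01 * median(fit$mu))
})

test_that("a duplicated gene column is perfectly correlated after clipping", {
  cm <- toy_cm(400, 5, seed = 6)
  X <- cbind(cm$counts, dup = cm$counts[, 3])
  colnames(X) <- c(cm$gene_ids, "dup")
  cm2 <- count_matrix(X)
  fit <- fit_cscore(cm2)
  expect_equal(fit$rho["g003", "dup"], 1)
})

test_that("all-zero genes propagate as missing, never as zero correlation", {
  cm <- toy_cm(100, 6, seed = 7)
  cm$counts[, 4] <- 0
  fit <- fit_cscore(cm)
  expect_equal(unname(fit$mu[4]), 0)
  expect_true(all(is.na(fit$rho[4, ])))
  expect_true(all(is.na(fit$tstat[4, ])))
  expect_true(all(is.na(fit$pval[4, ])))
  expect_false(anyNA(fit$rho[-4, -4]))
})

test_that("p-values are the two-sided normal tail of the test statistic", {
  fit <- fit_cscore(toy_cm(200, 8, seed = 8))
  ut <- upper.tri(fit$tstat)
  expect_equal(fit$pval[ut], 2 * pnorm(-abs(fit$tstat[ut])),
               tolerance = 1e-12)
  expect_true(all(fit$pval[ut] > 0 & fit$pval[ut] <= 1))
  expect_true(isSymmetric(fit$rho) && isSymmetric(fit$tstat))
})

test_that("mean expression is recovered under known constant parameters", {
  # mu = 0.5, sigma_jj = 0.05 (cv2 = 0.2), constant depth
  set.seed(31)
  n <- 2000
  p <- 50
  s <- rep(30, n)
  Z <- matrix(rgamma(n * p, shape = 5, scale = 0.1), n, p) # mean .5 var .05
  X <- matrix(rpois(n * p, s[1] * Z), n, p)
  cm <- count_matrix(X, cell_ids = sprintf("c%04d", 1:n),
                     gene_ids = sprintf("g%02d", 1:p))
  fit <- fit_cscore(cm, depths = s)
  se <- sd(fit$mu) / sqrt(p)
  expect_lt(abs(mean(fit$mu) - 0.5), 3 * se + 1e-3)
  expect_lt(abs(median(fit$sigma_diag) - 0.05), 0.02)
})

test_that("correlation estimates sharpen as cells grow", {
  rmse <- vapply(c(500, 2000, 8000), function(n) {
    spec <- simulation_spec(n_genes = 30, n_cells_per_condition = n,
                            n_correlated_pairs = 10, block_corr = 0.6,
                            block_corr_jitter = 0, seed = 77)
    sim <- simulate_counts(spec)
    r <- cscore_correlations(fit_cscore(sim$cm_corr))
    sqrt(mean((r[sim$truth$pair_idx] - 0.6)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1] * 1.2)
  expect_lt(rmse[3], rmse[2] * 1.2)
  expect_lt(rmse[3], rmse[1])
})

test_that("designated-pair signs are recovered at realistic scale", {
  spec <- simulation_spec(n_genes = 100, n_cells_per_condition = 3000,
                          n_correlated_pairs = 40, block_corr = 0.6,
                          seed = 15)
  sim <- simulate_counts(spec)
  r <- cscore_correlations(fit_cscore(sim$cm_corr))
  signs <- sign(r[sim$truth$pair_idx])
  expect_gte(mean(signs == 1), 0.95)
})

test_that("long-format pair export carries r, T and p consistently", {
  fit <- fit_cscore(toy_cm(100, 5, seed = 2))
  df <- export_pairs(fit)
  expect_equal(nrow(df), choose(5, 2))
  i <- which(df$gene_a == "g002" & df$gene_b == "g004")
  expect_equal(df$r[i], fit$rho["g002", "g004"])
  expect_equal(df$p[i], fit$pval["g002", "g004"])
})
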