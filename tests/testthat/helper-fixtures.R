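# Small fixtures built in code; all randomness under explicit seeds.

# Gamma-Poisson toy count matrix with lognormal depths and biological
# overdispersion (cv2 = 0.5), no correlation structure.
toy_cm <- function(n_cells = 60, n_genes = 20, mu = 0.01, seed = 1,
                   condition = NULL, cv2 = 0.5) {
  set.seed(seed)
  s <- rlnorm(n_cells, log(500), 0.3)
  Z <- matrix(rgamma(n_cells * n_genes, shape = 1 / cv2, scale = cv2 * mu),
              n_cells, n_genes)
  X <- matrix(rpois(n_cells * n_genes, lambda = s * Z), n_cells, n_genes)
  X[, 1] <- X[, 1] + 1 # guard against all-zero cells in tiny fixtures
  count_matrix(X,
               cell_ids = sprintf("c%03d", seq_len(n_cells)),
               gene_ids = sprintf("g%03d", seq_len(n_genes)),
               condition = condition)
}

# Two-condition matrix from one homogeneous population (true null).
toy_cm_null <- function(n_cells = 60, n_genes = 20, seed = 1) {
  toy_cm(n_cells, n_genes, seed = seed,
         condition = rep(c("a", "b"), length.out = n_cells))
}

# A valid correlation-like symmetric matrix from random data.
random_corr <- function(p, n = 50, seed = 1) {
  set.seed(seed)
  r <- cor(matrix(rnorm(n * p), n, p))
  dimnames(r) <- list(sprintf("g%02d", 1:p), sprintf("g%02d", 1:p))
  r
}

# Minimal weight_vector stub for statistic arithmetic tests.
wv_stub <- function(w, genes = sprintf("g%d", seq_along(w))) {
  structure(list(genes = genes, w_raw = w / sum(w) * length(w),
                 w_norm = stats::setNames(w, genes),
                 eigenvalue = 1, degenerate = FALSE),
            class = "weight_vector")
}
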