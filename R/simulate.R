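#' Specify a synthetic scRNA-seq benchmark simulation
#'
#' The generator draws per-gene relative expression `mu_j` and biological
#' overdispersion `sigma_jj = cv2_j * mu_j^2` (with `cv2_j` from
#' `disp_range`, the squared biological coefficient of variation), imposes a
#' block Gaussian-copula correlation structure on designated gene pairs,
#' maps to gamma marginals, draws per-cell sequencing depths lognormally and
#' observes counts through a Poisson measurement layer. Two datasets share
#' marginals and depths: one preserves the designated pair correlations, the
#' other uses the identity copula (no co-expression).
#'
#' @param n_genes Number of genes (default 500).
#' @param n_cells_per_condition Cells per dataset (default 3000).
#' @param mu_range Interval for per-gene relative expression (fraction of a
#'   cell's depth; default `c(0.001, 0.01)`, i.e. mean counts of roughly
#'   5-50 at the default depth).
#' @param disp_range Interval for the squared biological coefficient of
#'   variation `sigma_jj / mu_j^2` (default `c(0.1, 1)`).
#' @param depth_lognormal_params `c(meanlog, sdlog)` of per-cell depth
#'   (default `c(log(5000), 0.35)`).
#' @param block_corr Target copula correlation of designated gene pairs
#'   (default 0.6).
#' @param block_corr_jitter Half-width of the per-pair correlation spread:
#'   each designated pair's copula correlation is drawn uniformly from
#'   `block_corr +/- block_corr_jitter`, clipped to `[0.05, 0.95]` (default
#'   0.2, mimicking the spread of highly correlated pairs in real tissues;
#'   0 gives every pair exactly `block_corr`).
#' @param background_corr Mean within-module background copula correlation
#'   in the correlation-preserving dataset (default 0, i.e. non-designated
#'   gene pairs are independent). When positive, genes are
#'   partitioned into modules of roughly 25 genes, each loading on a module
#'   factor, emulating the modular low-level co-expression of real tissue;
#'   across-module background is 0 and designated pairs sit on top at their
#'   target correlation. The correlation-destroying dataset never has it.
#'   Set 0 for fully independent non-designated genes.
#' @param n_correlated_pairs Number of disjoint designated pairs (default
#'   150; requires `2 * n_correlated_pairs <= n_genes`).
#' @param pathway_sizes Pathway sizes for [build_pathways()] (default
#'   `c(20, 40, 60, 80, 100)`).
#' @param positive_cutoff,negative_cutoff Correlated-gene fraction cutoffs
#'   labeling a pathway positive (`> positive_cutoff`) or negative
#'   (`< negative_cutoff`); defaults 0.4 and 0.2.
#' @param dropout_fraction Target matrix-wide zero fraction applied by
#'   [corrupt_dropout()] in [run_benchmark()] (0 = no corruption).
#' @param noise_prob Per-entry multiplicative-noise probability applied by
#'   [corrupt_noise()] in [run_benchmark()].
#' @param seed Integer seed; all generator randomness derives from it.
#' @return List of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec(n_genes = 40, n_cells_per_condition = 100,
#'                         n_correlated_pairs = 10, seed = 1)
#' sim <- simulate_counts(spec)
#' sim$cm_corr
#' @export
simulation_spec <- function(n_genes = 500L, n_cells_per_condition = 3000L,
                            mu_range = c(0.001, 0.01),
                            disp_range = c(0.1, 1),
                            depth_lognormal_params = c(log(5000), 0.35),
                            block_corr = 0.6, block_corr_jitter = 0.2,
                            background_corr = 0,
                            n_correlated_pairs = 150L,
                            pathway_sizes = c(20L, 40L, 60L, 80L, 100L),
                            positive_cutoff = 0.4, negative_cutoff = 0.2,
                            dropout_fraction = 0, noise_prob = 0,
                            seed = 1L) {
  stopifnot(n_genes >= 4, n_cells_per_condition >= 10,
            length(mu_range) == 2, mu_range[1] > 0, diff(mu_range) >= 0,
            length(disp_range) == 2, disp_range[1] >= 0,
            diff(disp_range) >= 0,
            length(depth_lognormal_params) == 2,
            block_corr > 0, block_corr < 1,
            block_corr_jitter >= 0, block_corr_jitter < 1,
            background_corr >= 0, background_corr < 1,
            n_correlated_pairs >= 0, 2 * n_correlated_pairs <= n_genes,
            negative_cutoff <= positive_cutoff,
            dropout_fraction >= 0, dropout_fraction <= 0.7,
            noise_prob >= 0, noise_prob <= 0.7)
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_condition = as.integer(n_cells_per_condition),
                 mu_range = mu_range, disp_range = disp_range,
                 depth_lognormal_params = depth_lognormal_params,
                 block_corr = block_corr,
                 block_corr_jitter = block_corr_jitter,
                 background_corr = background_corr,
                 n_correlated_pairs = as.integer(n_correlated_pairs),
                 pathway_sizes = as.integer(pathway_sizes),
                 positive_cutoff = positive_cutoff,
                 negative_cutoff = negative_cutoff,
                 dropout_fraction = dropout_fraction,
                 noise_prob = noise_prob, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Modular background structure: deterministic gene partition into modules of
# ~25 genes and per-gene factor loadings with mean sqrt(bg), so the mean
# within-module pairwise copula correlation is bg.
.background_loadings <- function(p, bg) {
  module <- rep(seq_len(max(1L, round(p / 25))), length.out = p)
  lam <- if (bg > 0) {
    m <- sqrt(bg)
    stats::runif(p, max(0, m - 0.2), min(0.95, m + 0.2))
  } else {
    rep(0, p)
  }
  list(module = module, lambda = lam)
}

# Latent gamma expression via Gaussian copula. `pairs` is a 2-column index
# matrix of disjoint gene pairs; `rho` gives each pair's copula correlation
# (recycled if scalar). Background: gene j = lambda_j * (its module factor)
# + sqrt(1 - lambda_j^2) * residual, so within-module pairs correlate at
# lambda_a lambda_b. Each designated pair's residual correlation is raised
# so its TOTAL copula correlation is its target rho (clipped if the
# background already exceeds it). Returns an n x p latent expression matrix.
.latent_expression <- function(n, mu, cv2, pairs, rho, bgl = NULL) {
  rho <- rep_len(rho, nrow(pairs))
  p <- length(mu)
  Y <- matrix(stats::rnorm(n * p), n, p)
  lam <- if (is.null(bgl)) rep(0, p) else bgl$lambda
  if (nrow(pairs) > 0) {
    a <- pairs[, 1]
    b <- pairs[, 2]
    same_mod <- if (is.null(bgl)) rep(FALSE, nrow(pairs)) else
      bgl$module[a] == bgl$module[b]
    bg_ab <- ifelse(same_mod, lam[a] * lam[b], 0)
    res_scale <- sqrt((1 - lam[a]^2) * (1 - lam[b]^2))
    rr <- pmin(pmax((rho - bg_ab) / res_scale, 0), 0.995)
    Y[, b] <- sweep(Y[, a, drop = FALSE], 2, rr, `*`) +
      sweep(Y[, b, drop = FALSE], 2, sqrt(1 - rr^2), `*`)
  }
  if (any(lam > 0)) {
    G <- matrix(stats::rnorm(n * max(bgl$module)), n)
    Y <- G[, bgl$module, drop = FALSE] * rep(lam, each = n) +
      sweep(Y, 2, sqrt(1 - lam^2), `*`)
  }
  U <- stats::pnorm(Y)
  Z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    if (cv2[j] < 1e-12) {
      Z[, j] <- mu[j]
    } else {
      Z[, j] <- stats::qgamma(U[, j], shape = 1 / cv2[j],
                              scale = cv2[j] * mu[j])
    }
  }
  Z
}

#' Simulate paired UMI count datasets with and without co-expression
#'
#' Generates `cm_corr` (designated gene pairs correlated at
#' `spec$block_corr` on the copula scale) and `cm_indep` (identical
#' marginals and the same per-cell depths, identity copula). Deterministic
#' given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `cm_corr`, `cm_indep` (both [count_matrix()]) and
#'   `truth`: generating parameters (`mu`, `sigma_diag`, `cv2`, `pairs`
#'   (id matrix), `pair_idx`, `correlated_genes`, `block_corr`, `depths`,
#'   `gene_ids`, `seed`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- spec$n_genes
  n <- spec$n_cells_per_condition
  gene_ids <- sprintf("g%04d", seq_len(p))
  par <- .with_seed(.derive_seed(spec$seed, 1), {
    mu <- stats::runif(p, spec$mu_range[1], spec$mu_range[2])
    cv2 <- stats::runif(p, spec$disp_range[1], spec$disp_range[2])
    corr_genes <- if (spec$n_correlated_pairs > 0)
      sample.int(p, 2 * spec$n_correlated_pairs) else integer(0)
    pair_rho <- pmin(pmax(stats::runif(spec$n_correlated_pairs,
                                       spec$block_corr - spec$block_corr_jitter,
                                       spec$block_corr + spec$block_corr_jitter),
                          0.05), 0.95)
    bgl <- .background_loadings(p, spec$background_corr)
    list(mu = mu, cv2 = cv2, corr_genes = corr_genes, pair_rho = pair_rho,
         bgl = bgl)
  })
  pairs <- if (spec$n_correlated_pairs > 0) {
    matrix(par$corr_genes, ncol = 2, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2)
  }
  depths <- .with_seed(.derive_seed(spec$seed, 2), {
    stats::rlnorm(n, spec$depth_lognormal_params[1],
                  spec$depth_lognormal_params[2])
  })
  draw <- function(stream, use_pairs) {
    .with_seed(.derive_seed(spec$seed, stream), {
      Z <- .latent_expression(n, par$mu, par$cv2,
                              if (use_pairs) pairs else pairs[0, , drop = FALSE],
                              par$pair_rho,
                              bgl = if (use_pairs) par$bgl else NULL)
      matrix(stats::rpois(n * p, lambda = depths * Z), n, p)
    })
  }
  X_corr <- draw(3, TRUE)
  X_indep <- draw(4, FALSE)
  cm_corr <- count_matrix(X_corr,
                          cell_ids = sprintf("cA%05d", seq_len(n)),
                          gene_ids = gene_ids)
  cm_indep <- count_matrix(X_indep,
                           cell_ids = sprintf("cB%05d", seq_len(n)),
                           gene_ids = gene_ids)
  truth <- list(mu = stats::setNames(par$mu, gene_ids),
                sigma_diag = stats::setNames(par$cv2 * par$mu^2, gene_ids),
                cv2 = stats::setNames(par$cv2, gene_ids),
                pair_idx = pairs,
                pairs = matrix(gene_ids[pairs], ncol = 2),
                correlated_genes = gene_ids[as.vector(pairs)],
                block_corr = spec$block_corr,
                background_corr = spec$background_corr,
                background_modules = par$bgl$module,
                background_loadings = par$bgl$lambda,
                pair_rho = par$pair_rho,
                depths = depths, gene_ids = gene_ids, seed = spec$seed)
  list(cm_corr = cm_corr, cm_indep = cm_indep, truth = truth)
}

#' Build labeled benchmark pathways from designated correlated pairs
#'
#' For each requested `(size, n_corr)` combination, takes the genes of
#' `n_corr` designated correlated pairs and fills the remainder with
#' randomly chosen non-correlated genes. The correlated-gene fraction
#' `2 * n_corr / size` determines the truth label: positive above
#' `positive_cutoff`, negative below `negative_cutoff`, ambiguous otherwise.
#'
#' @param truth The `truth` element of [simulate_counts()] output.
#' @param pathway_sizes Integer vector of pathway sizes.
#' @param correlated_counts List (parallel to `pathway_sizes`) or single
#'   vector of numbers of correlated pairs per pathway; a vector is recycled
#'   across sizes, skipping combinations with `2 * n_corr > size`.
#' @param all_genes Character vector of measured gene ids.
#' @param positive_cutoff,negative_cutoff Label cutoffs (defaults 0.4, 0.2).
#' @param seed Integer seed for pair/filler sampling.
#' @return A `gene_set_collection` with a `truth_label` attribute.
#' @export
build_pathways <- function(truth, pathway_sizes, correlated_counts,
                           all_genes, positive_cutoff = 0.4,
                           negative_cutoff = 0.2, seed = 1L) {
  if (!is.list(correlated_counts))
    correlated_counts <- rep(list(correlated_counts), length(pathway_sizes))
  stopifnot(length(correlated_counts) == length(pathway_sizes))
  n_avail <- nrow(truth$pair_idx)
  free_genes <- setdiff(all_genes, truth$correlated_genes)
  sets <- list()
  labels <- character(0)
  .with_seed(seed, {
    for (k in seq_along(pathway_sizes)) {
      size <- pathway_sizes[k]
      for (nc in correlated_counts[[k]]) {
        if (2 * nc > size)
          stop("pathway size ", size, " cannot fit ", nc, " correlated pairs")
        if (nc > n_avail)
          stop("requested ", nc, " correlated pairs but only ", n_avail,
               " are designated")
        pg <- if (nc > 0) {
          as.vector(t(truth$pairs[sample.int(n_avail, nc), , drop = FALSE]))
        } else character(0)
        n_fill <- size - length(pg)
        if (n_fill > length(free_genes))
          stop("not enough non-correlated genes to fill pathway of size ",
               size)
        fill <- sample(free_genes, n_fill)
        frac <- 2 * nc / size
        lab <- if (frac > positive_cutoff) "positive"
               else if (frac < negative_cutoff) "negative" else "ambiguous"
        nm <- sprintf("pw_size%03d_ncorr%03d", size, nc)
        sets[[nm]] <- c(pg, fill)
        labels[nm] <- lab
      }
    }
  })
  gene_set_collection(sets, truth_label = unname(labels))
}

#' Corrupt a count matrix with expression-dependent dropout
#'
#' Zeroes out nonzero entries, preferring low counts (selection weight
#' `exp(-x)`), until the matrix-wide zero fraction reaches
#' `target_zero_fraction` (within 0.005). Entries are only ever set to
#' zero, never otherwise modified.
#'
#' @param cm A [count_matrix()].
#' @param target_zero_fraction Target overall zero fraction; must be at
#'   least the current zero fraction.
#' @param seed Integer seed.
#' @return The corrupted `count_matrix`.
#' @export
corrupt_dropout <- function(cm, target_zero_fraction, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  X <- cm$counts
  N <- length(X)
  cur <- sum(X == 0) / N
  if (target_zero_fraction < cur - 1e-12)
    stop(sprintf("target zero fraction %.3f is below current %.3f",
                 target_zero_fraction, cur))
  m <- round(target_zero_fraction * N) - sum(X == 0)
  if (m > 0) {
    nz <- which(X != 0)
    w <- exp(-X[nz])
    # weighted sampling without replacement (exponential-key trick)
    drop_idx <- .with_seed(seed, {
      keys <- stats::rexp(length(nz)) / w
      nz[order(keys)[seq_len(m)]]
    })
    X[drop_idx] <- 0
  }
  cm$counts <- X
  cm
}

#' Corrupt a count matrix with multiplicative noise
#'
#' Each nonzero entry is independently selected with probability
#' `noise_prob`; selected entries are multiplied by Uniform(1.3, 1.5)
#' (a 30-50% increase) or Uniform(0.6, 0.8) (a 20-40% decrease), direction
#' chosen by a fair coin, then rounded to the nearest integer. Zeros are
#' untouched.
#'
#' @param cm A [count_matrix()].
#' @param noise_prob Per-entry selection probability in `[0, 0.7]`.
#' @param seed Integer seed.
#' @return The corrupted `count_matrix`.
#' @export
corrupt_noise <- function(cm, noise_prob, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"),
            noise_prob >= 0, noise_prob <= 0.7)
  if (noise_prob == 0) return(cm)
  X <- cm$counts
  nz <- which(X != 0)
  X[nz] <- .with_seed(seed, {
    hit <- stats::runif(length(nz)) < noise_prob
    fac <- rep(1, length(nz))
    nh <- sum(hit)
    up <- stats::runif(nh) < 0.5
    fac[hit] <- ifelse(up, stats::runif(nh, 1.3, 1.5),
                       stats::runif(nh, 0.6, 0.8))
    ifelse(hit, round(X[nz] * fac), X[nz])
  })
  cm$counts <- X
  cm
}
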