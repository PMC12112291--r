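#' Eigenvector gene weights of a correlation network
#'
#' Genes in a set are assigned weights such that each gene's weight equals
#' the sum of its partners' weights scaled by the (absolute) pairwise
#' correlations -- the fixed point is the leading eigenvector of the matrix
#' `A` with `A_ij = |r_ij|` off the diagonal and `A_ii = 0`. Absolute values
#' guarantee a nonnegative matrix, hence (Perron-Frobenius) a nonnegative
#' leading eigenvector. The returned weights are scaled to mean exactly 1
#' (`w_norm = p * w_raw / sum(w_raw)`), so "important" genes sit above 1.
#'
#' Genes with any undefined (`NA`) correlation are removed before the
#' eigen-decomposition; at least 3 genes must remain.
#'
#' @param r Symmetric correlation matrix (may contain `NA` entries).
#' @return Object of class `weight_vector`: list with `genes`, `w_raw`,
#'   `w_norm`, `eigenvalue`, `degenerate` (TRUE when the top two eigenvalues
#'   are within 1e-10, flagged rather than perturbed).
#' @examples
#' r <- cor(matrix(rnorm(200), 40, 5))
#' weight_vector(r)$w_norm
#' @export
weight_vector <- function(r) {
  if (!isSymmetric(unname(r), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  genes <- rownames(r)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(r)))
  A <- abs(r)
  diag(A) <- 0
  # drop offending genes greedily (a zero-variance gene NAs a whole row AND
  # one entry of every other row; removing by most-missing keeps the rest)
  while (anyNA(A) && nrow(A) > 0) {
    worst <- which.max(rowSums(is.na(A)))
    A <- A[-worst, -worst, drop = FALSE]
    genes <- genes[-worst]
  }
  if (nrow(A) < 3)
    stop("fewer than 3 genes with fully defined correlations")
  p <- nrow(A)
  if (all(A == 0)) stop("degenerate input: all correlations are zero")
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-12] <- 0 # numerical noise on disconnected genes
  if (any(v < 0)) v <- pmax(v, 0) # Perron vector is nonnegative
  sw <- sum(v)
  if (sw <= 0) stop("degenerate input: zero leading eigenvector mass")
  degenerate <- (length(e$values) > 1 && e$values[1] - e$values[2] < 1e-10)
  structure(list(genes = genes, w_raw = stats::setNames(v, genes),
                 w_norm = stats::setNames(p * v / sw, genes),
                 eigenvalue = e$values[1], degenerate = degenerate),
            class = "weight_vector")
}

#' L1 network-difference statistic between two weight vectors
#'
#' Sum of absolute differences between the scaled (mean-1) weight vectors of
#' the same gene set under two conditions; zero iff the weight profiles
#' coincide.
#'
#' @param w1,w2 `weight_vector` objects over the identical ordered gene list.
#' @return Nonnegative scalar.
#' @export
gsnca_statistic <- function(w1, w2) {
  stopifnot(inherits(w1, "weight_vector"), inherits(w2, "weight_vector"))
  if (!identical(w1$genes, w2$genes))
    stop("weight vectors are over different gene lists")
  sum(abs(w1$w_norm - w2$w_norm))
}

#' Correlation-difference dispersion statistic
#'
#' Root-mean-square of the pairwise correlation differences between two
#' conditions over all unordered gene pairs -- the aggregate-dispersion style
#' of gene-set co-expression testing.
#'
#' @param r1,r2 Correlation matrices over the same gene set.
#' @return Nonnegative scalar (`NA` pairs dropped from the mean).
#' @export
gsca_statistic <- function(r1, r2) {
  if (!identical(dim(r1), dim(r2)) ||
      !identical(rownames(r1), rownames(r2)))
    stop("correlation matrices do not match")
  ut <- upper.tri(r1)
  d <- (r1 - r2)[ut]
  sqrt(mean(d^2, na.rm = TRUE))
}

#' Balance the two conditions to equal cell numbers
#'
#' Downsamples the larger condition without replacement to the size of the
#' smaller one, keeping the original cell order; deterministic given `seed`.
#'
#' @param cm A [count_matrix()] with a condition attached.
#' @param seed Integer seed.
#' @return A balanced `count_matrix`.
#' @export
balance_cells <- function(cm, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$condition)) stop("no condition attached")
  tb <- table(cm$condition)
  if (any(tb < 10))
    stop("condition '", names(tb)[which.min(tb)], "' has ", min(tb),
         " cells (< 10): too few for estimation")
  n_keep <- min(tb)
  keep <- logical(length(cm$cell_ids))
  withr_seed <- .with_seed(seed, {
    for (lev in names(tb)) {
      idx <- which(cm$condition == lev)
      if (length(idx) > n_keep) idx <- sort(sample(idx, n_keep))
      keep[idx] <- TRUE
    }
    keep
  })
  subset_cells(cm, cells = which(withr_seed))
}

# Depth-normalize to the median depth and log1p -- the conventional
# preprocessing for the Pearson-based baselines.
.lognormalize <- function(X, s) {
  f <- stats::median(s) / s
  log1p(X * f)
}

# Per-condition correlation matrices on a gene subset for a given backend.
# Returns list(r1, r2, genes) restricted to genes with fully defined
# correlations in BOTH conditions, or NULL if fewer than 3 remain.
.condition_correlations <- function(X, s, cond_idx1, cond_idx2, backend,
                                    max_iter = 10L, tol = 1e-6, L = NULL) {
  if (backend == "cscore") {
    r1 <- .cscore_rho(X[cond_idx1, , drop = FALSE], s[cond_idx1],
                      max_iter, tol)
    r2 <- .cscore_rho(X[cond_idx2, , drop = FALSE], s[cond_idx2],
                      max_iter, tol)
  } else {
    r1 <- suppressWarnings(stats::cor(L[cond_idx1, , drop = FALSE]))
    r2 <- suppressWarnings(stats::cor(L[cond_idx2, , drop = FALSE]))
  }
  # undefined genes carry NA on the whole row incl. the diagonal
  ok <- !is.na(diag(r1)) & !is.na(diag(r2))
  if (sum(ok) < 3) return(NULL)
  list(r1 = r1[ok, ok, drop = FALSE], r2 = r2[ok, ok, drop = FALSE],
       genes = colnames(X)[ok])
}

.method_backend <- c(gsncascr = "cscore", gsnca_pearson = "pearson",
                     gsca = "pearson")

# Observed statistic for one label split.
.split_statistic <- function(X, s, i1, i2, method, max_iter, tol, L) {
  backend <- .method_backend[[method]]
  cc <- .condition_correlations(X, s, i1, i2, backend, max_iter, tol, L)
  if (is.null(cc)) return(list(stat = NA_real_, n_genes = 0L))
  stat <- if (method == "gsca") {
    gsca_statistic(cc$r1, cc$r2)
  } else {
    gsnca_statistic(weight_vector(cc$r1), weight_vector(cc$r2))
  }
  list(stat = stat, n_genes = length(cc$genes))
}

#' Permutation test of differential co-expression for one gene set
#'
#' Computes the observed network-difference statistic between the two
#' conditions of a (balanced) count matrix, then re-computes it under
#' `n_perm` random reassignments of the cell condition labels. Backends:
#' `gsncascr` fits the Poisson measurement-model estimator per condition and
#' feeds its correlations into the eigenvector L1 statistic; `gsnca_pearson`
#' uses Pearson correlations of depth-normalized log counts with the same
#' statistic; `gsca` uses the Pearson correlations with the dispersion
#' statistic.
#'
#' p-values: `normal_approx` fits a normal to the permutation statistics and
#' returns the upper-tail probability of the observed value (the permutation
#' null of the L1 statistic is close to normal, which this mode exploits to
#' get resolution beyond `1/n_perm`); `empirical` returns
#' `(k + 1) / (n_perm + 1)` with `k` the number of permutation statistics at
#' or above the observed one. A Shapiro-Wilk p-value on the permutation
#' sample is recorded as a normality diagnostic. If the permutation
#' statistics are all identical (sd 0), the empirical mode is used with a
#' warning.
#'
#' @param cm A balanced [count_matrix()] with two condition levels.
#' @param geneset Character vector of gene ids (intersected with measured
#'   genes; at least 3 must remain).
#' @param method One of `"gsncascr"`, `"gsnca_pearson"`, `"gsca"`.
#' @param n_perm Number of permutations (>= 10; default 500).
#' @param seed Integer seed.
#' @param pvalue_mode `"normal_approx"` (default) or `"empirical"`.
#' @param max_iter,tol IRLS controls passed to the estimator backend.
#' @param depths Optional precomputed depths for `cm`.
#' @return One-row data.frame (class `pathway_test`) with columns `pathway`,
#'   `method`, `n_genes_used`, `statistic`, `perm_mean`, `perm_sd`, `n_perm`,
#'   `pvalue`, `pvalue_adj` (`NA` here; filled by [run_pathway_scan()]),
#'   `shapiro_p`, `seed`.
#' @export
permutation_test <- function(cm, geneset, method = c("gsncascr",
                                                     "gsnca_pearson", "gsca"),
                             n_perm = 500L, seed = 1L,
                             pvalue_mode = c("normal_approx", "empirical"),
                             max_iter = 10L, tol = 1e-6, depths = NULL,
                             pathway = "geneset") {
  stopifnot(inherits(cm, "count_matrix"))
  method <- match.arg(method)
  pvalue_mode <- match.arg(pvalue_mode)
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (is.null(cm$condition)) stop("no condition attached")
  genes <- geneset[geneset %in% cm$gene_ids]
  if (length(genes) < 3)
    stop("fewer than 3 set genes measured (", length(genes), ")")
  if (is.null(depths)) depths <- estimate_depths(cm)
  s <- as.numeric(depths)
  X <- cm$counts[, match(genes, cm$gene_ids), drop = FALSE]
  levs <- levels(cm$condition)
  i1 <- which(cm$condition == levs[1])
  i2 <- which(cm$condition == levs[2])
  backend <- .method_backend[[method]]
  L <- if (backend == "pearson") .lognormalize(X, s) else NULL

  obs <- .split_statistic(X, s, i1, i2, method, max_iter, tol, L)
  if (is.na(obs$stat))
    stop("set '", pathway, "': fewer than 3 genes with defined correlations")
  n <- length(i1) + length(i2)
  n1 <- length(i1)
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pi1 <- sample.int(n, n1)
      pi2 <- setdiff(seq_len(n), pi1)
      .split_statistic(X, s, pi1, pi2, method, max_iter, tol, L)$stat
    }, numeric(1))
  })
  perm_ok <- perm[!is.na(perm)]
  if (length(perm_ok) < 10)
    stop("set '", pathway, "': too many degenerate permutations")
  pm <- mean(perm_ok)
  psd <- stats::sd(perm_ok)
  shap <- if (length(perm_ok) >= 3 && length(perm_ok) <= 5000 && psd > 0) {
    tryCatch(stats::shapiro.test(perm_ok)$p.value, error = function(e) NA_real_)
  } else NA_real_
  emp_p <- (sum(perm_ok >= obs$stat) + 1) / (length(perm_ok) + 1)
  if (psd == 0 && pvalue_mode == "normal_approx") {
    warning("permutation statistics are constant; falling back to empirical ",
            "p-value for set '", pathway, "'")
    pvalue_mode <- "empirical"
  }
  pv <- if (pvalue_mode == "normal_approx") {
    max(stats::pnorm(obs$stat, pm, psd, lower.tail = FALSE),
        .Machine$double.xmin)
  } else {
    emp_p
  }
  structure(data.frame(pathway = pathway, method = method,
                       n_genes_used = obs$n_genes, statistic = obs$stat,
                       perm_mean = pm, perm_sd = psd,
                       n_perm = length(perm_ok), pvalue = pv,
                       pvalue_adj = NA_real_, shapiro_p = shap,
                       seed = as.integer(seed),
                       stringsAsFactors = FALSE),
            class = c("pathway_test", "data.frame"))
}

#' Scan a gene-set collection for differential co-expression
#'
#' Balances the two conditions once (using `seed`), then runs
#' [permutation_test()] on every set with a per-set derived seed
#' (`seed + set index`, so subsets of a collection can be run independently
#' and merged), and adjusts p-values across all tested sets by
#' Benjamini-Hochberg. Sets that shrink below 3 measured genes (or below 3
#' genes with defined correlations) are skipped with a logged reason.
#'
#' @param cm A [count_matrix()] with a two-level condition.
#' @param sets A `gene_set_collection` (already size-filtered).
#' @param method,n_perm,pvalue_mode,max_iter,tol As [permutation_test()].
#' @param seed Top-level integer seed.
#' @param alpha Significance level recorded on the result (default 0.05).
#' @return data.frame of class `pathway_scan` ordered by p-value, one row
#'   per tested set, with `pvalue_adj` filled; skipped sets are listed in
#'   `attr(, "skipped")`.
#' @export
run_pathway_scan <- function(cm, sets, method = c("gsncascr", "gsnca_pearson",
                                                  "gsca"),
                             n_perm = 500L, seed = 1L, alpha = 0.05,
                             pvalue_mode = c("normal_approx", "empirical"),
                             max_iter = 10L, tol = 1e-6) {
  method <- match.arg(method)
  pvalue_mode <- match.arg(pvalue_mode)
  bal <- balance_cells(cm, seed = seed)
  depths <- estimate_depths(bal)
  rows <- list()
  skipped <- character(0)
  for (k in seq_along(sets)) {
    nm <- names(sets)[k]
    res <- tryCatch(
      permutation_test(bal, sets[[k]], method = method, n_perm = n_perm,
                       seed = seed + k, pvalue_mode = pvalue_mode,
                       max_iter = max_iter, tol = tol, depths = depths,
                       pathway = nm),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[nm] <- res
    } else {
      rows[[nm]] <- res
    }
  }
  if (length(rows) == 0) stop("all gene sets were skipped")
  out <- do.call(rbind, rows)
  out$pvalue_adj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pathway_scan", "data.frame"),
            skipped = skipped, alpha = alpha, seed = as.integer(seed),
            n_cells_per_condition = table(bal$condition))
}

#' @export
print.pathway_scan <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("Pathway differential co-expression scan: %d sets, method %s\n",
              nrow(x), x$method[1]))
  nc <- attr(x, "n_cells_per_condition")
  if (!is.null(nc))
    cat("  cells per condition:",
        paste(names(nc), nc, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  significant at BH-adjusted p < %g: %d\n", alpha,
              sum(x$pvalue_adj < alpha)))
  sk <- attr(x, "skipped")
  if (length(sk) > 0) cat("  skipped sets:", length(sk), "\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("pathway", "n_genes_used",
                                                    "statistic", "pvalue",
                                                    "pvalue_adj")], 10),
                   digits = 4)
  if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write a pathway scan as TSV
#'
#' @param x A `pathway_scan`.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_pathway_scan <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
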