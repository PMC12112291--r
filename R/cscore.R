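#' Per-cell sequencing depths
#'
#' Depth of a cell is its total UMI count across all genes in the matrix.
#' Depths are always computed on the full matrix, before any gene-set
#' restriction, so that pathway-level results are mutually consistent.
#'
#' @param cm A [count_matrix()].
#' @return Numeric vector of strictly positive depths, named by cell id.
#' @export
estimate_depths <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  s <- rowSums(cm$counts)
  if (any(s <= 0))
    stop("cells with zero total count: ",
         paste(utils::head(cm$cell_ids[s <= 0], 10), collapse = ", "))
  stats::setNames(s, cm$cell_ids)
}

# Core IRLS moment estimation under the Poisson measurement model.
#
# Model: z_i. ~ F(mu, Sigma); x_ij | z_ij ~ Poisson(s_i z_ij), giving the
# moment identities E(x_ij) = s_i mu_j, Var(x_ij) = s_i mu_j + s_i^2 sigma_jj,
# E[(x_ij - s_i mu_j)(x_ij' - s_i mu_j')] = s_i^2 sigma_jj'.
#
# Each IRLS pass refreshes the per-entry weights w_ij = 1 / Var(x_ij) from the
# current (mu, sigma_diag), re-estimates mu_j by weighted regression of x on s
# through the origin, then sigma_jj by weighted regression of
# (x - s mu)^2 - s mu on s^2 (weights w^2). The pairwise covariances use the
# product-residual regression on s^2 with weights g_ijj' = w_ij w_ij'; since g
# factorizes, the whole pairwise stage reduces to two crossproducts and is
# computed once with the final weights.
#
# Returns mu, sigma_diag (floored at 0), the pairwise numerator/denominator
# crossproducts, iteration count, convergence flag, and a logical mask of
# genes that are all-zero (estimates undefined).
#
# The default engine is compiled (src/cscore_irls.cpp); this pure-R
# reference implements identical arithmetic and backs the cross-check tests.
.cscore_irls <- function(X, s, max_iter = 10L, tol = 1e-6) {
  .cscore_irls_cpp(X, as.numeric(s), as.integer(max_iter), tol)
}

.cscore_irls_r <- function(X, s, max_iter = 10L, tol = 1e-6) {
  n <- nrow(X)
  p <- ncol(X)
  s2 <- s^2
  s4 <- s2^2
  mu <- colSums(X) / sum(s)
  zero <- mu <= 0
  M <- outer(s, mu)
  E <- X - M
  sig <- pmax(colSums(s2 * (E^2 - M)) / sum(s4), 0)
  sig[zero] <- 0
  converged <- FALSE
  it <- 0L
  W <- NULL
  for (it in seq_len(max_iter)) {
    V <- M + outer(s2, sig)
    if (any(zero)) V[, zero] <- 1 # placeholder; excluded from results
    W <- 1 / V
    Ws <- W * s
    mu_new <- colSums(Ws * X) / colSums(Ws * s)
    mu_new[zero] <- 0
    M <- outer(s, mu_new)
    E <- X - M
    W2 <- W * W
    sig_new <- pmax(colSums(W2 * s2 * (E^2 - M)) / colSums(W2 * s4), 0)
    sig_new[zero] <- 0
    delta <- max(abs(mu_new - mu), abs(sig_new - sig))
    mu <- mu_new
    sig <- sig_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # final weights from the converged (mu, sigma_diag)
  V <- M + outer(s2, sig)
  if (any(zero)) V[, zero] <- 1
  W <- 1 / V
  B <- W * E * s        # crossprod(B)[j,j'] = sum_i s^2 g_ijj' xi_ijj'
  C <- W * s2           # crossprod(C)[j,j'] = sum_i s^4 g_ijj'
  list(mu = mu, sig = sig, num = crossprod(B), den = crossprod(C),
       n_iter = it, converged = converged, zero = zero)
}

# Correlation matrix only (fast path used inside permutation loops).
.cscore_rho <- function(X, s, max_iter = 10L, tol = 1e-6) {
  f <- .cscore_irls(X, s, max_iter, tol)
  Sig <- f$num / f$den
  diag(Sig) <- f$sig
  d <- f$sig
  ok <- d > 0 & !f$zero
  R <- Sig / sqrt(outer(d, d))
  R[R > 1] <- 1
  R[R < -1] <- -1
  R[!ok, ] <- NA_real_
  R[, !ok] <- NA_real_
  diag(R)[ok] <- 1
  dimnames(R) <- dimnames(X)[c(2, 2)]
  R
}

#' Fit the Poisson measurement-model co-expression estimator
#'
#' Estimates per-gene mean relative expression `mu`, per-gene biological
#' overdispersion `sigma_jj`, and all pairwise covariances / correlations of
#' the latent expression levels from raw UMI counts, accounting for per-cell
#' sequencing depth. Estimation is moment-based weighted least squares,
#' iterated (IRLS): weights are refreshed from the current estimates each
#' pass until the maximum absolute change in `(mu, sigma_jj)` falls below
#' `tol` or `max_iter` passes are reached. A per-pair independence test
#' statistic (standard normal under the null that the two latent expression
#' levels are independent) and its two-sided p-value are also returned.
#'
#' Genes with zero counts in every cell have undefined correlations and are
#' reported as `NA` throughout (never as zero correlation). Genes whose
#' overdispersion estimate is floored at 0 likewise get `NA` correlations.
#'
#' @param cm A [count_matrix()]; depths are computed on all its genes.
#' @param genes Optional gene ids (or indices) restricting the fit; depths
#'   still come from the full matrix.
#' @param max_iter Maximum IRLS passes (default 10).
#' @param tol Convergence tolerance on `(mu, sigma_jj)` (default 1e-6).
#' @param depths Optional precomputed depth vector (cells order).
#' @return Object of class `cscore_fit` with elements `genes`, `depths`,
#'   `mu`, `sigma_diag`, `sigma`, `rho`, `tstat`, `pval`, `n_iter`,
#'   `converged`.
#' @examples
#' sim <- simulate_counts(simulation_spec(n_genes = 30,
#'                                        n_cells_per_condition = 200,
#'                                        n_correlated_pairs = 5, seed = 1))
#' fit <- fit_cscore(sim$cm_corr)
#' fit
#' head(coef(fit))
#' @export
fit_cscore <- function(cm, genes = NULL, max_iter = 10L, tol = 1e-6,
                       depths = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(depths)) depths <- estimate_depths(cm)
  if (is.null(genes)) genes <- cm$gene_ids
  if (is.numeric(genes)) genes <- cm$gene_ids[genes]
  if (length(genes) < 2) stop("need at least 2 genes")
  gi <- match(genes, cm$gene_ids)
  if (anyNA(gi)) stop("unknown gene id(s): ",
                      paste(utils::head(genes[is.na(gi)], 5), collapse = ", "))
  X <- cm$counts[, gi, drop = FALSE]
  s <- as.numeric(depths)
  f <- .cscore_irls(X, s, max_iter, tol)
  p <- length(genes)
  Sig <- f$num / f$den
  diag(Sig) <- f$sig
  Tm <- f$num / sqrt(f$den)
  d <- f$sig
  ok <- d > 0 & !f$zero
  R <- Sig / sqrt(outer(d, d))
  R[R > 1] <- 1
  R[R < -1] <- -1
  R[!ok, ] <- NA_real_
  R[, !ok] <- NA_real_
  diag(R)[ok] <- 1
  und <- f$zero
  if (any(und)) {
    Sig[und, ] <- NA_real_
    Sig[, und] <- NA_real_
    Tm[und, ] <- NA_real_
    Tm[, und] <- NA_real_
  }
  P <- 2 * stats::pnorm(-abs(Tm))
  P[P < .Machine$double.xmin] <- .Machine$double.xmin
  diag(Tm) <- NA_real_
  diag(P) <- NA_real_
  dn <- list(genes, genes)
  dimnames(Sig) <- dimnames(R) <- dimnames(Tm) <- dimnames(P) <- dn
  structure(list(genes = genes,
                 depths = stats::setNames(s, cm$cell_ids),
                 mu = stats::setNames(f$mu, genes),
                 sigma_diag = stats::setNames(f$sig, genes),
                 sigma = Sig, rho = R, tstat = Tm, pval = P,
                 n_iter = f$n_iter, converged = f$converged),
            class = "cscore_fit")
}

#' Extract the latent-expression correlation matrix from a fit
#'
#' `r_jj' = sigma_jj' / sqrt(sigma_jj sigma_j'j')`, clipped into `[-1, 1]`;
#' entries involving a gene with zero estimated overdispersion are `NA`.
#'
#' @param fit A `cscore_fit`.
#' @return Symmetric correlation matrix with unit diagonal where defined.
#' @export
cscore_correlations <- function(fit) {
  stopifnot(inherits(fit, "cscore_fit"))
  fit$rho
}

#' Per-pair independence test statistics and p-values
#'
#' The statistic divides the estimated covariance by its weighted
#' least-squares standard error; it is standard normal under the null that
#' the pair's latent expression levels are independent, so the p-value is the
#' two-sided normal tail.
#'
#' @param fit A `cscore_fit`.
#' @return List with symmetric matrices `tstat` and `pval`.
#' @export
coexpression_test <- function(fit) {
  stopifnot(inherits(fit, "cscore_fit"))
  list(tstat = fit$tstat, pval = fit$pval)
}

#' @export
coef.cscore_fit <- function(object, ...) {
  data.frame(gene = object$genes, mu = unname(object$mu),
             sigma_jj = unname(object$sigma_diag))
}

#' @export
print.cscore_fit <- function(x, ...) {
  p <- length(x$genes)
  cat("Poisson measurement-model co-expression fit\n")
  cat(sprintf("  %d genes, %d cells; IRLS %d pass(es), %s\n", p,
              length(x$depths), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  r <- x$rho[upper.tri(x$rho)]
  cat(sprintf("  correlations: %d pairs, %d undefined, median |r| = %.3f\n",
              length(r), sum(is.na(r)),
              stats::median(abs(r), na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cscore_fit <- function(object, ...) {
  r <- object$rho[upper.tri(object$rho)]
  pv <- object$pval[upper.tri(object$pval)]
  out <- list(n_genes = length(object$genes),
              n_cells = length(object$depths),
              mu_quartiles = stats::quantile(object$mu, c(.25, .5, .75)),
              frac_sig_floored = mean(object$sigma_diag == 0),
              n_pairs = length(r),
              n_undefined = sum(is.na(r)),
              frac_pairs_p05 = mean(pv < 0.05, na.rm = TRUE),
              converged = object$converged)
  class(out) <- "summary.cscore_fit"
  out
}

#' @export
print.summary.cscore_fit <- function(x, ...) {
  cat(sprintf("cscore fit: %d genes x %d cells (%d pairs)\n", x$n_genes,
              x$n_cells, x$n_pairs))
  cat(sprintf("  mu quartiles: %.4g / %.4g / %.4g\n",
              x$mu_quartiles[1], x$mu_quartiles[2], x$mu_quartiles[3]))
  cat(sprintf("  sigma_jj floored at 0: %.1f%% of genes\n",
              100 * x$frac_sig_floored))
  cat(sprintf("  undefined pairs: %d; pairs with p < 0.05: %.1f%%\n",
              x$n_undefined, 100 * x$frac_pairs_p05))
  invisible(x)
}

#' Export pairwise fit results as a long-format table
#'
#' @param fit A `cscore_fit`.
#' @param path Optional TSV output path; when `NULL` the data.frame is
#'   returned only.
#' @return data.frame with columns `gene_a`, `gene_b`, `r`, `T`, `p`
#'   (each unordered pair once, `gene_a` before `gene_b` in fit order).
#' @export
export_pairs <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cscore_fit"))
  ut <- upper.tri(fit$rho)
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(gene_a = fit$genes[idx[, 1]], gene_b = fit$genes[idx[, 2]],
                   r = fit$rho[ut], T = fit$tstat[ut], p = fit$pval[ut])
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
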