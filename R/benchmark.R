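#' Confusion metrics of pathway calls against truth labels
#'
#' A pathway is called differentially co-expressed when its BH-adjusted
#' p-value is below `alpha`. Sensitivity = TP/(TP+FN), false positive rate =
#' FP/(FP+TN), precision = TP/(TP+FP) (reported as `NA` when nothing is
#' called), accuracy = (TP+TN)/(TP+TN+FP+FN).
#'
#' @param results data.frame with columns `pathway`, `method`, `pvalue_adj`
#'   (e.g. a [run_pathway_scan()] result or several rbind-ed together).
#' @param truth Named vector of `"positive"`/`"negative"` labels keyed by
#'   pathway name (ambiguous sets must be excluded upstream).
#' @param alpha Calling threshold on the adjusted p-value (default 0.05).
#' @return data.frame, one row per method: `method`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `fpr`, `precision`, `accuracy`.
#' @export
confusion_metrics <- function(results, truth, alpha = 0.05) {
  results <- as.data.frame(results)
  results <- results[results$pathway %in% names(truth), , drop = FALSE]
  if (nrow(results) == 0) stop("no labeled pathways in results")
  lab <- truth[results$pathway]
  stopifnot(all(lab %in% c("positive", "negative")))
  called <- !is.na(results$pvalue_adj) & results$pvalue_adj < alpha
  out <- lapply(split(seq_len(nrow(results)), results$method), function(ii) {
    pos <- lab[ii] == "positive"
    cl <- called[ii]
    tp <- sum(pos & cl); fp <- sum(!pos & cl)
    fn <- sum(pos & !cl); tn <- sum(!pos & !cl)
    data.frame(method = results$method[ii[1]], tp = tp, fp = fp, tn = tn,
               fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               accuracy = (tp + tn) / (tp + tn + fp + fn))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank-based ROC AUC of pathway scores against truth labels
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' pathway outranks a randomly chosen negative one, with ties counted one
#' half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores, higher = more differential (the benchmark
#'   uses `-log10` p-values).
#' @param truth `"positive"`/`"negative"` labels parallel to `scores` (or
#'   named, matched by name).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  if (!is.null(names(scores)) && !is.null(names(truth)))
    truth <- truth[names(scores)]
  stopifnot(length(scores) == length(truth),
            all(truth %in% c("positive", "negative")))
  pos <- truth == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both positive and negative pathways are required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run the full simulated pathway-detection benchmark
#'
#' Simulates paired datasets with and without co-expression
#' ([simulate_counts()]), builds labeled pathways across sizes and
#' correlated-gene fractions ([build_pathways()]), optionally applies
#' dropout / multiplicative-noise corruption to both datasets symmetrically,
#' then scans the pathway collection with each requested method treating
#' "co-expression maintained" vs "co-expression removed" as the two
#' conditions, and scores calls (confusion metrics at BH-adjusted
#' `p < alpha`) and rankings (ROC AUC of `-log10 p`). Ambiguous pathways are
#' excluded from both metrics and AUC. A pathway a method cannot test (too
#' few genes with defined correlations, e.g. under extreme corruption)
#' counts as not detected: it enters the confusion metrics uncalled and the
#' ROC ranking with the lowest possible score.
#'
#' @param spec A [simulation_spec()]; its `seed`, corruption fields and
#'   pathway sizes define the run.
#' @param methods Character subset of
#'   `c("gsncascr", "gsnca_pearson", "gsca")`.
#' @param n_perm Permutations per pathway (default 200).
#' @param alpha Calling threshold (default 0.05).
#' @param fractions Correlated-gene fractions spanning 0-1 used at every
#'   pathway size (default `c(0, 0.1, 0.5, 0.6, 0.8, 1)`), rounded to a
#'   feasible pair count per size.
#' @param pvalue_mode Passed to [permutation_test()].
#' @return List of class `benchmark_result`: `per_pathway` (long
#'   data.frame), `metrics` (per-method confusion metrics + `auc`),
#'   `truth_label`, `alpha`, `spec`, `seed`.
#' @export
run_benchmark <- function(spec, methods = c("gsncascr", "gsnca_pearson",
                                            "gsca"),
                          n_perm = 200L, alpha = 0.05,
                          fractions = c(0, 0.1, 0.5, 0.6, 0.8, 1),
                          pvalue_mode = "normal_approx") {
  stopifnot(inherits(spec, "simulation_spec"),
            all(methods %in% c("gsncascr", "gsnca_pearson", "gsca")))
  sim <- simulate_counts(spec)
  counts <- lapply(fractions, function(f)
    as.integer(round(f * spec$pathway_sizes / 2)))
  corr_counts <- lapply(seq_along(spec$pathway_sizes), function(k)
    unique(vapply(counts, `[[`, integer(1), k)))
  sets <- build_pathways(sim$truth, spec$pathway_sizes, corr_counts,
                         all_genes = sim$truth$gene_ids,
                         positive_cutoff = spec$positive_cutoff,
                         negative_cutoff = spec$negative_cutoff,
                         seed = .derive_seed(spec$seed, 5))
  cm_corr <- sim$cm_corr
  cm_indep <- sim$cm_indep
  if (spec$dropout_fraction > 0) {
    cm_corr <- corrupt_dropout(cm_corr, spec$dropout_fraction,
                               seed = .derive_seed(spec$seed, 6))
    cm_indep <- corrupt_dropout(cm_indep, spec$dropout_fraction,
                                seed = .derive_seed(spec$seed, 7))
  }
  if (spec$noise_prob > 0) {
    cm_corr <- corrupt_noise(cm_corr, spec$noise_prob,
                             seed = .derive_seed(spec$seed, 8))
    cm_indep <- corrupt_noise(cm_indep, spec$noise_prob,
                              seed = .derive_seed(spec$seed, 9))
  }
  cm <- count_matrix(rbind(cm_corr$counts, cm_indep$counts),
                     cell_ids = c(cm_corr$cell_ids, cm_indep$cell_ids),
                     gene_ids = cm_corr$gene_ids,
                     condition = rep(c("cond1", "cond2"),
                                     c(length(cm_corr$cell_ids),
                                       length(cm_indep$cell_ids))))
  tl <- attr(sets, "truth_label")
  labeled <- names(sets)[tl != "ambiguous"]
  truth <- tl[labeled]
  per_pathway <- list()
  metrics <- list()
  for (m in methods) {
    scan <- run_pathway_scan(cm, sets, method = m, n_perm = n_perm,
                             seed = spec$seed, alpha = alpha,
                             pvalue_mode = pvalue_mode)
    df <- as.data.frame(scan)
    skipped <- setdiff(names(sets), df$pathway)
    if (length(skipped) > 0) {
      pad <- df[rep(NA_integer_, length(skipped)), , drop = FALSE]
      pad$pathway <- skipped
      pad$method <- m
      pad$seed <- spec$seed
      df <- rbind(df, pad)
    }
    df$truth_label <- unname(tl[df$pathway])
    df$called <- !is.na(df$pvalue_adj) & df$pvalue_adj < alpha
    per_pathway[[m]] <- df
    lab_df <- df[df$pathway %in% labeled, , drop = FALSE]
    cmx <- confusion_metrics(lab_df, truth, alpha = alpha)
    score <- -log10(lab_df$pvalue)
    score[is.na(score)] <- -Inf # untestable = never detected
    cmx$auc <- roc_auc(stats::setNames(score, lab_df$pathway), truth)
    metrics[[m]] <- cmx
  }
  structure(list(per_pathway = do.call(rbind, per_pathway),
                 metrics = do.call(rbind, metrics),
                 truth_label = tl, alpha = alpha, spec = spec,
                 seed = spec$seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  tl <- x$truth_label
  cat(sprintf(paste0("Pathway-detection benchmark (seed %d): %d pathways ",
                     "(%d positive, %d negative, %d ambiguous)\n"),
              x$seed, length(tl), sum(tl == "positive"),
              sum(tl == "negative"), sum(tl == "ambiguous")))
  if (x$spec$dropout_fraction > 0 || x$spec$noise_prob > 0)
    cat(sprintf("  corruption: dropout to %.2f zeros, noise prob %.2f\n",
                x$spec$dropout_fraction, x$spec$noise_prob))
  rownames(x$metrics) <- NULL
  print.data.frame(x$metrics, digits = 3)
  invisible(x)
}

#' Replicate a benchmark over several seeds and average its metrics
#'
#' Runs [run_benchmark()] once per seed (all other spec fields shared) and
#' returns the per-seed metric tables plus their per-method means. This is
#' the harness used for the package's headline simulation experiment:
#' correlation-preserving vs correlation-destroying datasets, pathways of
#' sizes 20-100 spanning correlated-gene fractions 0-1, positive/negative
#' labels at the 0.4/0.2 fraction cutoffs.
#'
#' @param seeds Integer vector of simulation seeds (one benchmark each).
#' @param spec_fields Named list of [simulation_spec()] overrides applied to
#'   every seed (the seed field is supplied per replicate).
#' @param methods,n_perm,alpha,fractions,pvalue_mode As [run_benchmark()].
#' @return List of class `benchmark_replicates`: `per_seed` (list of
#'   `benchmark_result`), `metrics` (long data.frame with a `seed` column),
#'   `mean_metrics` (per-method means over seeds).
#' @export
run_benchmark_replicates <- function(seeds, spec_fields = list(),
                                     methods = c("gsncascr",
                                                 "gsnca_pearson", "gsca"),
                                     n_perm = 200L, alpha = 0.05,
                                     fractions = c(0, 0.1, 0.5, 0.6, 0.8, 1),
                                     pvalue_mode = "normal_approx") {
  per_seed <- lapply(seeds, function(sd) {
    spec <- do.call(simulation_spec, c(spec_fields, list(seed = sd)))
    run_benchmark(spec, methods = methods, n_perm = n_perm, alpha = alpha,
                  fractions = fractions, pvalue_mode = pvalue_mode)
  })
  names(per_seed) <- as.character(seeds)
  metrics <- do.call(rbind, lapply(seq_along(seeds), function(k) {
    m <- per_seed[[k]]$metrics
    m$seed <- seeds[k]
    m
  }))
  rownames(metrics) <- NULL
  num_cols <- c("sensitivity", "fpr", "precision", "accuracy", "auc")
  mean_metrics <- do.call(rbind, lapply(split(metrics, metrics$method),
                                        function(d) {
    out <- data.frame(method = d$method[1])
    for (cl in num_cols) out[[cl]] <- mean(d[[cl]], na.rm = TRUE)
    out
  }))
  rownames(mean_metrics) <- NULL
  structure(list(per_seed = per_seed, metrics = metrics,
                 mean_metrics = mean_metrics, seeds = seeds),
            class = "benchmark_replicates")
}

#' @export
print.benchmark_replicates <- function(x, ...) {
  cat("Benchmark over seeds:", paste(x$seeds, collapse = ", "), "\n")
  cat("Per-method means:\n")
  print.data.frame(x$mean_metrics, digits = 3)
  invisible(x)
}
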