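#' Rank genes by weighted node connectivity in condition and differential
#' co-expression networks
#'
#' Weighted node connectivity (WNC) of gene `i` in a condition network is the
#' sum of absolute correlations to all other genes, `sum_{j != i} |r_ij|`.
#' In the differential network the edge weight is the absolute correlation
#' difference `|r1_ij - r2_ij|`, and only edges whose difference exceeds
#' `edge_threshold` are retained (the condition networks are never
#' thresholded). The unthresholded differential sum is also reported
#' (`wnc_diff_raw`).
#'
#' @param r1,r2 Symmetric correlation matrices over the same gene list
#'   (condition 1 and condition 2).
#' @param edge_threshold Differential-network edge retention threshold
#'   (strict `>`; default 0.2).
#' @return data.frame of class `hub_table` with columns `gene`, `wnc_cond1`,
#'   `wnc_cond2`, `wnc_diff`, `wnc_diff_raw`, ordered by `wnc_diff`
#'   descending with ties broken by gene id; `edge_threshold` stored as an
#'   attribute.
#' @export
wnc_scores <- function(r1, r2, edge_threshold = 0.2) {
  .check_pair_matrices(r1, r2)
  genes <- rownames(r1)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(r1)))
  a1 <- abs(r1); diag(a1) <- 0
  a2 <- abs(r2); diag(a2) <- 0
  d <- abs(r1 - r2); diag(d) <- 0
  out <- data.frame(gene = genes,
                    wnc_cond1 = rowSums(a1),
                    wnc_cond2 = rowSums(a2),
                    wnc_diff = rowSums(d * (d > edge_threshold)),
                    wnc_diff_raw = rowSums(d))
  out <- out[order(-out$wnc_diff, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hub_table", "data.frame"),
            edge_threshold = edge_threshold)
}

#' Export differential-network edges as a long-format table
#'
#' Emits each unordered gene pair whose absolute correlation difference
#' exceeds `edge_threshold` once, with `gene_a` before `gene_b`
#' lexicographically.
#'
#' @inheritParams wnc_scores
#' @param path Optional TSV output path.
#' @return data.frame with columns `gene_a`, `gene_b`, `r1`, `r2`, `diff`.
#' @export
export_edges <- function(r1, r2, edge_threshold = 0.2, path = NULL) {
  .check_pair_matrices(r1, r2)
  genes <- rownames(r1)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(r1)))
  ut <- which(upper.tri(r1), arr.ind = TRUE)
  d <- (r1 - r2)[upper.tri(r1)]
  keep <- which(abs(d) > edge_threshold)
  ga <- genes[ut[keep, 1]]
  gb <- genes[ut[keep, 2]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  df <- data.frame(gene_a = ga, gene_b = gb,
                   r1 = r1[upper.tri(r1)][keep],
                   r2 = r2[upper.tri(r2)][keep],
                   diff = d[keep])
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

.check_pair_matrices <- function(r1, r2) {
  if (!identical(dim(r1), dim(r2)) || !identical(rownames(r1), rownames(r2)))
    stop("correlation matrices do not match")
  if (!isSymmetric(unname(r1), tol = 1e-8) ||
      !isSymmetric(unname(r2), tol = 1e-8))
    stop("correlation matrices must be symmetric (tolerance 1e-8)")
}

#' @export
print.hub_table <- function(x, ...) {
  cat(sprintf("Hub gene ranking (%d genes, differential edge threshold %g)\n",
              nrow(x), attr(x, "edge_threshold")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}
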