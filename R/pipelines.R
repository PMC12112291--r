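#' Pathway differential co-expression pipeline over files
#'
#' Reads counts, labels and a GMT collection, size-filters the collection
#' against the measured genes, balances the conditions, scans every pathway
#' and writes the result table plus a small run log into `out_dir`.
#'
#' @param counts Count matrix file (.mtx or delimited).
#' @param format `"mtx"` or `"csv"`.
#' @param genes_path,cells_path Sidecar id files (mtx).
#' @param genes_as_rows On-disk orientation.
#' @param labels Two-column TSV `cell_id<TAB>condition`.
#' @param gmt GMT gene-set file.
#' @param method,n_perm,alpha,seed As [run_pathway_scan()].
#' @param min_size,max_size Pathway size filter bounds (defaults 40, 1000).
#' @param out_dir Output directory (created; refuses to overwrite an
#'   existing run manifest).
#' @return The `pathway_scan` result, invisibly; writes
#'   `pathway_results.tsv` and `run_log.txt`.
#' @export
dcx_test <- function(counts, labels, gmt, format = c("mtx", "csv"),
                     genes_path = NULL, cells_path = NULL,
                     genes_as_rows = TRUE, method = "gsncascr",
                     n_perm = 500L, alpha = 0.05, seed = 1L,
                     min_size = 40L, max_size = 1000L, out_dir = ".") {
  format <- match.arg(format)
  cm <- read_counts(counts, format = format, genes_as_rows = genes_as_rows,
                    genes_path = genes_path, cells_path = cells_path)
  cm <- attach_condition(cm, read_labels(labels))
  col <- read_gmt(gmt)
  col <- filter_genesets(col, cm$gene_ids, min_size = min_size,
                         max_size = max_size)
  if (length(col) == 0) stop("no gene sets pass the size filter")
  scan <- run_pathway_scan(cm, col, method = method, n_perm = n_perm,
                           seed = seed, alpha = alpha)
  .ensure_run_dir(out_dir)
  write_pathway_scan(scan, file.path(out_dir, "pathway_results.tsv"))
  nc <- attr(scan, "n_cells_per_condition")
  log_lines <- c(
    sprintf("method: %s", method),
    sprintf("seed: %d", seed),
    sprintf("cells per condition: %s",
            paste(names(nc), nc, sep = "=", collapse = ", ")),
    sprintf("sets tested: %d", nrow(scan)),
    sprintf("sets skipped: %d", length(attr(scan, "skipped"))),
    if (length(attr(scan, "skipped")) > 0)
      paste0("  skipped ", names(attr(scan, "skipped")), ": ",
             attr(scan, "skipped")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(scan)
}

#' Hub-gene ranking pipeline over files
#'
#' Fits the co-expression estimator per condition on one pathway's genes and
#' writes the weighted-node-connectivity hub table and the thresholded
#' differential edge list.
#'
#' @inheritParams dcx_test
#' @param set_name Name of the pathway in `gmt` to analyze.
#' @param edge_threshold Differential edge retention threshold (default 0.2).
#' @param balance_seed Seed for cell balancing.
#' @return The `hub_table`, invisibly; writes `hub_table.tsv` and
#'   `edges.tsv`.
#' @export
dcx_hubs <- function(counts, labels, gmt, set_name, format = c("mtx", "csv"),
                     genes_path = NULL, cells_path = NULL,
                     genes_as_rows = TRUE, edge_threshold = 0.2,
                     balance_seed = 1L, out_dir = ".") {
  format <- match.arg(format)
  cm <- read_counts(counts, format = format, genes_as_rows = genes_as_rows,
                    genes_path = genes_path, cells_path = cells_path)
  cm <- attach_condition(cm, read_labels(labels))
  col <- read_gmt(gmt)
  if (!set_name %in% names(col))
    stop("set '", set_name, "' not found in ", gmt)
  genes <- intersect(col[[set_name]], cm$gene_ids)
  if (length(genes) < 3) stop("fewer than 3 measured genes in set")
  bal <- balance_cells(cm, seed = balance_seed)
  depths <- estimate_depths(bal)
  levs <- levels(bal$condition)
  fits <- lapply(levs, function(lv) {
    sub <- subset_cells(bal, cells = which(bal$condition == lv))
    fit_cscore(sub, genes = genes, depths = depths[bal$condition == lv])
  })
  r1 <- cscore_correlations(fits[[1]])
  r2 <- cscore_correlations(fits[[2]])
  ok <- !apply(is.na(r1), 1, any) & !apply(is.na(r2), 1, any)
  r1 <- r1[ok, ok, drop = FALSE]
  r2 <- r2[ok, ok, drop = FALSE]
  hub <- wnc_scores(r1, r2, edge_threshold = edge_threshold)
  .ensure_run_dir(out_dir)
  utils::write.table(as.data.frame(hub), file.path(out_dir, "hub_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_edges(r1, r2, edge_threshold = edge_threshold,
               path = file.path(out_dir, "edges.tsv"))
  invisible(hub)
}

#' Simulation pipeline over files
#'
#' Runs [simulate_counts()] and [build_pathways()] and writes the two count
#' matrices as MTX bundles, the pathway collection as GMT, the truth labels
#' as TSV and the generating parameters plus config as JSON.
#'
#' @param spec A [simulation_spec()] (or path to a JSON file of its fields).
#' @param fractions Correlated-gene fractions per size (as
#'   [run_benchmark()]).
#' @param out_dir Output directory.
#' @return Invisibly, the simulation list.
#' @export
dcx_simulate <- function(spec, fractions = c(0, 0.1, 0.5, 0.6, 0.8, 1),
                         out_dir = ".") {
  spec <- .load_spec(spec)
  sim <- simulate_counts(spec)
  corr_counts <- lapply(spec$pathway_sizes, function(sz)
    unique(as.integer(round(fractions * sz / 2))))
  sets <- build_pathways(sim$truth, spec$pathway_sizes, corr_counts,
                         all_genes = sim$truth$gene_ids,
                         positive_cutoff = spec$positive_cutoff,
                         negative_cutoff = spec$negative_cutoff,
                         seed = .derive_seed(spec$seed, 5))
  .ensure_run_dir(out_dir)
  for (nm in c("cm_corr", "cm_indep")) {
    write_counts(sim[[nm]], file.path(out_dir, paste0(nm, ".mtx")),
                 format = "mtx", genes_as_rows = TRUE,
                 genes_path = file.path(out_dir, paste0(nm, "_genes.txt")),
                 cells_path = file.path(out_dir, paste0(nm, "_cells.txt")))
  }
  write_gmt(sets, file.path(out_dir, "pathways.gmt"))
  tl <- attr(sets, "truth_label")
  utils::write.table(data.frame(pathway = names(sets),
                                truth_label = unname(tl)),
                     file.path(out_dir, "truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(spec = unclass(spec),
                            truth = list(mu = sim$truth$mu,
                                         sigma_diag = sim$truth$sigma_diag,
                                         pairs = sim$truth$pairs,
                                         block_corr = sim$truth$block_corr,
                                         seed = sim$truth$seed)),
                       file.path(out_dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, sets = sets))
}

#' Benchmark pipeline over files
#'
#' Runs [run_benchmark()] and writes the per-pathway table (TSV) and the
#' metrics report (JSON, including the spec and seed for regeneration).
#'
#' @inheritParams dcx_simulate
#' @param methods,n_perm,alpha As [run_benchmark()].
#' @return Invisibly, the `benchmark_result`.
#' @export
dcx_benchmark <- function(spec, methods = c("gsncascr", "gsnca_pearson",
                                            "gsca"),
                          n_perm = 200L, alpha = 0.05,
                          fractions = c(0, 0.1, 0.5, 0.6, 0.8, 1),
                          out_dir = ".") {
  spec <- .load_spec(spec)
  bm <- run_benchmark(spec, methods = methods, n_perm = n_perm,
                      alpha = alpha, fractions = fractions)
  .ensure_run_dir(out_dir)
  utils::write.table(bm$per_pathway, file.path(out_dir, "per_pathway.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(metrics = bm$metrics, alpha = bm$alpha,
                            seed = bm$seed, spec = unclass(bm$spec)),
                       file.path(out_dir, "benchmark_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(bm)
}

.load_spec <- function(spec) {
  if (inherits(spec, "simulation_spec")) return(spec)
  if (is.character(spec) && file.exists(spec)) {
    fields <- jsonlite::read_json(spec, simplifyVector = TRUE)
    return(do.call(simulation_spec, fields))
  }
  if (is.list(spec)) return(do.call(simulation_spec, spec))
  stop("spec must be a simulation_spec, a field list, or a JSON path")
}

# Create the run directory; refuse to reuse a directory that already holds a
# manifest from a previous run.
.ensure_run_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- file.path(out_dir, ".dcx_run")
  if (file.exists(manifest))
    stop("output directory ", out_dir,
         " already holds a run; choose a fresh directory")
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), manifest)
  invisible(out_dir)
}
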