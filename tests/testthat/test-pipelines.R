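# End-to-end file pipelines on a small synthetic fixture.

write_fixture <- function(d, n_cells = 60, n_genes = 50, seed = 44) {
  cm <- toy_cm(n_cells, n_genes, mu = 0.02, seed = seed)
  write_counts(cm, file.path(d, "m.mtx"), format = "mtx",
               genes_path = file.path(d, "genes.txt"),
               cells_path = file.path(d, "cells.txt"))
  writeLines(sprintf("%s\t%s", cm$cell_ids,
                     rep(c("case", "ctrl"), length.out = n_cells)),
             file.path(d, "labels.tsv"))
  writeLines(c(paste(c("SET1", "na", cm$gene_ids[1:10]), collapse = "\t"),
               paste(c("SET2", "na", cm$gene_ids[11:25]), collapse = "\t")),
             file.path(d, "sets.gmt"))
  cm
}

test_that("the test pipeline produces the documented table and log", {
  d <- withr::local_tempdir()
  write_fixture(d)
  scan <- dcx_test(counts = file.path(d, "m.mtx"),
                   labels = file.path(d, "labels.tsv"),
                   gmt = file.path(d, "sets.gmt"), format = "mtx",
                   genes_path = file.path(d, "genes.txt"),
                   cells_path = file.path(d, "cells.txt"),
                   method = "gsnca_pearson", n_perm = 30, seed = 7,
                   min_size = 3, max_size = 1000,
                   out_dir = file.path(d, "out1"))
  tsv <- read.delim(file.path(d, "out1", "pathway_results.tsv"))
  expect_equal(nrow(tsv), 2)
  expect_true(all(c("pathway", "method", "n_genes_used", "statistic",
                    "perm_mean", "perm_sd", "n_perm", "pvalue",
                    "pvalue_adj", "shapiro_p", "seed") %in% names(tsv)))
  expect_true(file.exists(file.path(d, "out1", "run_log.txt")))
  # deterministic rerun into a fresh directory
  dcx_test(counts = file.path(d, "m.mtx"),
           labels = file.path(d, "labels.tsv"),
           gmt = file.path(d, "sets.gmt"), format = "mtx",
           genes_path = file.path(d, "genes.txt"),
           cells_path = file.path(d, "cells.txt"),
           method = "gsnca_pearson", n_perm = 30, seed = 7,
           min_size = 3, max_size = 1000,
           out_dir = file.path(d, "out2"))
  expect_identical(readLines(file.path(d, "out1", "pathway_results.tsv")),
                   readLines(file.path(d, "out2", "pathway_results.tsv")))
  # refuses to reuse a run directory
  expect_error(dcx_test(counts = file.path(d, "m.mtx"),
                        labels = file.path(d, "labels.tsv"),
                        gmt = file.path(d, "sets.gmt"), format = "mtx",
                        genes_path = file.path(d, "genes.txt"),
                        cells_path = file.path(d, "cells.txt"),
                        min_size = 3, out_dir = file.path(d, "out1")),
               "already holds a run")
})

test_that("a cell without a label is named in the error", {
  d <- withr::local_tempdir()
  write_fixture(d)
  lab <- readLines(file.path(d, "labels.tsv"))
  writeLines(lab[-5], file.path(d, "labels.tsv"))
  expect_error(
    dcx_test(counts = file.path(d, "m.mtx"),
             labels = file.path(d, "labels.tsv"),
             gmt = file.path(d, "sets.gmt"), format = "mtx",
             genes_path = file.path(d, "genes.txt"),
             cells_path = file.path(d, "cells.txt"),
             min_size = 3, out_dir = file.path(d, "out")),
    "c005")
})

test_that("the hubs pipeline ranks a constructed hub first", {
  d <- withr::local_tempdir()
  spec <- simulation_spec(n_genes = 30, n_cells_per_condition = 500,
                          n_correlated_pairs = 3, block_corr = 0.75,
                          block_corr_jitter = 0, seed = 50)
  sim <- simulate_counts(spec)
  cm <- count_matrix(rbind(sim$cm_corr$counts, sim$cm_indep$counts),
                     cell_ids = c(sim$cm_corr$cell_ids,
                                  sim$cm_indep$cell_ids),
                     gene_ids = sim$cm_corr$gene_ids)
  write_counts(cm, file.path(d, "m.mtx"), format = "mtx",
               genes_path = file.path(d, "genes.txt"),
               cells_path = file.path(d, "cells.txt"))
  writeLines(sprintf("%s\t%s", cm$cell_ids,
                     rep(c("corr", "indep"), each = 500)),
             file.path(d, "labels.tsv"))
  pair_genes <- sim$truth$pairs[1, ]
  set_genes <- unique(c(pair_genes, sim$truth$gene_ids[1:12]))
  writeLines(paste(c("HUBSET", "na", set_genes), collapse = "\t"),
             file.path(d, "sets.gmt"))
  hub <- dcx_hubs(counts = file.path(d, "m.mtx"),
                  labels = file.path(d, "labels.tsv"),
                  gmt = file.path(d, "sets.gmt"), set_name = "HUBSET",
                  format = "mtx", genes_path = file.path(d, "genes.txt"),
                  cells_path = file.path(d, "cells.txt"),
                  edge_threshold = 0.2, out_dir = file.path(d, "hubs"))
  expect_true(all(file.exists(file.path(d, "hubs",
                                        c("hub_table.tsv", "edges.tsv")))))
  # the designated pair genes carry the differential signal
  expect_true(all(hub$gene[1:2] %in% pair_genes))
  edges <- read.delim(file.path(d, "hubs", "edges.tsv"))
  expect_true(nrow(edges) >= 1)
  expect_true(all(abs(edges$diff) > 0.2))
})

test_that("simulate and benchmark pipelines write their file inventories", {
  d <- withr::local_tempdir()
  spec <- simulation_spec(n_genes = 60, n_cells_per_condition = 120,
                          n_correlated_pairs = 15,
                          pathway_sizes = c(10L, 20L), seed = 60)
  dcx_simulate(spec, fractions = c(0, 0.5, 1),
               out_dir = file.path(d, "sim"))
  expect_true(all(file.exists(file.path(d, "sim", c(
    "cm_corr.mtx", "cm_corr_genes.txt", "cm_corr_cells.txt",
    "cm_indep.mtx", "cm_indep_genes.txt", "cm_indep_cells.txt",
    "pathways.gmt", "truth_labels.tsv", "truth_params.json")))))
  tl <- read.delim(file.path(d, "sim", "truth_labels.tsv"))
  expect_true(all(tl$truth_label %in% c("positive", "negative",
                                        "ambiguous")))
  bm <- dcx_benchmark(spec, methods = "gsnca_pearson", n_perm = 30,
                      fractions = c(0, 0.5, 1),
                      out_dir = file.path(d, "bm"))
  rep_json <- jsonlite::read_json(file.path(d, "bm",
                                            "benchmark_report.json"),
                                  simplifyVector = TRUE)
  expect_equal(rep_json$seed, 60)
  expect_true("auc" %in% names(rep_json$metrics))
  expect_true(file.exists(file.path(d, "bm", "per_pathway.tsv")))
})
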