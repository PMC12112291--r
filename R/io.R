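#' Read a UMI count matrix from MatrixMarket or delimited text
#'
#' MatrixMarket input (`format = "mtx"`) expects two one-column sidecar files
#' with gene and cell identifiers whose lengths match the matrix dimensions.
#' Delimited input (`format = "csv"`) expects identifiers in the first row and
#' first column. On-disk orientation is declared with `genes_as_rows`
#' (CellRanger-style MTX is genes x cells); the returned object is always
#' cells x genes.
#'
#' @param path Count matrix file (.mtx or delimited text).
#' @param format `"mtx"` or `"csv"` (the latter also covers TSV via `sep`).
#' @param genes_as_rows Logical; `TRUE` if genes are rows on disk.
#' @param genes_path,cells_path Sidecar id files (mtx only).
#' @param sep Field separator for delimited input.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "csv"), genes_as_rows = TRUE,
                        genes_path = NULL, cells_path = NULL, sep = ",") {
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx input requires genes_path and cells_path sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    cells <- readLines(cells_path)
    cells <- cells[nzchar(cells)]
    n_gene_dim <- if (genes_as_rows) nrow(m) else ncol(m)
    n_cell_dim <- if (genes_as_rows) ncol(m) else nrow(m)
    if (length(genes) != n_gene_dim)
      stop("format error: ", genes_path, " has ", length(genes),
           " ids but matrix has ", n_gene_dim, " genes")
    if (length(cells) != n_cell_dim)
      stop("format error: ", cells_path, " has ", length(cells),
           " ids but matrix has ", n_cell_dim, " cells")
    if (genes_as_rows) m <- t(m)
    dimnames(m) <- list(cells, genes)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (genes_as_rows) m <- t(m)
  }
  count_matrix(m)
}

#' Write a count matrix to MatrixMarket or delimited text
#'
#' Inverse of [read_counts()]; round-trips counts and id order exactly.
#'
#' @param cm A [count_matrix()].
#' @param path Output matrix file.
#' @param format `"mtx"` or `"csv"`.
#' @param genes_as_rows On-disk orientation to write.
#' @param genes_path,cells_path Sidecar id files (mtx only).
#' @param sep Field separator for delimited output.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(cm, path, format = c("mtx", "csv"),
                         genes_as_rows = TRUE,
                         genes_path = NULL, cells_path = NULL, sep = ",") {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  m <- cm$counts
  if (genes_as_rows) m <- t(m)
  if (format == "mtx") {
    if (is.null(genes_path) || is.null(cells_path))
      stop("mtx output requires genes_path and cells_path")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(cm$gene_ids, genes_path)
    writeLines(cm$cell_ids, cells_path)
  } else {
    df <- as.data.frame(m, check.names = FALSE)
    utils::write.table(cbind(id = rownames(m), df), path, sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' GMT is the tab-separated MSigDB exchange format: each line is
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description is
#' discarded; duplicate genes within a line are deduplicated keeping the
#' first occurrence; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return A named list of character vectors (class `gene_set_collection`),
#'   possibly with a `truth_label` attribute (see [build_pathways()]).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  sets <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT parse error at line ", line_no[k], ": fewer than 3 fields")
    name <- fields[1]
    if (name %in% names(sets))
      stop("GMT parse error at line ", line_no[k], ": duplicate set name '",
           name, "'")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[name]] <- genes[!duplicated(genes)]
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene id vectors.
#' @param path Output file.
#' @param descriptions Optional per-set description strings (default "na").
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(k) {
    paste(c(names(sets)[k], descriptions[k], sets[[k]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors; genes within a set must be
#'   unique, set names unique.
#' @param truth_label Optional per-set labels in
#'   `{"positive","negative","ambiguous"}` for benchmarking.
#' @return List of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, truth_label = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("sets must have unique names")
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) stop("duplicate genes in set ", nm)
  }
  if (!is.null(truth_label)) {
    stopifnot(length(truth_label) == length(sets),
              all(truth_label %in% c("positive", "negative", "ambiguous")))
    truth_label <- stats::setNames(truth_label, names(sets))
  }
  structure(sets, class = "gene_set_collection", truth_label = truth_label)
}

#' Size-filter a gene-set collection against the measured genes
#'
#' Each set is first intersected with `measured_genes` (order preserved),
#' then retained iff its post-intersection size lies in
#' `[min_size, max_size]` inclusive. The defaults implement the convention of
#' discarding pathways with fewer than 40 or more than 1000 genes.
#'
#' @param col A `gene_set_collection` (or plain named list).
#' @param measured_genes Character vector of gene ids present in the data.
#' @param min_size,max_size Inclusive size bounds (min_size >= 2).
#' @return A filtered `gene_set_collection`; truth labels are subset along.
#' @export
filter_genesets <- function(col, measured_genes, min_size = 40L,
                            max_size = 1000L) {
  stopifnot(min_size >= 2, max_size >= min_size)
  tl <- attr(col, "truth_label")
  inter <- lapply(col, function(g) g[g %in% measured_genes])
  sizes <- lengths(inter)
  keep <- sizes >= min_size & sizes <= max_size
  out <- inter[keep]
  gene_set_collection(out, truth_label = if (!is.null(tl)) unname(tl[keep]))
}

#' Read a two-column cell label table
#'
#' @param path TSV with columns `cell_id<TAB>condition` (header optional,
#'   detected by whether the first field matches a known id pattern is NOT
#'   attempted; a header line named `cell_id` is skipped).
#' @return Named character vector of conditions keyed by cell id.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2) stop("label table must have two tab-separated columns")
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(df[[2]], df[[1]])
}
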