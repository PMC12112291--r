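#' Construct a UMI count matrix container
#'
#' Bundles an integer UMI count matrix (cells in rows, genes in columns) with
#' its cell and gene identifiers and, optionally, a two-level per-cell
#' condition label. All downstream estimation assumes this orientation.
#'
#' @param counts Non-negative integer matrix, cells x genes. A
#'   `Matrix::sparseMatrix` is densified.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#'   Defaults to rownames of `counts`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to colnames of `counts`.
#' @param condition Optional per-cell factor/character with exactly two
#'   levels, or `NULL` if labels are attached later.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (base integer-valued matrix with dimnames), `cell_ids`, `gene_ids`,
#'   `condition` (factor or `NULL`).
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), condition = NULL) {
  if (methods::is(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(counts), ")")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(counts), ")")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or fractional count at [cell ", bad[1, 1], ", gene ",
         bad[1, 2], "]: ", counts[bad[1, 1], bad[1, 2]])
  dimnames(counts) <- list(cell_ids, gene_ids)
  obj <- structure(list(counts = counts, cell_ids = cell_ids,
                        gene_ids = gene_ids, condition = NULL),
                   class = "count_matrix")
  if (!is.null(condition)) obj <- attach_condition(obj, condition)
  obj
}

#' Attach a two-level condition label to a count matrix
#'
#' @param cm A `count_matrix`.
#' @param condition Either a vector of labels in cell order, or a named
#'   vector / two-column data.frame (`cell_id`, `condition`) matched by cell
#'   id. Must resolve to exactly two levels covering every cell.
#' @return The `count_matrix` with `condition` set (a factor).
#' @export
attach_condition <- function(cm, condition) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.data.frame(condition)) {
    condition <- stats::setNames(as.character(condition[[2]]),
                                 as.character(condition[[1]]))
  }
  if (!is.null(names(condition))) {
    missing_cells <- setdiff(cm$cell_ids, names(condition))
    if (length(missing_cells) > 0)
      stop("no condition label for cell(s): ",
           paste(utils::head(missing_cells, 5), collapse = ", "))
    condition <- condition[cm$cell_ids]
  }
  if (length(condition) != length(cm$cell_ids))
    stop("condition length != number of cells")
  condition <- factor(as.character(condition))
  if (anyNA(condition)) stop("missing condition labels")
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels, got ", nlevels(condition))
  cm$condition <- condition
  cm
}

#' Subset a count matrix by cells and/or genes
#'
#' @param cm A `count_matrix`.
#' @param cells,genes Index or id vectors; `NULL` keeps all.
#' @return A `count_matrix`.
#' @export
subset_cells <- function(cm, cells = NULL, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  ci <- if (is.null(cells)) seq_along(cm$cell_ids) else cells
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else genes
  if (is.character(ci)) ci <- match(ci, cm$cell_ids)
  if (is.character(gi)) gi <- match(gi, cm$gene_ids)
  if (anyNA(ci)) stop("unknown cell id(s)")
  if (anyNA(gi)) stop("unknown gene id(s)")
  out <- cm
  out$counts <- cm$counts[ci, gi, drop = FALSE]
  out$cell_ids <- cm$cell_ids[ci]
  out$gene_ids <- cm$gene_ids[gi]
  if (!is.null(cm$condition)) out$condition <- droplevels(cm$condition[ci])
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("UMI count matrix:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes\n")
  nz <- mean(x$counts == 0)
  cat(sprintf("  zero fraction: %.3f, median depth: %.0f\n",
              nz, stats::median(rowSums(x$counts))))
  if (!is.null(x$condition)) {
    tb <- table(x$condition)
    cat("  condition:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  } else {
    cat("  condition: <none attached>\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
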