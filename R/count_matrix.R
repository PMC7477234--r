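#' Construct a validated gene-by-cell count matrix
#'
#' The in-memory container shared by every stage of the workflow. Counts are
#' stored as a sparse non-negative integer matrix with genes in rows and cells
#' (or, after pseudobulk aggregation, samples) in columns. Per-cell metadata
#' (`sample_id`, `group`, `day`, `batch`, optional labels) is keyed by
#' `cell_id`; per-gene metadata carries the display `symbol` and logical
#' `is_mito` / `is_ribo` flags used by the QC fraction filters.
#'
#' The orientation is fixed: genes x cells, matching the on-disk MatrixMarket
#' convention of 10x-style output. All constructors and readers validate that
#' dimensions match the id vectors, ids are unique, counts are integral and
#' non-negative, and every cell id has a metadata row.
#'
#' @param counts matrix or sparse Matrix of non-negative integers, genes x cells.
#' @param gene_meta data.frame with at least `gene_id`; optional `symbol`,
#'   `is_mito`, `is_ribo` (defaults: symbol = gene_id, flags FALSE).
#' @param cell_meta data.frame with at least `cell_id`; optional `sample_id`,
#'   `group`, `day`, `batch` and any label columns.
#' @return An object of class `CountMatrix` (a list with elements `counts`,
#'   `gene_meta`, `cell_meta`).
#' @export
count_matrix <- function(counts, gene_meta = NULL, cell_meta = NULL) {
  if (!inherits(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (!is.numeric(counts@x)) counts <- methods::as(counts, "dMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must carry gene (row) and cell (column) names")
  }
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- character(0)
  cell_ids <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- character(0)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in counts")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in counts")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(gene_meta)) gene_meta <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  if (is.null(cell_meta)) cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(gene_meta)) stop("gene_meta needs a gene_id column")
  if (!"cell_id" %in% names(cell_meta)) stop("cell_meta needs a cell_id column")
  if (!setequal(gene_meta$gene_id, gene_ids) || nrow(gene_meta) != length(gene_ids)) {
    stop("gene_meta does not match the genes of the count matrix")
  }
  if (!setequal(cell_meta$cell_id, cell_ids) || nrow(cell_meta) != length(cell_ids)) {
    stop("cell_meta does not match the cells of the count matrix")
  }
  gene_meta <- gene_meta[match(gene_ids, gene_meta$gene_id), , drop = FALSE]
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(gene_meta) <- NULL
  rownames(cell_meta) <- NULL
  if (!"symbol" %in% names(gene_meta)) gene_meta$symbol <- gene_meta$gene_id
  if (!"is_mito" %in% names(gene_meta)) gene_meta$is_mito <- FALSE
  if (!"is_ribo" %in% names(gene_meta)) gene_meta$is_ribo <- FALSE
  if (anyDuplicated(gene_meta$symbol)) {
    warning("gene symbols are not unique; gene ids remain the primary identity")
  }
  structure(
    list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
    class = "CountMatrix"
  )
}

#' @export
#' @method print CountMatrix
print.CountMatrix <- function(x, ...) {
  cat(sprintf(
    "CountMatrix: %d genes x %d cells (%.2f%% non-zero)\n",
    nrow(x$counts), ncol(x$counts),
    100 * length(x$counts@x) / max(1, prod(dim(x$counts)))
  ))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell_meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param cm CountMatrix.
#' @param genes,cells character vectors of ids (or logical/integer indices).
#' @return CountMatrix restricted to the requested genes/cells, metadata kept
#'   in step.
#' @export
subset_count_matrix <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(cm$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(cm$counts)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(cm$counts))
  if (is.character(ci)) ci <- match(ci, colnames(cm$counts))
  if (anyNA(gi)) stop("unknown gene ids in subset")
  if (anyNA(ci)) stop("unknown cell ids in subset")
  counts <- cm$counts[gi, ci, drop = FALSE]
  count_matrix(
    counts,
    gene_meta = cm$gene_meta[match(rownames(counts), cm$gene_meta$gene_id), , drop = FALSE],
    cell_meta = cm$cell_meta[match(colnames(counts), cm$cell_meta$cell_id), , drop = FALSE]
  )
}

# internal: named per-cell vector from cell_meta
cell_field <- function(cm, field) {
  stats::setNames(cm$cell_meta[[field]], cm$cell_meta$cell_id)
}
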