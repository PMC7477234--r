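#' Read a 10x-style triplet directory into a CountMatrix
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate integer, genes in rows),
#' `barcodes.tsv` (one cell barcode per line) and `features.tsv` (gene id,
#' optionally a symbol column). An optional `cell_meta.tsv` (written by
#' [write_counts_10x()]) supplies sample/group/batch metadata; truth columns
#' emitted by the simulator are prefixed `truth_`.
#'
#' Readers are strict: dimension mismatches between the MatrixMarket header
#' and the tsv line counts, or negative/non-integral values, are hard errors
#' naming the offending file rather than silent coercions.
#'
#' @param path directory containing the triplet.
#' @return CountMatrix with gene and cell order preserved from the files.
#' @export
read_counts_10x <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  bcf <- file.path(path, "barcodes.tsv")
  ftf <- file.path(path, "features.tsv")
  for (f in c(mtx, bcf, ftf)) if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(mtx)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  barcodes <- readLines(bcf)
  if (!length(barcodes)) stop("empty barcodes file: ", bcf)
  features <- utils::read.delim(ftf, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(features)) stop("empty features file: ", ftf)
  if (nrow(m) != nrow(features)) {
    stop(sprintf("matrix.mtx has %d rows but features.tsv has %d lines (%s)",
                 nrow(m), nrow(features), ftf))
  }
  if (ncol(m) != length(barcodes)) {
    stop(sprintf("matrix.mtx has %d columns but barcodes.tsv has %d lines (%s)",
                 ncol(m), length(barcodes), bcf))
  }
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes
  gene_meta <- data.frame(gene_id = features[[1]], stringsAsFactors = FALSE)
  if (ncol(features) >= 2) gene_meta$symbol <- features[[2]]
  if (ncol(features) >= 3) {
    gene_meta$is_mito <- features[[3]] %in% c("mito", "TRUE")
    gene_meta$is_ribo <- features[[3]] %in% c("ribo", "TRUE")
  }
  metaf <- file.path(path, "cell_meta.tsv")
  cell_meta <- NULL
  if (file.exists(metaf)) {
    cell_meta <- utils::read.delim(metaf, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(cell_meta)) stop("cell_meta.tsv lacks a cell_id column: ", metaf)
  }
  count_matrix(m, gene_meta = gene_meta, cell_meta = cell_meta)
}

#' Write a CountMatrix as a 10x-style triplet
#'
#' Emits `matrix.mtx`, `barcodes.tsv`, `features.tsv` (gene id, symbol, and a
#' mito/ribo/none flag column) and `cell_meta.tsv`. Round-trips through
#' [read_counts_10x()] to an equal object.
#'
#' @param cm CountMatrix.
#' @param path output directory (created if missing).
#' @export
write_counts_10x <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(cm$counts, "generalMatrix"), "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(colnames(cm$counts), file.path(path, "barcodes.tsv"))
  flag <- ifelse(cm$gene_meta$is_mito, "mito", ifelse(cm$gene_meta$is_ribo, "ribo", "none"))
  utils::write.table(
    data.frame(cm$gene_meta$gene_id, cm$gene_meta$symbol, flag),
    file.path(path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write_results(cm$cell_meta, file.path(path, "cell_meta.tsv"))
  invisible(path)
}

#' Read a GMT geneset collection
#'
#' One tab-separated line per term: term id, description, then member genes.
#' Duplicate genes within a line are deduplicated; duplicate term ids across
#' lines are an error.
#'
#' @param path GMT file.
#' @param universe optional character vector restricting the gene universe.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors), `names` (term descriptions) and `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields (%s)", bad[1], path))
  }
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in GMT: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(vapply(parts, `[[`, "", 2), ids))
}

#' Construct a geneset collection
#'
#' @param sets named list of character gene vectors (non-empty, unique term ids).
#' @param descriptions optional named character vector of term descriptions.
#' @param universe optional gene universe.
#' @return GeneSetCollection.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) stop("sets must have unique names")
  if (any(lengths(sets) == 0)) stop("genesets must be non-empty")
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  structure(
    list(sets = lapply(sets, unique), names = descriptions, universe = universe),
    class = "GeneSetCollection"
  )
}

#' Write a GeneSetCollection as GMT
#' @param gsc GeneSetCollection.
#' @param path output file.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$names[[id]], gsc$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Stable column order, full float precision (15 significant digits), no
#' quoting, no row names. The standard output format of every stage.
#'
#' @param table data.frame with a non-empty header.
#' @param path output file; the parent directory must exist.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  if (!ncol(table)) stop("results table has no columns")
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  fmt <- table
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      fmt[[j]] <- formatC(fmt[[j]], digits = 15, format = "g")
      fmt[[j]][is.na(table[[j]])] <- "NA"
    }
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_results()]
#' @param path TSV file with a header row.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
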