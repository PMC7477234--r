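#' QC thresholds for single-cell or single-nucleus data
#'
#' Per-cell gene-detection bounds (400-4000 detected genes), a combined
#' mitochondrial + ribosomal UMI-fraction ceiling (20% for single-cell, 5%
#' for single-nucleus) and a minimum number of cells a gene must be detected
#' in (10 for single-cell, 5 for single-nucleus). The mito and ribo UMIs are
#' pooled into a single fraction by default; separate ceilings can be set
#' via `max_mito_fraction` / `max_ribo_fraction`.
#'
#' @param mode "single_cell" or "single_nucleus".
#' @param min_genes,max_genes inclusive detected-gene bounds per cell.
#' @param max_mito_ribo_fraction ceiling on the combined mito+ribo UMI share;
#'   cells strictly above it are discarded.
#' @param min_cells_per_gene genes detected in fewer cells are discarded.
#' @param barcode_fraction fraction of the 99th-percentile top-barcode total
#'   used by [call_barcodes()].
#' @param expected_cells expected number of recovered cells.
#' @param max_mito_fraction,max_ribo_fraction optional separate ceilings.
#' @return QCThresholds list.
#' @export
qc_thresholds <- function(mode = c("single_cell", "single_nucleus"),
                          min_genes = 400, max_genes = 4000,
                          max_mito_ribo_fraction = NULL,
                          min_cells_per_gene = NULL,
                          barcode_fraction = 0.10,
                          expected_cells = 3000,
                          max_mito_fraction = NULL,
                          max_ribo_fraction = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_mito_ribo_fraction)) {
    max_mito_ribo_fraction <- if (mode == "single_cell") 0.20 else 0.05
  }
  if (is.null(min_cells_per_gene)) {
    min_cells_per_gene <- if (mode == "single_cell") 10L else 5L
  }
  stopifnot(min_genes < max_genes,
            max_mito_ribo_fraction > 0, max_mito_ribo_fraction <= 1,
            barcode_fraction > 0, barcode_fraction <= 1)
  structure(list(
    mode = mode, min_genes = min_genes, max_genes = max_genes,
    max_mito_ribo_fraction = max_mito_ribo_fraction,
    min_cells_per_gene = min_cells_per_gene,
    barcode_fraction = barcode_fraction, expected_cells = expected_cells,
    max_mito_fraction = max_mito_fraction, max_ribo_fraction = max_ribo_fraction
  ), class = "QCThresholds")
}

#' Call cell-containing barcodes from UMI totals
#'
#' Keeps barcodes whose total UMI count exceeds `fraction` times the 99th
#' percentile of the top `expected_cells` barcode totals.
#'
#' @param barcode_totals named numeric vector of per-barcode UMI totals.
#' @param expected_cells expected number of recovered cells (>= 1).
#' @param fraction threshold fraction (default 0.10).
#' @return character vector of kept barcodes.
#' @export
call_barcodes <- function(barcode_totals, expected_cells, fraction = 0.10) {
  if (!length(barcode_totals)) stop("no barcodes supplied")
  stopifnot(expected_cells >= 1)
  if (expected_cells > length(barcode_totals)) {
    warning("expected_cells exceeds the number of barcodes; using all barcodes")
    expected_cells <- length(barcode_totals)
  }
  top <- sort(barcode_totals, decreasing = TRUE)[seq_len(expected_cells)]
  threshold <- fraction * stats::quantile(top, 0.99, names = FALSE)
  names(barcode_totals)[barcode_totals > threshold]
}

#' Per-cell QC metrics
#'
#' Detected genes, total UMIs and mito/ribo UMI fractions per cell -- the
#' inputs of the QC filters and the covariates regressed out before PCA.
#'
#' @param cm CountMatrix with `is_mito` / `is_ribo` gene flags.
#' @return data.frame keyed by `cell_id`.
#' @export
qc_cell_metrics <- function(cm) {
  detected <- Matrix::colSums(cm$counts > 0)
  total <- Matrix::colSums(cm$counts)
  mito <- Matrix::colSums(cm$counts[cm$gene_meta$is_mito, , drop = FALSE])
  ribo <- Matrix::colSums(cm$counts[cm$gene_meta$is_ribo, , drop = FALSE])
  data.frame(
    cell_id = colnames(cm$counts), n_genes = as.integer(detected),
    total_umi = as.numeric(total),
    mito_fraction = ifelse(total > 0, mito / total, 0),
    ribo_fraction = ifelse(total > 0, ribo / total, 0),
    mito_ribo_fraction = ifelse(total > 0, (mito + ribo) / total, 0),
    stringsAsFactors = FALSE
  )
}

#' Filter cells then genes by QC thresholds
#'
#' Cells with a detected-gene count outside `[min_genes, max_genes]`
#' (boundaries retained) or with a combined mito+ribo UMI fraction strictly
#' above the mode's ceiling are discarded first; genes detected in fewer than
#' `min_cells_per_gene` of the remaining cells are then discarded. The
#' cell-then-gene order is fixed, and the operation is idempotent.
#'
#' @param cm CountMatrix with `is_mito` / `is_ribo` gene flags.
#' @param thresholds QCThresholds from [qc_thresholds()].
#' @return filtered CountMatrix with a `qc_report` attribute (per-cell
#'   metrics and kept/dropped flags).
#' @export
filter_cells_genes <- function(cm, thresholds) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(thresholds, "QCThresholds"))
  met <- qc_cell_metrics(cm)
  keep <- met$n_genes >= thresholds$min_genes & met$n_genes <= thresholds$max_genes
  if (is.null(thresholds$max_mito_fraction)) {
    keep <- keep & met$mito_ribo_fraction <= thresholds$max_mito_ribo_fraction
  } else {
    keep <- keep & met$mito_fraction <= thresholds$max_mito_fraction &
      met$ribo_fraction <= thresholds$max_ribo_fraction
  }
  met$kept <- keep
  if (!any(keep)) stop("QC removed every cell; check thresholds against the data")
  sub <- cm$counts[, keep, drop = FALSE]
  gene_keep <- Matrix::rowSums(sub > 0) >= thresholds$min_cells_per_gene
  out <- subset_count_matrix(cm, genes = which(gene_keep), cells = which(keep))
  attr(out, "qc_report") <- met
  out
}

#' Library-size log-normalization
#'
#' `log(1 + scale * count / cell_total)`, the fully specified substitute used
#' in place of a variance-stabilizing regression model: downstream statistics
#' consume only a normalized matrix. Zeros stay zero; within a cell the
#' transform is invariant to rescaling all counts by a common factor.
#'
#' @param cm CountMatrix.
#' @param scale library-size scale (default 1e4).
#' @return sparse genes x cells matrix of normalized values.
#' @export
normalize_log <- function(cm, scale = 1e4) {
  totals <- Matrix::colSums(cm$counts)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("zero-total cell(s): ", paste(utils::head(colnames(cm$counts)[zero], 5), collapse = ", "))
  }
  norm <- cm$counts
  norm@x <- log1p(scale * norm@x / rep.int(totals, diff(norm@p)))
  norm
}

#' Select highly variable genes by standardized dispersion
#'
#' Genes are ranked by the z-score of their dispersion (variance / mean of
#' normalized values) within equal-occupancy mean bins (20, fewer when the
#' gene set is small, so every bin keeps at least ~20 genes); ties break by
#' gene id so the selection is deterministic.
#'
#' @param norm normalized genes x cells matrix.
#' @param n_top number of genes to return (default 2000).
#' @param n_bins mean bins used for the dispersion z-score.
#' @return character vector of selected gene ids.
#' @export
select_variable_genes <- function(norm, n_top = 2000, n_bins = 20) {
  n_genes <- nrow(norm)
  if (n_top > n_genes) {
    warning("n_top exceeds the number of genes; returning all genes")
    n_top <- n_genes
  }
  # keep bins populated enough that the within-bin z-score is meaningful
  n_bins <- max(1, min(n_bins, floor(n_genes / 20)))
  mu <- Matrix::rowMeans(norm)
  v <- Matrix::rowMeans(norm^2) - mu^2
  v <- v * ncol(norm) / max(1, ncol(norm) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(norm))
  rownames(norm)[ord][seq_len(n_top)]
}

#' Regress out per-cell covariates and scale
#'
#' Per gene, replaces normalized values with ordinary-least-squares residuals
#' against the supplied covariates (total UMIs, mito/ribo fractions, ...),
#' then centers, scales to unit variance and clips to `+/- clip`. Constant
#' covariate columns are dropped with a warning.
#'
#' @param norm normalized genes x cells matrix (dense or sparse).
#' @param covariates data.frame of per-cell covariates, rows in cell order.
#' @param clip clipping bound after scaling (default 10).
#' @return dense genes x cells matrix of scaled residuals.
#' @export
regress_and_scale <- function(norm, covariates, clip = 10) {
  norm <- as.matrix(norm)
  stopifnot(nrow(covariates) == ncol(norm))
  X <- stats::model.matrix(~., data = as.data.frame(covariates))
  const <- apply(X[, -1, drop = FALSE], 2, function(col) stats::var(col) == 0)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X[, -1, drop = FALSE])[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  qrX <- qr(X)
  resid <- t(qr.resid(qrX, t(norm)))
  s <- apply(resid, 1, stats::sd)
  s[s == 0] <- 1
  scaled <- (resid - rowMeans(resid)) / s
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  dimnames(scaled) <- dimnames(norm)
  scaled
}

#' Principal component embedding
#'
#' Exact singular value decomposition of the cells x genes scaled matrix.
#' Sign convention: the largest-magnitude gene loading of each component is
#' positive, making the decomposition fully deterministic.
#'
#' @param scaled genes x cells scaled matrix (per-gene centered).
#' @param n_pcs number of components (default 30).
#' @return An `Embedding`: list with `cell_ids`, `coordinates`
#'   (cells x n_pcs), `explained_variance`, `loadings` (genes x n_pcs) and
#'   `sdev`.
#' @export
run_pca <- function(scaled, n_pcs = 30) {
  X <- t(as.matrix(scaled))            # cells x genes
  X <- sweep(X, 2, colMeans(X))        # defensive re-centering
  n_pcs_req <- n_pcs
  n_pcs <- min(n_pcs, dim(X))
  if (n_pcs < n_pcs_req) warning("n_pcs truncated to ", n_pcs)
  sv <- svd(X, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  coords <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  rownames(coords) <- colnames(scaled)
  rownames(loadings) <- rownames(scaled)
  colnames(coords) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  structure(list(
    cell_ids = colnames(scaled),
    coordinates = coords,
    explained_variance = sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2),
    loadings = loadings,
    sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(X) - 1))
  ), class = "Embedding")
}

# shared-nearest-neighbor graph from an embedding
snn_graph <- function(coords, k_neighbors) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k_neighbors + 1)]))
  # Jaccard overlap of neighbor sets (including self) between kNN pairs
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors),
    j = as.vector(t(nn)), x = 1, dims = c(n, n)
  )
  adj <- adj + Matrix::Diagonal(n)
  shared <- Matrix::tcrossprod(adj)
  sizes <- Matrix::rowSums(adj)
  edges <- which(as.matrix(shared > 0), arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  s <- shared[edges]
  jac <- as.numeric(s) / (sizes[edges[, 1]] + sizes[edges[, 2]] - as.numeric(s))
  keep <- jac > 1 / 15   # prune spurious overlaps, Seurat-style
  igraph::graph_from_data_frame(
    data.frame(from = edges[keep, 1], to = edges[keep, 2], weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbor graph in embedding space (Euclidean), weights
#' edges by the Jaccard overlap of shared neighbors, and partitions it by
#' modularity (Louvain) at the given resolution. Deterministic under a fixed
#' seed.
#'
#' @param embedding Embedding from [run_pca()] (or any cells x d matrix).
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution (default 0.1).
#' @param seed integer seed.
#' @return `ClusterLabels`: list with `cluster` (named integer vector, dense
#'   ids from 0), `resolution`, `k_neighbors`.
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 0.1, seed = 1L) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coordinates else as.matrix(embedding)
  n <- nrow(coords)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  g <- snn_graph(coords, k_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  # dense ids from 0, ordered by decreasing cluster size (stable tie-break)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cl <- relabel[as.character(memb)]
  names(cl) <- rownames(coords)
  structure(list(cluster = cl, resolution = resolution, k_neighbors = k_neighbors),
            class = "ClusterLabels")
}

#' Per-cell silhouette widths
#'
#' `(b - a) / max(a, b)` with `a` the mean distance to the cell's own cluster
#' and `b` the smallest mean distance to another cluster. Cells in singleton
#' clusters get silhouette 0.
#'
#' @param coords cells x d coordinate matrix.
#' @param cluster per-cell cluster ids (vector in cell order).
#' @return numeric vector of silhouettes, named by row names of `coords`.
#' @export
silhouette_widths <- function(coords, cluster) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(cluster) == n)
  ids <- unique(cluster)
  if (length(ids) < 2) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(coords))
  sizes <- table(cluster)
  # mean distance from every cell to every cluster
  md <- vapply(ids, function(k) {
    rowSums(d[, cluster == k, drop = FALSE]) / sizes[[as.character(k)]]
  }, numeric(n))
  colnames(md) <- as.character(ids)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    k <- as.character(cluster[i])
    nk <- sizes[[k]]
    if (nk == 1) {
      sil[i] <- 0
      next
    }
    a <- md[i, k] * nk / (nk - 1)   # exclude self from own-cluster mean
    b <- min(md[i, setdiff(colnames(md), k)])
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  if (any(sizes == 1)) warning("singleton cluster(s); their silhouette is defined as 0")
  stats::setNames(sil, rownames(coords))
}

#' Remove ambiguously placed cells by silhouette
#'
#' Cells with silhouette width below 0 sit closer to another cluster than to
#' their own and are dropped.
#'
#' @param embedding Embedding or cells x d matrix.
#' @param labels ClusterLabels (or named cluster vector).
#' @return character vector of retained cell ids.
#' @export
silhouette_filter <- function(embedding, labels) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coordinates else as.matrix(embedding)
  cl <- if (inherits(labels, "ClusterLabels")) labels$cluster else labels
  cl <- cl[rownames(coords)]
  sil <- silhouette_widths(coords, cl)
  names(sil)[sil >= 0]
}

#' Flag clusters dominated by a single sample
#'
#' A cluster is flagged when any one sample contributes at least `fraction`
#' of its cells (boundary inclusive: a cluster with exactly half its cells
#' from one sample is flagged at the 0.5 default).
#'
#' @param labels ClusterLabels or named cluster vector.
#' @param sample_of named per-cell sample vector.
#' @param fraction domination threshold (default 0.5).
#' @return vector of flagged cluster ids.
#' @export
flag_sample_dominated_clusters <- function(labels, sample_of, fraction = 0.5) {
  cl <- if (inherits(labels, "ClusterLabels")) labels$cluster else labels
  stopifnot(length(cl) > 0)
  tab <- table(cluster = cl, sample = sample_of[names(cl)])
  share <- apply(tab, 1, max) / rowSums(tab)
  flagged <- names(share)[share >= fraction]
  if (length(unique(sample_of[names(cl)])) == 1 && length(flagged)) {
    warning("single-sample dataset: every cluster is sample-dominated by construction")
  }
  flagged
}
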