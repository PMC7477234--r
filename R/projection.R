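#' Train a reference projector for cell-type label transfer
#'
#' Selects variable genes on the reference, records per-gene scaling
#' parameters (mean, sd of log-normalized expression), fits reference PCA,
#' and stores the reference embedding with its labels. Query cells are later
#' scaled with these *reference* parameters and projected onto the reference
#' loadings, so the projection lives in reference space; labels are assigned
#' by majority vote among the k nearest reference cells.
#'
#' @param ref CountMatrix of the labeled reference.
#' @param labels named per-cell label vector covering every reference cell.
#' @param n_pcs PCs for the reference embedding (default 30).
#' @param k neighbors used in the vote (default 30).
#' @param n_var_genes variable genes selected on the reference.
#' @return `ProjectionModel` list.
#' @export
train_reference <- function(ref, labels, n_pcs = 30, k = 30, n_var_genes = 1000) {
  stopifnot(inherits(ref, "CountMatrix"))
  cells <- colnames(ref$counts)
  if (!all(cells %in% names(labels)) || anyNA(labels[cells])) {
    stop("every reference cell needs a label")
  }
  labels <- labels[cells]
  if (length(unique(labels)) < 2) stop("reference must contain at least 2 labels")
  if (k > length(cells)) stop("k exceeds the number of reference cells")
  norm <- normalize_log(ref)
  var_genes <- select_variable_genes(norm, n_top = min(n_var_genes, nrow(norm)))
  sub <- as.matrix(norm[var_genes, , drop = FALSE])
  mu <- rowMeans(sub)
  sd <- apply(sub, 1, stats::sd)
  sd[sd == 0] <- 1
  scaled <- (sub - mu) / sd
  # per-cell centering removes compositional depression: a population whose
  # transcriptome mass sits elsewhere would otherwise project as a uniformly
  # "low" profile and inherit whichever reference type is lower overall
  scaled <- sweep(scaled, 2, colMeans(scaled))
  emb <- run_pca(scaled, n_pcs = min(n_pcs, length(var_genes), length(cells)))
  # out-of-reference gate: the reference's own k-th-neighbor distance
  # distribution defines how far a query cell may sit from the reference
  # before its vote is considered meaningless
  dref <- as.matrix(stats::dist(emb$coordinates))
  kth <- apply(dref, 1, function(row) sort(row)[min(k, length(row) - 1) + 1])
  structure(list(
    var_genes = var_genes, gene_mean = mu, gene_sd = sd,
    loadings = emb$loadings, ref_embedding = emb$coordinates,
    ref_labels = labels, k = k,
    max_query_dist = stats::quantile(kth, 0.99, names = FALSE)
  ), class = "ProjectionModel")
}

#' Project labels onto query cells with per-cell confidence
#'
#' Query cells are log-normalized, scaled with the reference means/sds over
#' the genes shared with the model, projected onto the reference PC loadings,
#' and labeled by majority vote among the `k` nearest reference cells.
#' Confidence is the vote fraction (a multiple of 1/k); a label is kept only
#' when confidence strictly exceeds `threshold`. Vote ties break by smaller
#' mean neighbor distance, then lexicographically. Query cells farther from
#' their nearest reference cell than the reference's own 99th-percentile
#' k-th-neighbor distance are out-of-reference and stay unassigned -- a
#' population absent from a reference cannot inherit its labels, which is
#' what makes iterative projection over partial atlases meaningful.
#'
#' @param model ProjectionModel from [train_reference()].
#' @param query CountMatrix.
#' @param threshold confidence threshold in [0, 1] (the workflow uses 0.75
#'   for the main atlas pass and 0.50 for the tanycyte/oligodendrocyte
#'   analyses).
#' @return `LabelAssignment` data.frame: cell_id, label (NA = unassigned),
#'   confidence (NA iff unassigned).
#' @export
project_labels <- function(model, query, threshold = 0.75) {
  stopifnot(inherits(model, "ProjectionModel"), inherits(query, "CountMatrix"))
  empty <- data.frame(cell_id = character(0), label = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  if (ncol(query$counts) == 0) return(empty)
  shared <- intersect(model$var_genes, rownames(query$counts))
  if (length(shared) == 0) stop("no genes shared between model and query")
  if (length(shared) < 5) {
    warning("fewer than 5 genes shared with the reference; all cells unassigned")
    return(data.frame(cell_id = colnames(query$counts), label = NA_character_,
                      confidence = NA_real_, stringsAsFactors = FALSE))
  }
  qnorm <- as.matrix(normalize_log(query)[shared, , drop = FALSE])
  qscaled <- (qnorm - model$gene_mean[shared]) / model$gene_sd[shared]
  qscaled <- sweep(qscaled, 2, colMeans(qscaled))   # same per-cell centering
  qcoords <- t(qscaled) %*% model$loadings[shared, , drop = FALSE]
  ref <- model$ref_embedding
  k <- model$k
  # squared Euclidean distances query x reference
  d2 <- outer(rowSums(qcoords^2), rowSums(ref^2), "+") - 2 * qcoords %*% t(ref)
  out <- data.frame(cell_id = colnames(query$counts), label = NA_character_,
                    confidence = NA_real_, stringsAsFactors = FALSE)
  gate2 <- if (is.null(model$max_query_dist)) Inf else model$max_query_dist^2
  for (i in seq_len(nrow(qcoords))) {
    nn <- order(d2[i, ])[seq_len(k)]
    if (d2[i, nn[1]] > gate2) next   # out-of-reference cell: unassigned
    votes <- table(model$ref_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) {
        mean(d2[i, nn[model$ref_labels[nn] == l]])
      }, 0)
      top <- top[order(mean_d, top)][1]
    }
    conf <- as.numeric(max(votes)) / k
    if (conf > threshold) {
      out$label[i] <- top
      out$confidence[i] <- conf
    }
  }
  out
}

#' Iterative projection against an ordered list of references
#'
#' References are applied in order; cells confidently labeled by reference i
#' are removed from the query before reference i + 1 and are never relabeled.
#' The final assignment is the union, with a `reference` column naming the
#' source of each label and per-reference assignment counts attached as the
#' `assignment_counts` attribute (reference order matters and is surfaced).
#'
#' @param references list of `list(model = ProjectionModel, threshold = real)`
#'   entries (a bare ProjectionModel gets the 0.75 default).
#' @param query CountMatrix.
#' @return LabelAssignment data.frame with columns cell_id, label,
#'   confidence, reference.
#' @export
iterative_projection <- function(references, query) {
  stopifnot(length(references) >= 1)
  remaining <- query
  out <- data.frame(cell_id = colnames(query$counts), label = NA_character_,
                    confidence = NA_real_, reference = NA_character_,
                    stringsAsFactors = FALSE)
  counts <- integer(length(references))
  for (i in seq_along(references)) {
    entry <- references[[i]]
    if (inherits(entry, "ProjectionModel")) entry <- list(model = entry, threshold = 0.75)
    if (ncol(remaining$counts) == 0) break
    asg <- project_labels(entry$model, remaining, threshold = entry$threshold)
    hit <- asg$cell_id[!is.na(asg$label)]
    counts[i] <- length(hit)
    if (length(hit)) {
      j <- match(hit, out$cell_id)
      out$label[j] <- asg$label[match(hit, asg$cell_id)]
      out$confidence[j] <- asg$confidence[match(hit, asg$cell_id)]
      out$reference[j] <- names(references)[i] %||% paste0("ref", i)
      keep <- setdiff(colnames(remaining$counts), hit)
      if (!length(keep)) {
        remaining <- subset_count_matrix(remaining, cells = integer(0))
      } else {
        remaining <- subset_count_matrix(remaining, cells = keep)
      }
    }
  }
  names(counts) <- vapply(seq_along(references), function(i) {
    names(references)[i] %||% paste0("ref", i)
  }, "")
  attr(out, "assignment_counts") <- counts
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a) || a == "") b else a
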