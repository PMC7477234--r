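#' Aggregate single-cell counts to pseudobulk
#'
#' Sums raw counts per gene over the masked cells of each sample, yielding a
#' genes x samples matrix suitable for sample-level (animal-level)
#' differential expression. Total counts over the masked cells are conserved.
#'
#' @param cm CountMatrix.
#' @param cell_mask character vector of cells to aggregate (default: all).
#' @param sample_of named per-cell sample vector (default: `sample_id` from
#'   the cell metadata).
#' @return `PseudobulkMatrix`: list with `counts` (genes x samples dense
#'   matrix), `design` (per-sample group/batch/day table) and `size_factors`
#'   (NULL until [estimate_size_factors()] is run).
#' @export
aggregate_pseudobulk <- function(cm, cell_mask = NULL, sample_of = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cell_mask)) cell_mask <- colnames(cm$counts)
  if (!length(cell_mask)) stop("cell_mask is empty")
  if (is.null(sample_of)) sample_of <- cell_field(cm, "sample_id")
  sample_of <- sample_of[cell_mask]
  if (anyNA(sample_of)) stop("every masked cell needs a sample")
  samples <- unique(sample_of)
  ind <- Matrix::sparseMatrix(
    i = match(cell_mask, colnames(cm$counts)),
    j = match(sample_of, samples), x = 1,
    dims = c(ncol(cm$counts), length(samples))
  )
  pb <- as.matrix(cm$counts %*% ind)
  colnames(pb) <- samples
  design <- NULL
  meta_cols <- intersect(c("group", "batch", "day"), names(cm$cell_meta))
  if (length(meta_cols)) {
    meta <- cm$cell_meta[match(cell_mask, cm$cell_meta$cell_id), , drop = FALSE]
    design <- unique(cbind(data.frame(sample_id = sample_of), meta[meta_cols]))
    design <- design[match(samples, design$sample_id), , drop = FALSE]
    rownames(design) <- NULL
  }
  structure(list(counts = pb, design = design, size_factors = NULL),
            class = "PseudobulkMatrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median ratio of its counts to the per-gene geometric
#' mean, over genes non-zero in every sample; factors are rescaled to
#' geometric mean 1. Falls back to library-size factors with a warning when
#' no gene is expressed in every sample.
#'
#' @param pb PseudobulkMatrix or genes x samples count matrix.
#' @return named positive numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(pb) {
  m <- if (inherits(pb, "PseudobulkMatrix")) pb$counts else as.matrix(pb)
  all_pos <- rowSums(m == 0) == 0
  if (!any(all_pos)) {
    warning("no gene expressed in all samples; using library-size factors")
    sf <- colSums(m)
  } else {
    logm <- log(m[all_pos, , drop = FALSE])
    loggeo <- rowMeans(logm)
    sf <- apply(exp(logm - loggeo), 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

# method-of-moments NB dispersion on size-factor-normalized counts,
# pooled within groups; var(K_s / sf_s) ~= mu * mean(1/sf) + alpha * mu^2
mom_dispersion <- function(q, group, inv_sf, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in unique(group)) {
    j <- group == g
    n <- sum(j)
    if (n < 2) next
    xb <- rowMeans(q[, j, drop = FALSE])
    s2 <- apply(q[, j, drop = FALSE], 1, stats::var)
    w <- n - 1
    num <- num + w * (s2 - xb * mean(inv_sf[j]))
    den <- den + w * xb^2
  }
  alpha <- ifelse(den > 0, num / den, floor)
  pmax(alpha, floor)
}

# one-gene NB log-link GLM by iteratively reweighted least squares with a
# fixed dispersion and an offset; returns coefficients and their SEs
nb_irls <- function(y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  beta <- qr.coef(qr(X), log((y + 0.5) / exp(offset)))
  beta[is.na(beta)] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(pmin(eta, 30)), 1e-10)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    delta <- max(abs(fit - beta))
    beta <- drop(fit)
    if (delta < tol) break
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(pmin(eta, 30)), 1e-10)
  W <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e) matrix(NA, ncol(X), ncol(X)))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)))
}

#' Negative-binomial Wald differential expression on pseudobulk counts
#'
#' A minimal self-contained NB engine: median-of-ratios size factors,
#' per-gene method-of-moments dispersion (floored at 1e-8) on normalized
#' counts, a log-link NB GLM fit by iteratively reweighted least squares
#' with `log(size factor)` offsets, and a Wald test on the treated-vs-control
#' coefficient with a normal reference. Batch enters the design as a fixed
#' effect whenever more than one batch is present. P-values are BH-adjusted
#' across tested genes; all-zero genes are reported as category "low" with
#' `p = NA` and are excluded from the correction.
#'
#' @param pb PseudobulkMatrix (design must include `group` with levels
#'   control/treated) or genes x samples matrix plus `design`.
#' @param design optional per-sample data.frame overriding `pb$design`.
#' @param include_batch add batch as a fixed covariate when >1 level
#'   (default TRUE).
#' @param size_factors optional per-sample factors (default: estimated).
#' @return `DEResult` data.frame: gene, baseMean, log2fc, se, stat, p, fdr,
#'   category.
#' @export
nb_wald_test <- function(pb, design = NULL, include_batch = TRUE, size_factors = NULL) {
  m <- if (inherits(pb, "PseudobulkMatrix")) pb$counts else as.matrix(pb)
  if (is.null(design) && inherits(pb, "PseudobulkMatrix")) design <- pb$design
  if (is.null(design) || !"group" %in% names(design)) {
    stop("a design table with a 'group' column is required")
  }
  stopifnot(ncol(m) == nrow(design))
  group <- factor(design$group, levels = c("control", "treated"))
  if (anyNA(group)) stop("group must take values 'control'/'treated'")
  if (any(table(group) < 2)) stop("need at least 2 samples per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  fml <- ~group
  if (include_batch && "batch" %in% names(design) &&
      length(unique(design$batch)) > 1) {
    fml <- ~ group + batch
  }
  X <- stats::model.matrix(fml, data = data.frame(group = group, design[setdiff(names(design), "group")]))
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qr(X)$rank)]
    stop("design matrix is not full rank; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  offset <- log(size_factors)
  q <- sweep(m, 2, size_factors, "/")
  alpha <- mom_dispersion(q, as.character(group), 1 / size_factors)
  coef_idx <- which(colnames(X) == "grouptreated")
  n_genes <- nrow(m)
  res <- data.frame(
    gene = rownames(m) %||chr% sprintf("gene%d", seq_len(n_genes)),
    baseMean = rowMeans(q), log2fc = NA_real_, se = NA_real_,
    stat = NA_real_, p = NA_real_, fdr = NA_real_,
    category = "low", stringsAsFactors = FALSE
  )
  testable <- which(rowSums(m) > 0)
  for (g in testable) {
    fit <- nb_irls(m[g, ], X, offset, alpha[g])
    b <- fit$beta[coef_idx]
    s <- fit$se[coef_idx]
    res$log2fc[g] <- b / log(2)
    res$se[g] <- s / log(2)
    if (is.finite(s) && s > 0) {
      res$stat[g] <- b / s
      res$p[g] <- 2 * stats::pnorm(-abs(b / s))
    }
    res$category[g] <- "ns"
  }
  res$fdr[!is.na(res$p)] <- stats::p.adjust(res$p[!is.na(res$p)], "BH")
  res
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

#' Categorize differential-expression results
#'
#' `up` when `log2fc > lfc` and `fdr < fdr_max`; `down` when
#' `log2fc < -lfc` and `fdr < fdr_max`; otherwise `ns` (untested genes keep
#' `low`). The workflow's volcano categories use (0.25, 0.05) for the
#' single-cell pseudobulk contrasts and (0.5, 0.05) for bulk.
#'
#' @param res DEResult data.frame.
#' @param lfc absolute log2 fold-change threshold.
#' @param fdr_max FDR threshold.
#' @return DEResult with an updated `category` column.
#' @export
classify_degs <- function(res, lfc = 0.25, fdr_max = 0.05) {
  cat <- res$category
  tested <- !is.na(res$fdr)
  cat[tested] <- "ns"
  cat[tested & res$log2fc > lfc & res$fdr < fdr_max] <- "up"
  cat[tested & res$log2fc < -lfc & res$fdr < fdr_max] <- "down"
  res$category <- cat
  res
}

#' DEG-count distribution under repeated downsampling
#'
#' Cell number strongly drives single-cell differential expression; this
#' resampling control draws `n_cells` cells per cluster per sample (without
#' replacement), aggregates them to pseudobulk, runs the NB Wald test, and
#' counts genes below the FDR threshold -- repeated `n_iter` times per
#' cluster to give a DEG-count distribution summarized by median and IQR.
#' Within a cluster, samples with fewer than `n_cells` cells are excluded;
#' clusters left with fewer than 2 samples in either arm are skipped with a
#' warning.
#'
#' @param cm CountMatrix.
#' @param cluster_of,sample_of,group_of named per-cell vectors (defaults:
#'   `cluster`, `sample_id`, `group` columns of the cell metadata).
#' @param n_cells cells per cluster per sample per iteration (default 10).
#' @param n_iter iterations per cluster (default 100).
#' @param fdr FDR threshold for counting DEGs (default 0.1).
#' @param seed integer seed.
#' @return `DownsampleDistribution`: list with `counts` (named list of
#'   integer vectors, one per cluster), `summary` (cluster, median, q25,
#'   q75), `skipped`, and the parameters used.
#' @export
downsample_deg_distribution <- function(cm, cluster_of = NULL, sample_of = NULL,
                                        group_of = NULL, n_cells = 10,
                                        n_iter = 100, fdr = 0.1, seed = 1L) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cluster_of)) cluster_of <- cell_field(cm, "cluster")
  if (is.null(sample_of)) sample_of <- cell_field(cm, "sample_id")
  if (is.null(group_of)) group_of <- cell_field(cm, "group")
  set.seed(seed)
  clusters <- sort(unique(cluster_of))
  out <- list()
  skipped <- character(0)
  for (cl in clusters) {
    cl_cells <- names(cluster_of)[cluster_of == cl]
    by_sample <- split(cl_cells, sample_of[cl_cells])
    by_sample <- by_sample[lengths(by_sample) >= n_cells]
    grp <- vapply(by_sample, function(cc) unique(group_of[cc])[1], "")
    if (sum(grp == "treated") < 2 || sum(grp == "control") < 2) {
      warning("cluster ", cl, " lacks ", n_cells, " cells in >= 2 samples per group; skipped")
      skipped <- c(skipped, as.character(cl))
      next
    }
    design <- data.frame(sample_id = names(by_sample), group = grp,
                         stringsAsFactors = FALSE)
    degs <- integer(n_iter)
    for (it in seq_len(n_iter)) {
      picked <- unlist(lapply(by_sample, sample, size = n_cells), use.names = FALSE)
      pb <- aggregate_pseudobulk(cm, cell_mask = picked, sample_of = sample_of)
      pb$design <- design[match(colnames(pb$counts), design$sample_id), , drop = FALSE]
      res <- nb_wald_test(pb, include_batch = FALSE)
      degs[it] <- sum(res$fdr < fdr, na.rm = TRUE)
    }
    out[[as.character(cl)]] <- degs
  }
  summary <- do.call(rbind, lapply(names(out), function(cl) {
    q <- stats::quantile(out[[cl]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cluster = cl, median = q[2], q25 = q[1], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  structure(list(counts = out, summary = summary, skipped = skipped,
                 n_cells = n_cells, n_iter = n_iter, fdr = fdr, seed = seed),
            class = "DownsampleDistribution")
}

#' Per-cluster cell-abundance t-test
#'
#' Two-sided unpaired Student's t-test on per-animal cell numbers for each
#' cluster, Bonferroni-adjusted across clusters. Clusters with zero variance
#' in both groups get `p = 1` when the group means agree (and 0 when they
#' differ deterministically).
#'
#' @param counts_per_animal clusters x animals matrix of cell numbers.
#' @param group_of named per-animal group vector ("treated"/"control").
#' @return data.frame: cluster, t, p, p_adj.
#' @export
abundance_test <- function(counts_per_animal, group_of) {
  m <- as.matrix(counts_per_animal)
  grp <- group_of[colnames(m)]
  stopifnot(all(table(grp) >= 2))
  res <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, grp == "treated"]
    y <- m[i, grp == "control"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      t <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(cluster = rownames(m)[i] %||chr% as.character(i), t = t, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- pmin(1, res$p * nrow(res))
  res
}
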