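#' Signed co-expression adjacency
#'
#' `a_ij = ((1 + cor(i, j)) / 2) ^ power` with Pearson correlation over
#' cells, so anti-correlated genes get adjacency near 0 (signed network).
#' Symmetric, unit diagonal, values in [0, 1], monotone decreasing in power
#' for correlations below 1. Zero-variance genes get correlation 0 (adjacency
#' `0.5^power`) with a warning.
#'
#' @param expr cells x genes normalized expression matrix.
#' @param power soft-threshold exponent (>= 1).
#' @return genes x genes adjacency matrix.
#' @export
signed_adjacency <- function(expr, power) {
  stopifnot(power >= 1)
  expr <- as.matrix(expr)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s); their correlations are set to 0")
  }
  cc <- suppressWarnings(stats::cor(expr))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  ((1 + cc) / 2)^power
}

#' Soft-threshold power selection for approximate scale-free topology
#'
#' For each candidate power, computes the signed adjacency, per-gene
#' connectivity `k_i = sum_j a_ij - 1`, and the scale-free fit: R-squared of
#' `log10 p(k)` against `log10 k` over 10 equal-width connectivity bins,
#' sign-adjusted so only negative slopes qualify. Candidate powers whose mean
#' connectivity lies at or above the 95th percentile of the candidates' mean
#' connectivities are discarded -- as are powers whose mean connectivity
#' exceeds `k_cap` (default: 10% of the gene count; a network where the
#' typical gene connects to a tenth of all genes is too dense to carve) or
#' falls below `k_floor` (the network fragments and the topological overlap
#' degenerates once the typical gene retains less than one neighbor
#' equivalent). The chosen power is the lowest surviving power with fit >=
#' `rsq_cut`; if none qualifies the argmax-fit power among the survivors is
#' returned with a warning.
#'
#' @param expr cells x genes normalized matrix (>= 50 genes, >= 20 cells).
#' @param powers candidate powers (default 1:30).
#' @param rsq_cut scale-free fit target (default 0.8).
#' @param k_floor minimum admissible mean connectivity (default 1).
#' @param k_cap maximum admissible mean connectivity (default `0.1 * n_genes`).
#' @return `SoftThresholdReport`: list with `table` (power, rsq, slope,
#'   mean_connectivity, discarded), `power` (chosen), `converged` (logical).
#' @export
pick_soft_threshold <- function(expr, powers = 1:30, rsq_cut = 0.8, k_floor = 1,
                                k_cap = NULL) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 50) stop("soft-threshold selection needs >= 50 genes")
  if (nrow(expr) < 20) stop("soft-threshold selection needs >= 20 cells")
  cc <- suppressWarnings(stats::cor(expr))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  base <- (1 + cc) / 2
  tab <- do.call(rbind, lapply(powers, function(p) {
    a <- base^p
    k <- colSums(a) - 1
    if (length(unique(signif(k, 10))) < 10) {
      stop("fewer than 10 distinct connectivity values; too few genes")
    }
    fit <- scale_free_fit(k)
    data.frame(power = p, rsq = fit$rsq, slope = fit$slope,
               mean_connectivity = mean(k))
  }))
  if (is.null(k_cap)) k_cap <- 0.1 * ncol(expr)
  cutk <- stats::quantile(tab$mean_connectivity, 0.95, names = FALSE)
  tab$discarded <- tab$mean_connectivity >= min(cutk, k_cap) |
    tab$mean_connectivity < k_floor
  if (all(tab$discarded)) tab$discarded <- tab$mean_connectivity >= cutk
  ok <- !tab$discarded & tab$slope < 0 & tab$rsq >= rsq_cut
  if (any(ok)) {
    power <- min(tab$power[ok])
    converged <- TRUE
  } else {
    cand <- tab[!tab$discarded, , drop = FALSE]
    score <- ifelse(cand$slope < 0, cand$rsq, -cand$rsq)
    power <- cand$power[which.max(score)]
    converged <- FALSE
    warning("no candidate power reaches scale-free fit ", rsq_cut,
            "; falling back to the best-fit power ", power)
  }
  structure(list(table = tab, power = power, converged = converged,
                 rsq_cut = rsq_cut),
            class = "SoftThresholdReport")
}

# R^2 of log10 p(k) vs log10 k over 10 equal-width connectivity bins (the
# standard scale-free fit index; empty bins dropped)
scale_free_fit <- function(k, n_bins = 10) {
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bins <- cut(k, breaks = br, include.lowest = TRUE, labels = FALSE)
  kb <- tapply(k, bins, mean)
  pb <- tapply(k, bins, length) / length(k)
  keep <- !is.na(kb) & kb > 0 & pb > 0
  if (sum(keep) < 3) return(list(rsq = 0, slope = 0))
  fit <- stats::lm(log10(pb[keep]) ~ log10(kb[keep]))
  rs <- summary(fit)$r.squared
  if (!is.finite(rs)) rs <- 0
  list(rsq = rs, slope = unname(stats::coef(fit)[2]))
}

#' Topological overlap matrix and dissimilarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `l_ij = sum_{u != i,j} a_iu a_uj` the shared-neighbor term and
#' `k = rowSums(a) - 1`; `TOM_ii = 1`. Values lie in [0, 1]; the clustering
#' distance is `1 - TOM`.
#'
#' @param adj symmetric adjacency in [0, 1] with unit diagonal.
#' @return list with `tom` and `dissim` (both genes x genes).
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  stopifnot(isSymmetric(unname(adj), tol = 1e-8))
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  l <- adj %*% adj - 2 * adj           # removes the u = i and u = j terms off-diagonal
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissim = 1 - tom)
}

# partition one dissimilarity block by its dendrogram: static cut at the
# global static-cut height plus recursive re-cut of branches that are
# heterogeneous (large height gap at the root join, or mean internal
# dissimilarity above the cohesion bound). Returns a list of index vectors.
split_branches <- function(sub, linkage, h_star, split_gap, min_size, max_core_scatter) {
  tree <- stats::hclust(stats::as.dist(sub), method = linkage)
  members <- vector("list", nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[i, ]
    members[[i]] <- c(if (kids[1] < 0) -kids[1] else members[[kids[1]]],
                      if (kids[2] < 0) -kids[2] else members[[kids[2]]])
  }
  node_height <- function(i) if (i < 0) 0 else tree$height[i]
  mean_intra <- function(idx) {
    if (length(idx) < 2) return(0)
    m <- sub[idx, idx]
    mean(m[upper.tri(m)])
  }
  clusters <- list()
  stack <- nrow(tree$merge)
  while (length(stack)) {
    node <- stack[1]
    stack <- stack[-1]
    idx <- if (node < 0) -node else members[[node]]
    if (node < 0 || length(idx) < 2 * min_size) {
      clusters[[length(clusters) + 1L]] <- idx
      next
    }
    kids <- tree$merge[node, ]
    gap <- tree$height[node] - max(node_height(kids[1]), node_height(kids[2]))
    if (tree$height[node] > h_star || gap >= split_gap ||
        mean_intra(idx) > max_core_scatter) {
      stack <- c(kids[1], kids[2], stack)
    } else {
      clusters[[length(clusters) + 1L]] <- idx
    }
  }
  clusters
}

# loosely attached members of a stable branch: sorted mean-dissimilarity-to-
# the-rest profile; a jump larger than trim_gap separates the branch core
# from chained-on stragglers (both halves are re-examined by the caller)
trim_stragglers <- function(sub, trim_gap) {
  m <- nrow(sub)
  att <- (rowSums(sub)) / (m - 1)
  ord <- order(att)
  sorted <- att[ord]
  from <- 2L
  gaps <- diff(sorted)[from:(m - 1)]
  if (!length(gaps) || max(gaps) <= trim_gap) return(NULL)
  cut_at <- from - 1L + which.max(gaps)
  list(core = ord[seq_len(cut_at)], rest = ord[(cut_at + 1L):m])
}

#' Deterministic dendrogram cutting into co-expression modules
#'
#' Genes are clustered hierarchically on the TOM dissimilarity (average
#' linkage below 3000 genes, complete linkage at or above, matching the
#' workflow's population sizes). The tree is cut deterministically, with no
#' post-hoc reassignment of genes between modules:
#'
#' 1. *Static cut and recursive re-cut*: branches above the `q`-quantile of
#'    merge heights (deepSplit 2 -> q = 0.92, deepSplit 4 -> q = 0.99) are
#'    forced apart, and a branch is recursively re-cut while it is
#'    heterogeneous -- its root join clears a height gap of `1 - q` (scaled
#'    by the spread of the dissimilarity) over its children, or its mean
#'    internal dissimilarity exceeds `max_core_scatter`.
#' 2. *Straggler trimming*: a stable branch may still carry chained-on genes
#'    that are only weakly attached (a known artifact of average linkage on
#'    topological-overlap dissimilarities, where low-connectivity genes can
#'    attach below the unrelated plateau). If the sorted profile of each
#'    member's mean dissimilarity to the rest jumps by more than `trim_gap`
#'    in its upper half, the members above the jump are detached and
#'    re-clustered among themselves; the branch core is re-examined the same
#'    way.
#' 3. *Validation*: a stable branch becomes a module only if it has at least
#'    `min_size` genes and mean internal dissimilarity at most
#'    `max_core_scatter` (unrelated genes have TOM dissimilarity ~1 by
#'    construction, so noise branches fail this bound and become grey).
#'
#' @param dissim square symmetric dissimilarity (typically `1 - TOM`).
#' @param linkage "average" or "complete"; default chosen by matrix size.
#' @param deep_split 2 (coarser) or 4 (finer).
#' @param min_size minimum module size in genes (default 15).
#' @param max_core_scatter cohesion bound on mean intra-module dissimilarity
#'   (default 0.97; unrelated genes sit near 1 on the TOM dissimilarity scale).
#' @param trim_gap attachment jump that detaches stragglers, as a fraction of
#'   the dissimilarity spread (default 0.1).
#' @return named character vector gene -> module id ("M1", "M2", ... by
#'   decreasing size; "grey" = unassigned), with the full `hclust` tree
#'   attached as attribute `tree`.
#' @export
cut_modules <- function(dissim, linkage = NULL, deep_split = 4, min_size = 15,
                        max_core_scatter = 0.97, trim_gap = 0.1) {
  dissim <- as.matrix(dissim)
  stopifnot(nrow(dissim) == ncol(dissim), deep_split %in% c(2, 4))
  n <- nrow(dissim)
  if (is.null(linkage)) linkage <- if (n < 3000) "average" else "complete"
  q <- c(`2` = 0.92, `4` = 0.99)[as.character(deep_split)]
  tree <- stats::hclust(stats::as.dist(dissim), method = linkage)
  # gap criteria are relative to the spread of the dissimilarity: the TOM
  # scale compresses as the soft power grows, so absolute gaps are meaningless
  off <- dissim[upper.tri(dissim)]
  scale <- max(off) - min(off)
  if (scale <= 0) scale <- 1
  split_gap <- (1 - q) * scale
  trim_gap <- trim_gap * scale
  # the static cut height is a property of the full tree, not of sub-branches
  h_star <- stats::quantile(tree$height, q, names = FALSE)

  modules <- list()
  work <- list(seq_len(n))
  while (length(work)) {
    idx <- work[[1]]
    work <- work[-1]
    if (length(idx) < min_size) next   # grey
    sub <- dissim[idx, idx, drop = FALSE]
    parts <- split_branches(sub, linkage, h_star, split_gap, min_size, max_core_scatter)
    if (length(parts) > 1) {
      work <- c(lapply(parts, function(p) idx[p]), work)
      next
    }
    trim <- if (length(idx) >= min_size + 2) trim_stragglers(sub, trim_gap) else NULL
    if (!is.null(trim)) {
      work <- c(list(idx[trim$core], idx[trim$rest]), work)
      next
    }
    m <- sub[upper.tri(sub)]
    if (length(idx) >= min_size && mean(m) <= max_core_scatter) {
      modules[[length(modules) + 1L]] <- idx
    }
  }

  assignment <- rep("grey", n)
  if (!length(modules)) {
    warning("no module passed the size and cohesion criteria; all genes grey")
  } else {
    modules <- modules[order(-lengths(modules))]
    for (i in seq_along(modules)) assignment[modules[[i]]] <- paste0("M", i)
  }
  names(assignment) <- rownames(dissim)
  attr(assignment, "tree") <- tree
  assignment
}

#' Module eigengenes
#'
#' Per module, the first-principal-component cell embedding of the
#' standardized member-gene submatrix, unit-norm and sign-oriented so its
#' correlation with the module's mean member expression is non-negative.
#'
#' @param expr cells x genes normalized matrix.
#' @param assignment named gene -> module vector ("grey" skipped).
#' @return cells x modules matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, assignment) {
  expr <- as.matrix(expr)
  mods <- setdiff(unique(assignment), "grey")
  if (!length(mods)) stop("no non-grey module to compute eigengenes for")
  mods <- mods[order(as.integer(sub("^M", "", mods)), mods)]
  me <- vapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    if (length(genes) < 2) stop("module ", m, " has fewer than 2 genes")
    sub <- scale(expr[, genes, drop = FALSE])
    sub[!is.finite(sub)] <- 0
    e <- svd(sub, nu = 1, nv = 0)$u[, 1]
    if (stats::cor(e, rowMeans(sub)) < 0) e <- -e
    e
  }, numeric(nrow(expr)))
  rownames(me) <- rownames(expr)
  me
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair whose eigengene dissimilarity
#' `1 - cor` is smallest, while that dissimilarity is at most `cut_height`
#' (0.2 by default, i.e. eigengene correlation >= 0.8), recomputing
#' eigengenes after every merge.
#'
#' @param expr cells x genes normalized matrix.
#' @param assignment named gene -> module vector.
#' @param cut_height eigengene dissimilarity threshold (default 0.2).
#' @return list with `assignment`, `eigengenes`, and `merges` (data.frame of
#'   merged pairs and their eigengene correlation).
#' @export
merge_modules <- function(expr, assignment, cut_height = 0.2) {
  history <- data.frame(kept = character(0), absorbed = character(0),
                        correlation = numeric(0), stringsAsFactors = FALSE)
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, assignment)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - cc[best[1], best[2]] > cut_height) break
    pair <- sort(colnames(cc)[best])
    assignment[assignment == pair[2]] <- pair[1]
    history <- rbind(history, data.frame(
      kept = pair[1], absorbed = pair[2],
      correlation = cc[best[1], best[2]], stringsAsFactors = FALSE
    ))
  }
  list(assignment = assignment,
       eigengenes = module_eigengenes(expr, assignment),
       merges = history)
}

#' Gene-module membership correlations (kME)
#'
#' Pearson correlation of each gene's expression with each module eigengene
#' over cells; the standard measure of how central a gene is to a module.
#' Zero-variance genes get kME 0 with a warning.
#'
#' @param expr cells x genes normalized matrix.
#' @param eigengenes cells x modules matrix.
#' @return genes x modules correlation matrix.
#' @export
compute_kme <- function(expr, eigengenes) {
  expr <- as.matrix(expr)
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance gene(s); their kME is set to 0")
  kme <- suppressWarnings(stats::cor(expr, eigengenes))
  kme[!is.finite(kme)] <- 0
  kme
}

#' Mixed-effects module-treatment association
#'
#' Gaussian linear mixed model on per-cell eigengene values with a random
#' intercept per sample; treatment (and batch, when more than one level is
#' present) enter as fixed effects. Fit by REML; the p-value is a Wald test
#' of the treatment coefficient against a normal reference. When the
#' between-sample variance collapses to zero the fit degenerates to OLS,
#' which lme4 handles as a boundary (singular) fit.
#'
#' @param eigengene per-cell numeric vector.
#' @param treatment per-cell factor/character ("control"/"treated").
#' @param sample per-cell sample (random-intercept grouping).
#' @param batch optional per-cell batch (fixed effect if > 1 level).
#' @return list(beta, se, p) for the treated-vs-control contrast.
#' @export
module_trait_lmm <- function(eigengene, treatment, sample, batch = NULL) {
  treatment <- factor(treatment, levels = c("control", "treated"))
  if (any(table(unique(data.frame(sample, treatment))$treatment) < 2)) {
    stop("need >= 2 samples per treatment arm")
  }
  df <- data.frame(y = eigengene, treatment = treatment, sample = sample)
  fml <- y ~ treatment + (1 | sample)
  if (!is.null(batch) && length(unique(batch)) > 1) {
    df$batch <- factor(batch)
    fml <- y ~ treatment + batch + (1 | sample)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  co <- summary(fit)$coefficients
  beta <- co["treatmenttreated", "Estimate"]
  se <- co["treatmenttreated", "Std. Error"]
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Module-treatment association across all modules
#'
#' Applies [module_trait_lmm()] to every eigengene column and BH-adjusts the
#' p-values across modules.
#'
#' @param eigengenes cells x modules matrix.
#' @param treatment,sample,batch per-cell vectors as in [module_trait_lmm()].
#' @return `ModuleTraitResult` data.frame: module, beta, se, p, fdr.
#' @export
module_trait_association <- function(eigengenes, treatment, sample, batch = NULL) {
  res <- do.call(rbind, lapply(colnames(eigengenes), function(m) {
    fit <- module_trait_lmm(eigengenes[, m], treatment, sample, batch)
    data.frame(module = m, beta = fit$beta, se = fit$se, p = fit$p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res
}

#' Hypergeometric overlap of two module assignments
#'
#' Upper-tail hypergeometric p-value of the gene overlap for every pair of
#' non-grey modules from two assignments over a shared universe, Bonferroni-
#' adjusted across all pairs.
#'
#' @param modules_a,modules_b named gene -> module vectors.
#' @param universe gene universe (non-empty).
#' @return data.frame: module_a, module_b, overlap, size_a, size_b, p, p_adj.
#' @export
module_overlap_hypergeom <- function(modules_a, modules_b, universe) {
  if (!length(universe)) stop("empty universe")
  modules_a <- modules_a[names(modules_a) %in% universe]
  modules_b <- modules_b[names(modules_b) %in% universe]
  ma <- setdiff(unique(modules_a), "grey")
  mb <- setdiff(unique(modules_b), "grey")
  N <- length(universe)
  grid <- expand.grid(module_a = ma, module_b = mb, stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ga <- names(modules_a)[modules_a == grid$module_a[i]]
    gb <- names(modules_b)[modules_b == grid$module_b[i]]
    ov <- length(intersect(ga, gb))
    data.frame(
      module_a = grid$module_a[i], module_b = grid$module_b[i],
      overlap = ov, size_a = length(ga), size_b = length(gb),
      p = stats::phyper(ov - 1, length(ga), N - length(ga), length(gb),
                        lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  res$p_adj <- pmin(1, res$p * nrow(res))
  res
}
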