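# project points onto a polyline; returns arc-length lambda of the foot and
# the squared distance to it. Vectorized over segments.
project_to_polyline <- function(points, vertices) {
  points <- as.matrix(points)
  vertices <- as.matrix(vertices)
  n <- nrow(points)
  m <- nrow(vertices) - 1
  seg <- vertices[-1, , drop = FALSE] - vertices[-(m + 1), , drop = FALSE]
  len2 <- rowSums(seg^2)
  len2[len2 == 0] <- 1e-300
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  best_d2 <- rep(Inf, n)
  best_lambda <- numeric(n)
  for (j in seq_len(m)) {
    rel <- sweep(points, 2, vertices[j, ])
    t <- pmin(pmax((rel %*% seg[j, ]) / len2[j], 0), 1)
    foot <- outer(drop(t), seg[j, ]) + rep(vertices[j, ], each = n)
    d2 <- rowSums((points - foot)^2)
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_lambda[better] <- cum[j] + drop(t)[better] * sqrt(len2[j])
  }
  list(lambda = best_lambda, dist2 = best_d2)
}

#' Fit a principal curve to a 2-D embedding
#'
#' Hastie-Stuetzle iteration: initialize at the first principal-component
#' line, then alternate projecting points to the current curve (lambda = arc
#' length of the projection foot) with smoothing each coordinate against
#' lambda by local linear regression (loess, span 0.3), until the relative
#' change in total squared projection distance falls below `tol` or
#' `max_iter` is reached. Applied to tanycyte PC1/PC2 embeddings this yields
#' the per-cell "pseudoventricle score" along the third-ventricle wall.
#'
#' @param embedding cells x 2 coordinate matrix (>= 20 cells).
#' @param max_iter maximum iterations (default 50).
#' @param tol relative convergence tolerance (default 1e-3).
#' @param span loess span of the coordinate smoother.
#' @return `PseudoventricleFit`: list with `curve` (ordered polyline),
#'   `lambda` (named per-cell arc length), `n_bins` (NA until
#'   [orient_and_scale()]), `iterations`, `mean_dist2`, `converged`.
#' @export
fit_principal_curve <- function(embedding, max_iter = 50, tol = 1e-3, span = 0.3) {
  X <- as.matrix(embedding)
  stopifnot(ncol(X) == 2)
  if (nrow(X) < 20) stop("principal-curve fitting needs >= 20 cells")
  if (all(apply(X, 2, stats::sd) == 0)) stop("degenerate embedding: all points identical")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  v1 <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  lambda <- drop(Xc %*% v1)
  lambda <- lambda - min(lambda)
  total_d2 <- sum(Xc^2) - sum(drop(Xc %*% v1)^2)   # residual from the PC1 line
  curve <- NULL
  iter <- 0
  for (iter in seq_len(max_iter)) {
    ord <- order(lambda)
    lam_s <- lambda[ord]
    fit_x <- stats::loess(X[ord, 1] ~ lam_s, span = span, degree = 1)
    fit_y <- stats::loess(X[ord, 2] ~ lam_s, span = span, degree = 1)
    keep <- !duplicated(lam_s)
    curve <- cbind(stats::fitted(fit_x)[keep], stats::fitted(fit_y)[keep])
    proj <- project_to_polyline(X, curve)
    lambda <- proj$lambda
    new_d2 <- sum(proj$dist2)
    if (abs(total_d2 - new_d2) / max(new_d2, 1e-12) < tol) {
      total_d2 <- new_d2
      break
    }
    total_d2 <- new_d2
  }
  lam <- lambda - min(lambda)
  names(lam) <- rownames(X)
  structure(list(curve = curve, lambda = lam, n_bins = NA_real_,
                 iterations = iter, mean_dist2 = total_d2 / nrow(X),
                 converged = iter < max_iter),
            class = "PseudoventricleFit")
}

#' Orient and rescale a principal-curve fit
#'
#' Flips lambda if the anchor expression (a ventral marker or ventral-type
#' label score, e.g. a beta2-tanycyte score) correlates positively with it,
#' so the anchor-high end sits at lambda 0; then rescales lambda linearly to
#' `[0, n_bins]` so width-1 bins tile the pseudoventricle. If the anchor is
#' essentially uncorrelated with lambda (|cor| < 0.1) the orientation is
#' kept with a warning.
#'
#' @param fit PseudoventricleFit.
#' @param anchor_expression named per-cell values for >= 10 fitted cells.
#' @param n_bins target lambda range (default 30).
#' @return PseudoventricleFit with oriented, rescaled lambda.
#' @export
orient_and_scale <- function(fit, anchor_expression, n_bins = 30) {
  stopifnot(inherits(fit, "PseudoventricleFit"))
  lam <- fit$lambda
  shared <- intersect(names(lam), names(anchor_expression))
  if (length(shared) < 10) stop("anchor expression available for fewer than 10 fitted cells")
  r <- suppressWarnings(stats::cor(lam[shared], anchor_expression[shared]))
  if (is.na(r) || abs(r) < 0.1) {
    warning("anchor is uncorrelated with lambda (|cor| < 0.1); keeping orientation")
  } else if (r > 0) {
    lam <- max(lam) - lam
    fit$curve <- fit$curve[rev(seq_len(nrow(fit$curve))), , drop = FALSE]
  }
  rng <- range(lam)
  if (diff(rng) == 0) stop("constant lambda; cannot rescale")
  fit$lambda <- (lam - rng[1]) / diff(rng) * n_bins
  fit$n_bins <- n_bins
  fit
}

#' Per-cell scaled module expression
#'
#' Mean over module genes of z-scored normalized expression; zero-variance
#' genes contribute 0.
#'
#' @param norm_expr genes x cells normalized matrix.
#' @param module_genes character vector of member genes (>= 2 present).
#' @return named per-cell score vector.
#' @export
score_module_per_cell <- function(norm_expr, module_genes) {
  present <- intersect(module_genes, rownames(norm_expr))
  if (length(present) < 2) stop("fewer than 2 module genes present in the matrix")
  sub <- as.matrix(norm_expr[present, , drop = FALSE])
  mu <- rowMeans(sub)
  s <- apply(sub, 1, stats::sd)
  s[s == 0] <- Inf        # zero-variance genes contribute exactly 0
  z <- (sub - mu) / s
  stats::setNames(colMeans(z), colnames(norm_expr))
}

#' Binned group comparison of module expression along the pseudoventricle
#'
#' Tiles the lambda axis with width-`bin_width` bins and, in every bin with
#' at least 3 cells per group, tests the treatment effect on the per-cell
#' module score with the random-intercept linear mixed model (per-sample
#' intercepts); bins where an arm retains a single sample fall back to a
#' two-sample t-test (recorded in the `method` column). P-values are
#' Bonferroni-adjusted across tested bins; under-populated bins are reported
#' untested and excluded from the adjustment denominator.
#'
#' @param lambda named per-cell lambda (from [orient_and_scale()]).
#' @param score named per-cell module score.
#' @param group,sample named per-cell vectors.
#' @param bin_width bin width on the lambda scale (default 1).
#' @param alpha significance level for the run statistic (default 0.05).
#' @param run_k consecutive significant bins required to flag a module
#'   (default 5).
#' @return `BinnedTestResult`: list with `bins` (per-bin table: bin, n per
#'   group, group means and SEM, p, p_adj, method, tested), `longest_run`,
#'   `flag`.
#' @export
binned_group_test <- function(lambda, score, group, sample, bin_width = 1,
                              alpha = 0.05, run_k = 5) {
  cells <- names(lambda)
  score <- score[cells]
  group <- group[cells]
  sample <- sample[cells]
  if (length(unique(group)) < 2) stop("need two groups")
  edges <- seq(0, ceiling(max(lambda) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(0, bin_width)
  bin <- cut(lambda, breaks = edges, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(b) {
    i <- which(bin == b)
    g <- group[i]
    n_t <- sum(g == "treated")
    n_c <- sum(g == "control")
    row <- data.frame(
      bin = b, lambda_lo = edges[b], lambda_hi = edges[b + 1],
      n_treated = n_t, n_control = n_c,
      mean_treated = if (n_t) mean(score[i][g == "treated"]) else NA_real_,
      sem_treated = if (n_t > 1) stats::sd(score[i][g == "treated"]) / sqrt(n_t) else NA_real_,
      mean_control = if (n_c) mean(score[i][g == "control"]) else NA_real_,
      sem_control = if (n_c > 1) stats::sd(score[i][g == "control"]) / sqrt(n_c) else NA_real_,
      p = NA_real_, method = NA_character_, tested = FALSE,
      stringsAsFactors = FALSE
    )
    if (n_t < 3 || n_c < 3) return(row)
    n_samp <- table(unique(data.frame(s = sample[i], g = g))$g)
    if (all(n_samp >= 2)) {
      fit <- tryCatch(
        module_trait_lmm(score[i], g, sample[i]),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        row$p <- fit$p
        row$method <- "lmm"
        row$tested <- TRUE
        return(row)
      }
    }
    tt <- tryCatch(stats::t.test(score[i][g == "treated"], score[i][g == "control"]),
                   error = function(e) NULL)
    if (!is.null(tt)) {
      row$p <- tt$p.value
      row$method <- "t"
      row$tested <- TRUE
    }
    row
  }))
  if (!any(out$tested)) stop("no bin satisfies the testing preconditions")
  n_tested <- sum(out$tested)
  out$p_adj <- ifelse(out$tested, pmin(1, out$p * n_tested), NA_real_)
  run <- consecutive_significant_run(out$p_adj, alpha = alpha, k = run_k)
  structure(list(bins = out, longest_run = run$longest_run, flag = run$flag,
                 alpha = alpha, run_k = run_k),
            class = "BinnedTestResult")
}

#' Longest run of consecutive significant bins
#'
#' Scans bins in lambda order for the longest run of tested bins with
#' adjusted p below `alpha`; untested bins (NA) break runs. A module is
#' flagged when the run reaches `k` (the "at least 5 consecutive points"
#' rule).
#'
#' @param adjusted_p per-bin adjusted p-values in lambda order (NA = untested).
#' @param alpha significance level (default 0.05).
#' @param k run length required to flag (default 5).
#' @return list(longest_run, flag).
#' @export
consecutive_significant_run <- function(adjusted_p, alpha = 0.05, k = 5) {
  sig <- !is.na(adjusted_p) & adjusted_p < alpha
  best <- 0
  cur <- 0
  for (s in sig) {
    cur <- if (s) cur + 1 else 0
    best <- max(best, cur)
  }
  list(longest_run = best, flag = best >= k)
}
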