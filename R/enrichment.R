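#' Hypergeometric over-representation analysis
#'
#' Terms are intersected with the background; terms whose background size
#' falls outside `[min_size, max_size]`, or whose overlap with the query is
#' below `min_intersect`, are excluded *before* multiple-testing correction.
#' The p-value is the upper-tail hypergeometric probability of the observed
#' overlap; adjustment is Bonferroni over tested terms. When `up` / `down`
#' partitions of the query are supplied, a direction z-score
#' `(n_up - n_down) / sqrt(n_overlap)` is reported per term.
#'
#' @param query gene set (subset of `background`).
#' @param collection GeneSetCollection.
#' @param background gene universe (non-empty; typically all genes that
#'   entered the DE analysis, or the 5000 most variable genes for module
#'   enrichment).
#' @param min_size,max_size term-size bounds within the background
#'   (defaults 10 and 300).
#' @param min_intersect minimum query-term overlap (default 3).
#' @param up,down optional partition of the query for the direction z-score.
#' @return `EnrichmentResult` data.frame: term_id, name, term_size, overlap,
#'   p, p_adj, z, genes.
#' @export
hypergeom_enrich <- function(query, collection, background,
                             min_size = 10, max_size = 300, min_intersect = 3,
                             up = NULL, down = NULL) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  query <- intersect(unique(query), background)
  if (!all(query %in% background)) stop("query must be a subset of the background")
  N <- length(background)
  nq <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    term <- intersect(collection$sets[[id]], background)
    k <- length(term)
    if (k < min_size || k > max_size) return(NULL)
    ov <- intersect(term, query)
    if (length(ov) < min_intersect) return(NULL)
    z <- NA_real_
    if (!is.null(up) || !is.null(down)) {
      n_up <- length(intersect(ov, up))
      n_down <- length(intersect(ov, down))
      z <- (n_up - n_down) / sqrt(length(ov))
    }
    data.frame(
      term_id = id, name = unname(collection$names[id]), term_size = k,
      overlap = length(ov),
      p = stats::phyper(length(ov) - 1, k, N - k, nq, lower.tail = FALSE),
      z = z, genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), name = character(0),
                      term_size = integer(0), overlap = integer(0),
                      p = numeric(0), p_adj = numeric(0), z = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p * nrow(res))
  res[order(res$p), c("term_id", "name", "term_size", "overlap",
                      "p", "p_adj", "z", "genes")]
}

#' Direction z-score of an enrichment overlap
#'
#' `(n_up - n_down) / sqrt(n_overlap)`: overlapping genes that are neither
#' up- nor downregulated count only in the denominator. Undefined (NA) for
#' an empty overlap.
#'
#' @param overlap genes overlapping between a term and the query.
#' @param up,down up- and downregulated gene sets.
#' @return numeric z (NA when the overlap is empty).
#' @export
direction_zscore <- function(overlap, up, down) {
  if (!length(overlap)) return(NA_real_)
  (length(intersect(overlap, up)) - length(intersect(overlap, down))) /
    sqrt(length(overlap))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(stat_sorted, hit, weight = 1) {
  w <- abs(stat_sorted)^weight
  n <- length(stat_sorted)
  nh <- sum(hit)
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Preranked geneset enrichment analysis
#'
#' Threshold-free GSEA on a ranked statistic: the weighted running-sum
#' enrichment score (hit increments proportional to `|stat|^weight`, uniform
#' miss decrements), a gene-label permutation null of equal set size, the
#' normalized enrichment score `NES = ES / mean(|null ES| of the same sign)`,
#' and the add-one empirical two-sided p-value
#' `(1 + #(|null ES| >= |ES|)) / (n_perm + 1)`.
#'
#' @param ranking named per-gene statistic (e.g. DE t or Wald statistics).
#' @param term gene set (>= 3 genes in the ranked universe).
#' @param n_perm permutations (default 1000).
#' @param weight hit-increment exponent (default 1).
#' @param seed integer seed.
#' @return `GseaResult` list: es, nes, p, leading_edge, n_perm, seed.
#' @export
preranked_gsea <- function(ranking, term, n_perm = 1000, weight = 1, seed = 1L) {
  stat <- sort(ranking, decreasing = TRUE)
  hit <- names(stat) %in% term
  if (sum(hit) < 3) stop("term shares fewer than 3 genes with the ranked universe")
  if (sum(hit) == length(stat)) stop("term covers the whole universe")
  es <- gsea_es(stat, hit, weight)
  set.seed(seed)
  n <- length(stat)
  nh <- sum(hit)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, nh)] <- TRUE
    gsea_es(stat, h, weight)
  }, 0)
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  # leading edge: hits at or before the running-sum extremum
  w <- abs(stat)^weight
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  leading <- if (es >= 0) names(stat)[seq_len(peak)][hit[seq_len(peak)]]
             else names(stat)[peak:n][hit[peak:n]]
  structure(list(es = es, nes = nes, p = p, leading_edge = leading,
                 n_perm = n_perm, seed = seed),
            class = "GseaResult")
}

#' Rank-rank hypergeometric overlap map
#'
#' For every pair of top-list thresholds `(i * step, j * step)`, the
#' upper-tail hypergeometric -log10 p of the overlap between the top
#' `i * step` genes of list A and the top `j * step` genes of list B over
#' their shared universe. Both lists must rank the identical universe. A
#' Benjamini-Yekutieli-adjusted grid is attached as `log_padj_by`.
#'
#' @param list_a,list_b full rankings: character vectors of gene ids in rank
#'   order, or named statistics (ranked by decreasing value).
#' @param step threshold step (default `max(1, floor(N / 100))`).
#' @return `RRHOMap`: list with `log_p` (grid of -log10 p), `overlap`
#'   (counts), `log_padj_by`, `step`, `n_genes`.
#' @export
rrho_map <- function(list_a, list_b, step = NULL) {
  as_ranking <- function(x) {
    if (is.numeric(x) && !is.null(names(x))) names(sort(x, decreasing = TRUE)) else as.character(x)
  }
  a <- as_ranking(list_a)
  b <- as_ranking(list_b)
  if (!setequal(a, b) || length(a) != length(b)) {
    diff <- union(setdiff(a, b), setdiff(b, a))
    stop("rankings cover different universes; symmetric difference: ",
         paste(utils::head(diff, 10), collapse = ", "))
  }
  N <- length(a)
  if (is.null(step)) step <- max(1, floor(N / 100))
  n_thr <- floor(N / step)
  pos_b <- match(a, b)                     # rank in B of A's i-th gene
  bin_b <- ceiling(pos_b / step)
  # counts[i, j] = |top(A, i*step) intersect top(B, j*step)|
  counts <- matrix(0L, n_thr, n_thr)
  for (i in seq_len(n_thr)) {
    tabs <- tabulate(bin_b[seq_len(i * step)], nbins = n_thr)
    counts[i, ] <- cumsum(tabs)
  }
  sizes <- seq_len(n_thr) * step
  log_p <- matrix(0, n_thr, n_thr)
  for (i in seq_len(n_thr)) {
    log_p[i, ] <- -stats::phyper(counts[i, ] - 1, sizes[i], N - sizes[i],
                                 sizes, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  p <- 10^(-log_p)
  padj <- matrix(stats::p.adjust(p, "BY"), n_thr, n_thr)
  dimnames(counts) <- dimnames(log_p) <- list(sizes, sizes)
  structure(list(log_p = log_p, overlap = counts,
                 log_padj_by = -log10(pmax(padj, 1e-320)),
                 step = step, n_genes = N),
            class = "RRHOMap")
}

#' Build reactivity genesets from condition-level DE tables
#'
#' Emulates the construction of astrocyte-reactivity genesets from external
#' injury models: per condition, genes with `log2fc > lfc_min` and
#' `fdr < fdr_max` (the FDR clause can be dropped per table via
#' `fdr_omit`); genes passing in both `pan_pair` conditions move to a "PAN"
#' set; any gene left in two or more condition sets is then removed from all
#' of them, so the condition-specific sets are pairwise disjoint.
#'
#' @param de_tables named list of DEResult data.frames sharing a gene
#'   universe (gene, log2fc, fdr).
#' @param lfc_min log2 fold-change floor (default 2).
#' @param fdr_max FDR ceiling (default 0.05).
#' @param pan_pair the two condition names whose shared genes form the PAN
#'   set (default: the first two tables).
#' @param fdr_omit condition names for which the FDR clause is dropped.
#' @return GeneSetCollection with one set per condition plus "PAN".
#' @export
build_reactivity_genesets <- function(de_tables, lfc_min = 2, fdr_max = 0.05,
                                      pan_pair = names(de_tables)[1:2],
                                      fdr_omit = character(0)) {
  if (!all(pan_pair %in% names(de_tables))) {
    stop("missing required condition(s): ",
         paste(setdiff(pan_pair, names(de_tables)), collapse = ", "))
  }
  pass <- lapply(names(de_tables), function(nm) {
    t <- de_tables[[nm]]
    keep <- t$log2fc > lfc_min
    if (!nm %in% fdr_omit) keep <- keep & !is.na(t$fdr) & t$fdr < fdr_max
    unique(t$gene[keep & !is.na(keep)])
  })
  names(pass) <- names(de_tables)
  pan <- intersect(pass[[pan_pair[1]]], pass[[pan_pair[2]]])
  pass <- lapply(pass, setdiff, y = pan)
  all_genes <- unlist(pass, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  pass <- lapply(pass, setdiff, y = dup)
  sets <- c(pass[lengths(pass) > 0], if (length(pan)) list(PAN = pan))
  if (!length(sets)) stop("no geneset passed the thresholds")
  gene_set_collection(sets)
}
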