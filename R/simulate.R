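#' Simulation configuration
#'
#' Describes a multi-sample, two-group (treated vs control) single-cell
#' experiment with cell types and marker genes, planted differential
#' expression, latent-factor co-expression modules, an optional 1-D spatial
#' gradient within one cell type, batch effects and flagged mitochondrial /
#' ribosomal genes. Counts are negative binomial with variance
#' `mu + alpha * mu^2`; `alpha` is drawn per gene from a gamma prior so the
#' generator matches the model assumed by the differential-expression engine.
#'
#' Defaults emulate the larger cohort design of the study the workflow
#' targets: 6 animals per arm across 2 batches, a median library of ~1800
#' UMIs per cell, and three hypothalamic cell types. No effect (DE, module
#' response, gradient) is planted unless requested, so the default
#' configuration is an honest null.
#'
#' @param n_genes gene universe size.
#' @param cell_types list of [sim_cell_type()] entries.
#' @param samples data.frame from [sim_samples()] (sample_id, group, batch_id).
#' @param library_size list(meanlog, sdlog) of the log-normal per-cell library.
#' @param nb_dispersion list(shape, rate) of the per-gene gamma dispersion prior.
#' @param de_spec list(fraction_de, log2fc_mean, log2fc_sd, prob_up,
#'   affected_cell_types); `fraction_de = 0` plants nothing.
#' @param module_spec list of [sim_module()] entries.
#' @param gradient_spec [sim_gradient()] entry or NULL.
#' @param mito_fraction,ribo_fraction expected UMI share of flagged genes.
#' @param n_mito,n_ribo number of flagged genes.
#' @param batch_sd standard deviation of per-gene log2 batch offsets.
#' @param seed default seed used when `simulate_dataset` is called without one.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 1000,
                       cell_types = list(
                         sim_cell_type("astro", 60, n_markers = 20),
                         sim_cell_type("tany", 40, n_markers = 20),
                         sim_cell_type("neuron", 50, n_markers = 20)
                       ),
                       samples = sim_samples(n_per_group = 6, n_batches = 2),
                       library_size = list(meanlog = log(1800), sdlog = 0.3),
                       nb_dispersion = list(shape = 2, rate = 20),
                       de_spec = list(fraction_de = 0, log2fc_mean = 1,
                                      log2fc_sd = 0.25, prob_up = 0.5,
                                      affected_cell_types = NULL),
                       module_spec = list(),
                       gradient_spec = NULL,
                       mito_fraction = 0.05,
                       ribo_fraction = 0.05,
                       n_mito = 15, n_ribo = 25,
                       batch_sd = 0.2,
                       seed = 1L) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  cfg <- list(
    n_genes = n_genes, genes = genes, cell_types = cell_types, samples = samples,
    library_size = library_size, nb_dispersion = nb_dispersion, de_spec = de_spec,
    module_spec = module_spec, gradient_spec = gradient_spec,
    mito_fraction = mito_fraction, ribo_fraction = ribo_fraction,
    n_mito = n_mito, n_ribo = n_ribo, batch_sd = batch_sd, seed = seed
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param name cell type name.
#' @param n_cells_per_sample cells of this type per sample.
#' @param marker_genes character vector of marker gene ids; if NULL,
#'   `n_markers` genes are auto-assigned from the universe at validation.
#' @param marker_log2fc log2 enrichment of markers in this type.
#' @param n_markers number of auto-assigned markers.
#' @export
sim_cell_type <- function(name, n_cells_per_sample, marker_genes = NULL,
                          marker_log2fc = 2, n_markers = 20) {
  list(name = name, n_cells_per_sample = n_cells_per_sample,
       marker_genes = marker_genes, marker_log2fc = marker_log2fc,
       n_markers = n_markers)
}

#' @rdname sim_config
#' @param n_per_group samples per arm (treated / control).
#' @param n_batches batches, assigned round-robin across samples.
#' @export
sim_samples <- function(n_per_group = 6, n_batches = 2) {
  n <- 2 * n_per_group
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("treated", "control"), each = n_per_group),
    batch_id = sprintf("b%d", ((seq_len(n) - 1L) %% n_batches) + 1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @param genes member gene ids (NULL with `n_genes_module` auto-assigns).
#' @param loading log2-scale loading of member genes on the latent factor.
#' @param treatment_effect shift of the factor mean in treated samples
#'   (units of the factor's unit standard deviation).
#' @param sample_sd standard deviation of per-sample factor intercepts
#'   (biological replicate variation).
#' @param n_genes_module size of an auto-assigned module.
#' @param expr_boost baseline-expression multiplier for member genes;
#'   detectable co-expression programs are carried by well-expressed genes,
#'   so module members sit above the sparse tail of the transcriptome.
#' @export
sim_module <- function(genes = NULL, loading = 1, treatment_effect = 0,
                       sample_sd = 0.05, n_genes_module = 25, expr_boost = 1) {
  list(genes = genes, loading = loading, treatment_effect = treatment_effect,
       sample_sd = sample_sd, n_genes_module = n_genes_module,
       expr_boost = expr_boost)
}

#' @rdname sim_config
#' @param cell_type name of the spatially graded type (e.g. a tanycyte-like
#'   population along the third-ventricle wall).
#' @param markers named list of functions of the latent position t in [0, 1],
#'   each returning a log2-scale expression offset (smooth zone profiles).
#' @export
sim_gradient <- function(cell_type, markers) {
  stopifnot(is.list(markers), !is.null(names(markers)))
  list(cell_type = cell_type, markers = markers)
}

validate_sim_config <- function(cfg) {
  genes <- cfg$genes
  stopifnot(cfg$n_genes >= 10)
  if (cfg$mito_fraction < 0 || cfg$ribo_fraction < 0 ||
      cfg$mito_fraction + cfg$ribo_fraction > 1) {
    stop("mito/ribo fractions must be non-negative and sum to at most 1")
  }
  # flagged genes live at the end of the universe
  cfg$mito_genes <- utils::tail(genes, cfg$n_mito + cfg$n_ribo)[seq_len(cfg$n_mito)]
  cfg$ribo_genes <- utils::tail(genes, cfg$n_ribo)
  reserved <- c(cfg$mito_genes, cfg$ribo_genes)
  used <- character(0)
  free <- setdiff(genes, reserved)
  claim <- function(requested, n_auto, what) {
    if (is.null(requested)) {
      if (n_auto > length(free)) stop("gene universe too small for ", what)
      requested <- free[seq_len(n_auto)]
    }
    if (!all(requested %in% genes)) stop(what, " genes outside the gene universe")
    dup <- intersect(requested, used)
    if (length(dup)) {
      stop("overlapping marker/module assignments for gene(s): ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
    used <<- c(used, requested)
    free <<- setdiff(free, requested)
    requested
  }
  for (i in seq_along(cfg$cell_types)) {
    ct <- cfg$cell_types[[i]]
    cfg$cell_types[[i]]$marker_genes <-
      claim(ct$marker_genes, ct$n_markers, paste0("marker (", ct$name, ")"))
  }
  for (i in seq_along(cfg$module_spec)) {
    m <- cfg$module_spec[[i]]
    cfg$module_spec[[i]]$genes <-
      claim(m$genes, m$n_genes_module, paste0("module ", i))
  }
  if (!is.null(cfg$gradient_spec)) {
    if (!cfg$gradient_spec$cell_type %in% vapply(cfg$cell_types, `[[`, "", "name")) {
      stop("gradient cell type not among configured cell types")
    }
    gm <- names(cfg$gradient_spec$markers)
    if (!all(gm %in% genes)) stop("gradient marker genes outside the gene universe")
  }
  de <- cfg$de_spec
  if (de$fraction_de < 0 || de$fraction_de > 1) stop("fraction_de must be in [0, 1]")
  if (de$fraction_de > 0) {
    for (g in c("treated", "control")) {
      if (sum(cfg$samples$group == g) < 2) {
        stop("need >= 2 samples per arm when de_spec is non-empty")
      }
    }
  }
  structure(cfg, class = "SimConfig")
}

#' Simulate a seeded single-cell dataset with known ground truth
#'
#' Draws gene-wise negative-binomial counts whose means are modulated by cell
#' type markers, planted treatment effects, module latent factors, batch
#' offsets and (optionally) a smooth 1-D spatial gradient, then scaled to a
#' log-normal per-cell library size. Identical `(config, seed)` yields
#' bit-identical output.
#'
#' @param config SimConfig from [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `counts` (CountMatrix; `cell_meta` carries sample_id,
#'   group, batch and `truth_`-prefixed cell truth) and `truth` (list of
#'   `cells` and `genes` data.frames: per-cell type/sample/group/batch/
#'   lambda_true; per-gene is_de / true_log2fc / module_id / marker_of).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(seed)
  genes <- config$genes
  n_genes <- config$n_genes
  smp <- config$samples

  # cell roster: every sample contributes each type's quota
  cells <- do.call(rbind, lapply(seq_len(nrow(smp)), function(i) {
    do.call(rbind, lapply(config$cell_types, function(ct) {
      data.frame(type = rep(ct$name, ct$n_cells_per_sample),
                 sample = smp$sample_id[i], group = smp$group[i],
                 batch = smp$batch_id[i], stringsAsFactors = FALSE)
    }))
  }))
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("c%05d", seq_len(n_cells))

  # baseline relative expression, with mito/ribo mass pinned to their shares.
  # Marker genes draw from a moderately expressed stratum: canonical cell-type
  # markers are robustly detected genes, not the sparse tail.
  w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  names(w) <- genes
  for (ct in config$cell_types) {
    w[ct$marker_genes] <- stats::rlnorm(length(ct$marker_genes),
                                        meanlog = 1, sdlog = 0.5)
  }
  is_mito <- genes %in% config$mito_genes
  is_ribo <- genes %in% config$ribo_genes
  other <- !(is_mito | is_ribo)
  w[is_mito] <- w[is_mito] / sum(w[is_mito]) * config$mito_fraction
  w[is_ribo] <- w[is_ribo] / sum(w[is_ribo]) * config$ribo_fraction
  w[other] <- w[other] / sum(w[other]) * (1 - config$mito_fraction - config$ribo_fraction)

  # log2-scale effect matrix
  eff <- matrix(0, n_genes, n_cells, dimnames = list(genes, cells$cell_id))
  gene_truth <- data.frame(
    gene_id = genes, is_de = FALSE, true_log2fc = 0,
    module_id = NA_character_, marker_of = NA_character_,
    stringsAsFactors = FALSE
  )

  for (ct in config$cell_types) {
    idx <- which(cells$type == ct$name)
    eff[ct$marker_genes, idx] <- eff[ct$marker_genes, idx] + ct$marker_log2fc
    gene_truth$marker_of[match(ct$marker_genes, genes)] <- ct$name
  }

  # batch offsets (reference batch = first level)
  batches <- unique(smp$batch_id)
  if (length(batches) > 1 && config$batch_sd > 0) {
    for (b in batches[-1]) {
      off <- stats::rnorm(n_genes, 0, config$batch_sd)
      idx <- which(cells$batch == b)
      eff[, idx] <- eff[, idx] + off
    }
  }

  # planted DE genes (never markers, module members or flagged genes)
  de <- config$de_spec
  if (de$fraction_de > 0) {
    eligible <- genes[other & is.na(gene_truth$marker_of)]
    eligible <- setdiff(eligible, unlist(lapply(config$module_spec, `[[`, "genes")))
    n_de <- min(length(eligible), round(de$fraction_de * n_genes))
    de_genes <- sample(eligible, n_de)
    sign <- ifelse(stats::runif(n_de) < de$prob_up, 1, -1)
    lfc <- sign * abs(stats::rnorm(n_de, de$log2fc_mean, de$log2fc_sd))
    aff_types <- de$affected_cell_types
    if (is.null(aff_types)) aff_types <- vapply(config$cell_types, `[[`, "", "name")
    idx <- which(cells$group == "treated" & cells$type %in% aff_types)
    eff[de_genes, idx] <- eff[de_genes, idx] + lfc
    gi <- match(de_genes, genes)
    gene_truth$is_de[gi] <- TRUE
    gene_truth$true_log2fc[gi] <- lfc
  }

  # module latent factors: per-sample intercept + treatment shift + unit noise
  for (i in seq_along(config$module_spec)) {
    m <- config$module_spec[[i]]
    w[m$genes] <- w[m$genes] * (m$expr_boost %||num% 1)
    b_s <- stats::setNames(stats::rnorm(nrow(smp), 0, m$sample_sd), smp$sample_id)
    f <- b_s[cells$sample] + m$treatment_effect * (cells$group == "treated") +
      stats::rnorm(n_cells)
    eff[m$genes, ] <- eff[m$genes, ] + m$loading * rep(f, each = length(m$genes))
    gene_truth$module_id[match(m$genes, genes)] <- paste0("simM", i)
  }

  # spatial gradient within one cell type
  cells$lambda_true <- NA_real_
  if (!is.null(config$gradient_spec)) {
    gs <- config$gradient_spec
    idx <- which(cells$type == gs$cell_type)
    t_c <- stats::runif(length(idx))
    cells$lambda_true[idx] <- t_c
    for (g in names(gs$markers)) {
      eff[g, idx] <- eff[g, idx] + gs$markers[[g]](t_c)
    }
  }

  # library sizes and NB draws
  lib <- stats::rlnorm(n_cells, config$library_size$meanlog, config$library_size$sdlog)
  mu <- w * 2^eff
  mu <- sweep(mu, 2, colSums(mu) / lib, "/")
  alpha <- stats::rgamma(n_genes, shape = config$nb_dispersion$shape,
                         rate = config$nb_dispersion$rate)
  alpha <- pmax(alpha, 1e-8)
  counts <- matrix(
    stats::rnbinom(n_genes * n_cells, size = 1 / alpha, mu = as.vector(mu)),
    n_genes, n_cells, dimnames = dimnames(eff)
  )

  gene_meta <- data.frame(gene_id = genes, symbol = genes,
                          is_mito = is_mito, is_ribo = is_ribo,
                          stringsAsFactors = FALSE)
  cell_meta <- data.frame(
    cell_id = cells$cell_id, sample_id = cells$sample, group = cells$group,
    batch = cells$batch, truth_type = cells$type,
    truth_lambda = cells$lambda_true, stringsAsFactors = FALSE
  )
  cm <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                     gene_meta = gene_meta, cell_meta = cell_meta)
  truth_cells <- data.frame(
    cell_id = cells$cell_id, type = cells$type, sample = cells$sample,
    group = cells$group, batch = cells$batch, lambda_true = cells$lambda_true,
    stringsAsFactors = FALSE
  )
  list(counts = cm, truth = list(cells = truth_cells, genes = gene_truth))
}

#' Simulate a labeled reference dataset for projection testing
#'
#' Draws from the same generative families as [simulate_dataset()] but with
#' no planted treatment effect, returning per-cell type labels. Stands in for
#' the public hypothalamic atlases used as projection references.
#'
#' @param config SimConfig with at least two cell types.
#' @param seed integer seed.
#' @return list(counts = CountMatrix, labels = named character vector).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  if (length(config$cell_types) < 2) {
    stop("a projection reference needs at least 2 cell types")
  }
  config$de_spec$fraction_de <- 0
  sim <- simulate_dataset(config, seed = seed)
  labels <- stats::setNames(sim$truth$cells$type, sim$truth$cells$cell_id)
  list(counts = sim$counts, labels = labels)
}

#' Simulate a pair of ranked gene lists with controlled concordance
#'
#' Generates two full rankings over the same gene universe whose Spearman
#' rank correlation approximates `concordance` (the underlying Gaussian
#' copula correlation is adjusted so the *rank* correlation is targeted).
#' `concordance = 1` returns identical rankings, `-1` exactly reversed ones.
#'
#' @param n_genes universe size (>= 10).
#' @param concordance target rank correlation in [-1, 1].
#' @param seed integer seed.
#' @return list with `stat_a`, `stat_b` (named statistics over the universe)
#'   and `ranking_a`, `ranking_b` (gene ids ordered by decreasing statistic).
#' @export
simulate_ranked_pair <- function(n_genes, concordance, seed = 1L) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (abs(concordance) > 1) stop("concordance must lie in [-1, 1]")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  a <- stats::rnorm(n_genes)
  if (abs(concordance) == 1) {
    b <- concordance * a
  } else {
    # Pearson rho on normals chosen so the Spearman correlation hits target
    rho <- 2 * sin(pi * concordance / 6)
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n_genes)
  }
  names(a) <- names(b) <- genes
  list(
    stat_a = a, stat_b = b,
    ranking_a = genes[order(a, decreasing = TRUE)],
    ranking_b = genes[order(b, decreasing = TRUE)]
  )
}
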