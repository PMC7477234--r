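# shared fixtures: planted-block expression, small configs, a Rand index

# cells x genes Gaussian matrix with correlated blocks planted at the front
make_blocks <- function(seed, n_cells, n_genes, sizes, rho = 0.8) {
  set.seed(seed)
  expr <- matrix(stats::rnorm(n_cells * n_genes), n_cells, n_genes)
  start <- 0
  for (s in sizes) {
    f <- stats::rnorm(n_cells)
    idx <- start + seq_len(s)
    expr[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * expr[, idx]
    start <- start + s
  }
  colnames(expr) <- sprintf("g%03d", seq_len(n_genes))
  rownames(expr) <- sprintf("c%03d", seq_len(n_cells))
  expr
}

rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  (choose(n, 2) + 2 * sum(choose(tab, 2)) -
     sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2))) / choose(n, 2)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# small two-type configuration with well-separated markers (no batch effect)
separable_config <- function(n_types = 2, n_genes = 300, cells = 40,
                             n_per_group = 3, markers = 30, lfc = 4) {
  types <- lapply(seq_len(n_types), function(i) {
    sim_cell_type(paste0("type", i), cells, n_markers = markers, marker_log2fc = lfc)
  })
  sim_config(n_genes = n_genes, cell_types = types,
             samples = sim_samples(n_per_group = n_per_group, n_batches = 1),
             batch_sd = 0)
}

# the module-chain study conditions: 3 planted modules, the first responsive
module_chain_config <- function() {
  sim_config(
    n_genes = 500,
    cell_types = list(sim_cell_type("astro", 100, n_markers = 0)),
    samples = sim_samples(n_per_group = 6, n_batches = 1),
    module_spec = list(
      sim_module(loading = 1.25, treatment_effect = 0.6, n_genes_module = 25),
      sim_module(loading = 1.25, n_genes_module = 25),
      sim_module(loading = 1.25, n_genes_module = 25)
    )
  )
}

# run the full module-discovery chain on a simulated dataset; returns the
# association table plus the module overlapping the planted responsive set
run_module_chain <- function(seed, deep_split = 4, n_var = 150) {
  sim <- simulate_dataset(module_chain_config(), seed = seed)
  norm <- normalize_log(sim$counts)
  vg <- select_variable_genes(norm, n_var)
  expr <- t(as.matrix(norm[vg, , drop = FALSE]))
  pw <- suppressWarnings(pick_soft_threshold(expr))
  tom <- topological_overlap(signed_adjacency(expr, pw$power))
  asg <- suppressWarnings(cut_modules(tom$dissim, deep_split = deep_split))
  if (length(setdiff(unique(asg), "grey")) < 2) {
    return(list(assoc = NULL, target = NA_character_, flagged = character(0)))
  }
  merged <- merge_modules(expr, asg, cut_height = 0.2)
  meta <- sim$counts$cell_meta
  assoc <- module_trait_association(merged$eigengenes, meta$group, meta$sample_id)
  truth <- sim$truth$genes
  resp <- truth$gene_id[!is.na(truth$module_id) & truth$module_id == "simM1"]
  mods <- setdiff(unique(merged$assignment), "grey")
  ov <- vapply(mods, function(m) {
    length(intersect(names(merged$assignment)[merged$assignment == m], resp))
  }, 0L)
  list(assoc = assoc, target = mods[which.max(ov)],
       flagged = assoc$module[assoc$fdr < 0.05 & abs(assoc$beta) > 0.005],
       power = pw$power)
}
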