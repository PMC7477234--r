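#!/usr/bin/env Rscript
# Generate the synthetic study data every later step consumes: a two-group
# (treated vs vehicle-like control) single-cell experiment with 6 animals per
# arm over 2 batches, three hypothalamic cell types (astrocyte-, tanycyte-
# and neuron-like), planted differential expression in the astrocyte-like
# population, three co-expression modules (one treatment-responsive), and a
# 1-D spatial gradient across the tanycyte-like population standing in for
# position along the third-ventricle wall. A separately seeded labeled
# reference emulates a public atlas for label projection.

suppressMessages(library(hypomod))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 101L

# zonation program: ventral (beta2-like), dorsal (alpha2-like) and mid-wall
# marker blocks with smooth log2 profiles of the latent position t
ventral_markers <- setNames(
  lapply(1:20, function(i) {
    function(t) 4 * (1 - t)
  }),
  sprintf("g%04d", 700:719)
)
dorsal_markers <- setNames(
  lapply(1:20, function(i) {
    function(t) 4 * t
  }),
  sprintf("g%04d", 720:739)
)
mid_markers <- setNames(
  lapply(1:10, function(i) {
    function(t) 3 * exp(-((t - 0.5) / 0.25)^2)
  }),
  sprintf("g%04d", 740:749)
)
gradient <- sim_gradient("tany", c(ventral_markers, dorsal_markers, mid_markers))

cfg <- sim_config(
  n_genes = 1200,
  cell_types = list(
    sim_cell_type("astro", 70, n_markers = 30, marker_log2fc = 3),
    sim_cell_type("tany", 150, n_markers = 30, marker_log2fc = 3),
    sim_cell_type("neuron", 60, n_markers = 30, marker_log2fc = 3)
  ),
  samples = sim_samples(n_per_group = 6, n_batches = 2),
  de_spec = list(fraction_de = 0.03, log2fc_mean = 1.2, log2fc_sd = 0.3,
                 prob_up = 0.5, affected_cell_types = "astro"),
  module_spec = list(
    sim_module(loading = 1.1, treatment_effect = 0.8, n_genes_module = 25),
    sim_module(loading = 1.1, n_genes_module = 25),
    sim_module(loading = 1.1, n_genes_module = 25)
  ),
  gradient_spec = gradient
)

sim <- simulate_dataset(cfg, seed = seed)
write_counts_10x(sim$counts, file.path(out, "query"))
write_results(sim$truth$genes, file.path(out, "truth_genes.tsv"))
write_results(sim$truth$cells, file.path(out, "truth_cells.tsv"))

ref <- simulate_reference(cfg, seed = seed + 1L)
write_counts_10x(ref$counts, file.path(out, "reference"))
write_results(data.frame(cell_id = names(ref$labels), label = ref$labels),
              file.path(out, "reference_labels.tsv"))

message(sprintf("query: %d genes x %d cells; %d planted DE genes, %d module genes, %d gradient cells",
                nrow(sim$counts$counts), ncol(sim$counts$counts),
                sum(sim$truth$genes$is_de),
                sum(!is.na(sim$truth$genes$module_id)),
                sum(!is.na(sim$truth$cells$lambda_true))))
message("reference: ", ncol(ref$counts$counts), " labeled cells, ",
        length(unique(ref$labels)), " types")
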