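#!/usr/bin/env Rscript
# Sample-level differential expression: pseudobulk NB Wald tests within the
# astrocyte-like population (where DE was planted), volcano categorization at
# the |log2FC| > 0.25, FDR < 0.05 thresholds, the repeated-downsampling
# DEG-count distribution per cell type (10 cells/sample/iteration, 100
# iterations), and the per-animal abundance t-test.

suppressMessages(library(hypomod))

query <- read_counts_10x("results/data/query")
truth_genes <- read_results("results/data/truth_genes.tsv")
type_of <- setNames(query$cell_meta$truth_type, query$cell_meta$cell_id)

## pseudobulk DE within the astrocyte-like cells
astro <- names(type_of)[type_of == "astro"]
pb <- aggregate_pseudobulk(query, cell_mask = astro)
res <- classify_degs(nb_wald_test(pb), lfc = 0.25, fdr_max = 0.05)
write_results(res, "results/de_astro.tsv")
called <- res$gene[res$category %in% c("up", "down")]
planted <- truth_genes$gene_id[truth_genes$is_de]
message(sprintf("astro pseudobulk: %d DEGs called; %d / %d planted DE genes recovered",
                length(called), length(intersect(called, planted)), length(planted)))

## DEG-count distributions under repeated downsampling
cm <- query
cm$cell_meta$cluster <- cm$cell_meta$truth_type
dd <- downsample_deg_distribution(cm, n_cells = 10, n_iter = 100, fdr = 0.1, seed = 7)
write_results(dd$summary, "results/downsample_summary.tsv")
message("downsampling medians (IQR):")
print(dd$summary)

## per-animal cell-type abundance
tab <- table(type_of, setNames(query$cell_meta$sample_id, query$cell_meta$cell_id)[names(type_of)])
grp <- setNames(query$cell_meta$group[match(colnames(tab), query$cell_meta$sample_id)],
                colnames(tab))
ab <- abundance_test(unclass(tab), grp)
write_results(ab, "results/abundance.tsv")
message("abundance t-tests (Bonferroni):")
print(ab)
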