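#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks stage names and parameter ranges,
#' injects defaults, and returns a validated `PipelineConfig`. Validation
#' happens in full before any stage executes; unknown stages or keys are
#' rejected with the offending key path (and a suggestion when a known key
#' is close).
#'
#' Supported stages and their defaulted parameters:
#' \describe{
#'   \item{simulate}{`n_genes` (500), `n_per_group` (6), plus optional
#'     `fraction_de`, `n_modules`, `treatment_effect`.}
#'   \item{qc}{`mode` ("single_cell"), `min_genes` (400), `max_genes`
#'     (4000), `resolution` (0.1), `k_neighbors` (20), `n_pcs` (30),
#'     `n_var_genes` (2000).}
#'   \item{de}{`lfc` (0.25), `fdr` (0.05).}
#'   \item{downsample}{`n_cells` (10), `n_iter` (100), `fdr` (0.1).}
#'   \item{modules}{`deep_split` (4), `min_size` (15), `merge_height`
#'     (0.2), `n_var_genes` (5000).}
#' }
#'
#' @param path YAML file with top-level keys `seed`, `out_dir`, `mode`
#'   (optional) and `stages` (named list).
#' @return `PipelineConfig` list.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("seed", "out_dir", "mode", "stages")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         "; expected one of ", paste(known_top, collapse = ", "))
  }
  defaults <- list(
    simulate = list(n_genes = 500, n_per_group = 6, fraction_de = 0,
                    n_modules = 0, treatment_effect = 0),
    qc = list(mode = "single_cell", min_genes = 400, max_genes = 4000,
              resolution = 0.1, k_neighbors = 20, n_pcs = 30,
              n_var_genes = 2000),
    de = list(lfc = 0.25, fdr = 0.05),
    downsample = list(n_cells = 10, n_iter = 100, fdr = 0.1),
    modules = list(deep_split = 4, min_size = 15, merge_height = 0.2,
                   n_var_genes = 5000)
  )
  stages <- raw$stages
  if (is.null(stages) || !length(stages)) stop("configuration lists no stages")
  bad <- setdiff(names(stages), names(defaults))
  if (length(bad)) {
    hint <- vapply(bad, function(b) {
      d <- utils::adist(b, names(defaults))
      if (min(d) <= 3) paste0(" (did you mean '", names(defaults)[which.min(d)], "'?)") else ""
    }, "")
    stop("unknown stage(s): ", paste0(bad, hint, collapse = ", "))
  }
  for (s in names(stages)) {
    params <- stages[[s]]
    if (is.null(params)) params <- list()
    unknown <- setdiff(names(params), names(defaults[[s]]))
    if (length(unknown)) {
      stop("unknown key(s) in stage '", s, "': ", paste(unknown, collapse = ", "))
    }
    stages[[s]] <- utils::modifyList(defaults[[s]], params)
  }
  if ("qc" %in% names(stages)) {
    p <- stages$qc
    if (p$min_genes >= p$max_genes) stop("qc: min_genes must be below max_genes")
    if (p$resolution <= 0) stop("qc: resolution must be positive")
  }
  if ("modules" %in% names(stages)) {
    p <- stages$modules
    if (p$min_size < 2) stop("modules: min_size must be >= 2")
    if (!p$deep_split %in% c(2, 4)) stop("modules: deep_split must be 2 or 4")
    if (p$merge_height < 0 || p$merge_height > 1) stop("modules: merge_height must be in [0, 1]")
  }
  if ("downsample" %in% names(stages) && stages$downsample$n_cells < 1) {
    stop("downsample: n_cells must be >= 1")
  }
  structure(list(
    seed = as.integer(raw$seed %||num% 1L),
    out_dir = raw$out_dir %||chr% "pipeline_out",
    stages = stages
  ), class = "PipelineConfig")
}

`%||num%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline
#'
#' Executes the configured stages in the fixed order simulate -> qc -> de ->
#' downsample -> modules, writing each stage's TSV outputs and a JSON
#' manifest entry (parameters, stage seed, input dimensions) under
#' `out_dir`. The global seed is fanned out as
#' `stage_seed = seed + 101 * stage_index` so any stage can be re-run
#' bit-identically without replaying earlier stages' random draws.
#'
#' @param config PipelineConfig from [validate_config()] (or a path to one).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  order <- intersect(c("simulate", "qc", "de", "downsample", "modules"),
                     names(config$stages))
  manifest <- list(seed = config$seed, stages = list())
  state <- list()
  for (i in seq_along(order)) {
    s <- order[i]
    p <- config$stages[[s]]
    stage_seed <- config$seed + 101L * i
    res <- switch(s,
      simulate = {
        mods <- if (p$n_modules > 0) {
          lapply(seq_len(p$n_modules), function(j) {
            sim_module(treatment_effect = if (j == 1) p$treatment_effect else 0)
          })
        } else list()
        cfg <- sim_config(n_genes = p$n_genes,
                          samples = sim_samples(n_per_group = p$n_per_group),
                          de_spec = list(fraction_de = p$fraction_de,
                                         log2fc_mean = 1, log2fc_sd = 0.25,
                                         prob_up = 0.5, affected_cell_types = NULL),
                          module_spec = mods)
        sim <- simulate_dataset(cfg, seed = stage_seed)
        write_counts_10x(sim$counts, file.path(config$out_dir, "simulated"))
        write_results(sim$truth$genes, file.path(config$out_dir, "sim_truth_genes.tsv"))
        state$counts <- sim$counts
        list(n_genes = nrow(sim$counts$counts), n_cells = ncol(sim$counts$counts))
      },
      qc = {
        if (is.null(state$counts)) stop("qc stage needs counts from a simulate stage")
        thr <- qc_thresholds(mode = p$mode, min_genes = p$min_genes,
                             max_genes = p$max_genes)
        filt <- filter_cells_genes(state$counts, thr)
        write_results(attr(filt, "qc_report"), file.path(config$out_dir, "qc_report.tsv"))
        norm <- normalize_log(filt)
        var_genes <- select_variable_genes(norm, n_top = min(p$n_var_genes, nrow(norm)))
        met <- qc_cell_metrics(filt)
        scaled <- regress_and_scale(norm[var_genes, , drop = FALSE],
                                    met[c("total_umi", "mito_ribo_fraction")])
        emb <- run_pca(scaled, n_pcs = min(p$n_pcs, length(var_genes)))
        cl <- cluster_cells(emb, k_neighbors = p$k_neighbors,
                            resolution = p$resolution, seed = stage_seed)
        filt$cell_meta$cluster <- unname(cl$cluster[filt$cell_meta$cell_id])
        state$counts <- filt
        state$embedding <- emb
        write_results(data.frame(cell_id = names(cl$cluster), cluster = cl$cluster),
                      file.path(config$out_dir, "clusters.tsv"))
        list(n_cells_kept = ncol(filt$counts), n_clusters = length(unique(cl$cluster)))
      },
      de = {
        if (is.null(state$counts)) stop("de stage needs counts")
        pb <- aggregate_pseudobulk(state$counts)
        res <- classify_degs(nb_wald_test(pb), lfc = p$lfc, fdr_max = p$fdr)
        write_results(res, file.path(config$out_dir, "de_results.tsv"))
        state$de <- res
        list(n_tested = sum(!is.na(res$p)),
             n_deg = sum(res$category %in% c("up", "down")))
      },
      downsample = {
        if (is.null(state$counts)) stop("downsample stage needs clustered counts")
        dd <- downsample_deg_distribution(state$counts, n_cells = p$n_cells,
                                          n_iter = p$n_iter, fdr = p$fdr,
                                          seed = stage_seed)
        if (!is.null(dd$summary)) {
          write_results(dd$summary, file.path(config$out_dir, "downsample_summary.tsv"))
        }
        list(clusters_tested = length(dd$counts), skipped = length(dd$skipped))
      },
      modules = {
        if (is.null(state$counts)) stop("modules stage needs counts")
        norm <- normalize_log(state$counts)
        var_genes <- select_variable_genes(norm, n_top = min(p$n_var_genes, nrow(norm)))
        expr <- t(as.matrix(norm[var_genes, , drop = FALSE]))
        pw <- pick_soft_threshold(expr)
        adj <- signed_adjacency(expr, pw$power)
        tom <- topological_overlap(adj)
        assignment <- cut_modules(tom$dissim, deep_split = p$deep_split,
                                  min_size = p$min_size)
        n_mods <- length(setdiff(unique(assignment), "grey"))
        out <- list(power = pw$power, n_modules = n_mods)
        write_results(data.frame(gene = names(assignment), module = assignment),
                      file.path(config$out_dir, "module_assignment.tsv"))
        if (n_mods >= 2) {
          merged <- merge_modules(expr, assignment, cut_height = p$merge_height)
          assignment <- merged$assignment
          me <- merged$eigengenes
        } else if (n_mods == 1) {
          me <- module_eigengenes(expr, assignment)
        } else {
          me <- NULL
        }
        if (!is.null(me)) {
          meta <- state$counts$cell_meta
          assoc <- module_trait_association(
            me, treatment = meta$group, sample = meta$sample_id,
            batch = if (length(unique(meta$batch)) > 1) meta$batch else NULL
          )
          write_results(assoc, file.path(config$out_dir, "module_trait.tsv"))
          out$n_significant <- sum(assoc$fdr < 0.05 & abs(assoc$beta) > 0.005)
        }
        out
      }
    )
    manifest$stages[[s]] <- c(list(seed = stage_seed, params = p), res)
    message(sprintf("[hypomod] stage %-10s done (%s)", s,
                    paste(names(res), unlist(res), sep = "=", collapse = ", ")))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(state = state, manifest = manifest))
}
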