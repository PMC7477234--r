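toy_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                1L, 3L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  count_matrix(Matrix::Matrix(m, sparse = TRUE),
               cell_meta = data.frame(cell_id = c("c1", "c2", "c3"),
                                      sample_id = c("s1", "s1", "s2"),
                                      group = c("treated", "treated", "control")))
}

test_that("pseudobulk aggregation sums counts per sample and conserves totals", {
  cm <- toy_counts()
  pb <- aggregate_pseudobulk(cm)
  expect_equal(pb$counts, matrix(c(5, 4, 2, 4), 2, 2,
                                 dimnames = list(c("g1", "g2"), c("s1", "s2"))))
  expect_equal(sum(pb$counts), sum(cm$counts))
  expect_identical(pb$design$group, c("treated", "control"))

  one_per_sample <- aggregate_pseudobulk(cm, cell_mask = c("c1", "c3"))
  expect_equal(unname(one_per_sample$counts[, "s1"]),
               as.numeric(cm$counts[, "c1"]))

  expect_error(aggregate_pseudobulk(cm, cell_mask = character(0)), "empty")
})

test_that("size factors follow the median-of-ratios rule", {
  m <- matrix(c(10, 20, 30, 40,
                20, 40, 60, 80), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  sf <- estimate_size_factors(m)
  # sample b is sample a doubled: factors sqrt(1/2) and sqrt(2) after
  # rescaling to geometric mean one
  expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  same <- cbind(a = c(3, 9, 1), b = c(3, 9, 1), c = c(3, 9, 1))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(same)), c(1, 1, 1))

  # hand-computed 4-gene toy
  toy <- matrix(c(10, 100, 4, 50,
                  20, 100, 8, 60), nrow = 4,
                dimnames = list(paste0("g", 1:4), c("a", "b")))
  geo <- exp(rowMeans(log(toy)))
  expected <- apply(toy / geo, 2, median)
  expected <- expected / exp(mean(log(expected)))
  expect_equal(estimate_size_factors(toy), expected)

  nz <- matrix(c(1, 0, 0, 2), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(estimate_size_factors(nz), "library-size")
})

test_that("the NB Wald engine agrees with a reference GLM fit", {
  skip_if_not_installed("MASS")
  set.seed(9)
  design <- data.frame(group = rep(c("control", "treated"), each = 4))
  mu <- rep(c(50, 120), each = 4)       # planted ~1.26 log2fc
  counts <- matrix(rnbinom(40 * 8, mu = rep(mu, each = 40), size = 10), 40, 8,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  sf <- estimate_size_factors(counts)
  res <- nb_wald_test(counts, design = design, size_factors = sf)
  for (g in c(1, 7, 23)) {
    alpha <- hypomod:::mom_dispersion(
      sweep(counts, 2, sf, "/"), design$group, 1 / sf
    )[g]
    fit <- suppressWarnings(stats::glm(
      counts[g, ] ~ design$group, offset = log(sf),
      family = MASS::negative.binomial(theta = 1 / alpha)
    ))
    expect_equal(res$log2fc[g], unname(coef(fit)[2]) / log(2), tolerance = 1e-4)
    # summary.glm estimates a dispersion scale for this family; divide it out
    # to compare pure Fisher-information standard errors
    se_fisher <- sqrt(diag(vcov(fit))[2] / summary(fit)$dispersion)
    expect_equal(res$se[g], unname(se_fisher) / log(2), tolerance = 1e-4)
  }
})

test_that("no-signal genes get zero fold change and all-zero genes are 'low'", {
  m <- matrix(7L, 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m[5, ] <- 0L
  res <- nb_wald_test(m, design = data.frame(group = rep(c("control", "treated"), 3)),
                      size_factors = setNames(rep(1, 6), colnames(m)))
  expect_equal(res$log2fc[1:4], rep(0, 4), tolerance = 1e-8)
  expect_identical(res$category[5], "low")
  expect_true(is.na(res$p[5]))
})

test_that("planted fold changes are recovered at adequate depth", {
  cfg <- sim_config(n_genes = 500,
                    cell_types = list(sim_cell_type("astro", 60, n_markers = 10)),
                    samples = sim_samples(n_per_group = 6, n_batches = 1),
                    de_spec = list(fraction_de = 0.1, log2fc_mean = 2, log2fc_sd = 0,
                                   prob_up = 1, affected_cell_types = NULL))
  sim <- simulate_dataset(cfg, seed = 12)
  res <- nb_wald_test(aggregate_pseudobulk(sim$counts))
  de <- sim$truth$genes$gene_id[sim$truth$genes$is_de]
  est <- mean(res$log2fc[match(de, res$gene)], na.rm = TRUE)
  expect_lt(abs(est - 2), 0.3)
})

test_that("fold-change estimates survive a global integer rescaling", {
  set.seed(3)
  counts <- matrix(rnbinom(200 * 6, mu = 40, size = 8), 200, 6,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  design <- data.frame(group = rep(c("control", "treated"), 3))
  r1 <- nb_wald_test(counts, design = design)
  r2 <- nb_wald_test(counts * 4L, design = design)
  expect_lt(median(abs(r1$log2fc - r2$log2fc), na.rm = TRUE), 0.05)
})

test_that("confounded designs are rejected with the columns named", {
  m <- matrix(5L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  design <- data.frame(group = c("control", "control", "treated", "treated"),
                       batch = c("b1", "b1", "b2", "b2"))
  expect_error(nb_wald_test(m, design = design), "full rank")
  expect_error(nb_wald_test(m, design = data.frame(group = c("control", "treated",
                                                             "treated", "treated"))),
               "2 samples")
})

test_that("volcano categories follow the published thresholds", {
  res <- data.frame(gene = paste0("g", 1:4),
                    log2fc = c(0.3, 0.3, -0.6, 0.1),
                    fdr = c(0.01, 0.06, 0.001, 0.2),
                    category = "ns")
  out <- classify_degs(res, lfc = 0.25, fdr_max = 0.05)
  expect_identical(out$category, c("up", "ns", "down", "ns"))

  out2 <- classify_degs(res, lfc = 0.5, fdr_max = 0.05)
  expect_identical(out2$category, c("ns", "ns", "down", "ns"))
})

test_that("BH adjustment is monotone along sorted p-values", {
  set.seed(2)
  counts <- matrix(rnbinom(100 * 6, mu = 30, size = 5), 100, 6,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  res <- nb_wald_test(counts, design = data.frame(group = rep(c("control", "treated"), 3)))
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12, na.rm = TRUE))
})

test_that("downsampling distributions are seeded, sized, and skip thin clusters", {
  cfg <- sim_config(n_genes = 120,
                    cell_types = list(sim_cell_type("astro", 30, n_markers = 10),
                                      sim_cell_type("rare", 3, n_markers = 10)),
                    samples = sim_samples(n_per_group = 2, n_batches = 1))
  sim <- simulate_dataset(cfg, seed = 5)
  cm <- sim$counts
  cm$cell_meta$cluster <- cm$cell_meta$truth_type
  expect_warning(
    dd <- downsample_deg_distribution(cm, n_cells = 10, n_iter = 3, fdr = 0.1, seed = 2),
    "skipped"
  )
  expect_named(dd$counts, "astro")
  expect_length(dd$counts$astro, 3)
  expect_identical(dd$skipped, "rare")

  dd1 <- suppressWarnings(
    downsample_deg_distribution(cm, n_cells = 10, n_iter = 1, fdr = 0.1, seed = 2)
  )
  expect_length(dd1$counts$astro, 1)
  expect_identical(dd1$summary$median, as.numeric(dd1$counts$astro))

  dd2 <- suppressWarnings(
    downsample_deg_distribution(cm, n_cells = 10, n_iter = 3, fdr = 0.1, seed = 2)
  )
  expect_identical(dd$counts, dd2$counts)
})

test_that("abundance testing matches the closed-form Student t", {
  tab <- rbind(k1 = c(10, 11, 9, 20, 21, 19),
               k2 = c(5, 5, 5, 5, 5, 5))
  colnames(tab) <- paste0("m", 1:6)
  grp <- setNames(rep(c("treated", "control"), each = 3), colnames(tab))
  res <- abundance_test(tab, grp)

  x <- c(10, 11, 9); y <- c(20, 21, 19)
  sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t[1], t_hand, tolerance = 1e-12)
  expect_equal(res$p[1], 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)

  expect_equal(res$p[2], 1)           # constant counts, equal means
  expect_equal(res$p_adj, pmin(1, res$p * 2))

  six <- tab[rep(1, 6), ]
  rownames(six) <- paste0("k", 1:6)
  res6 <- abundance_test(six, grp)
  expect_equal(res6$p_adj, pmin(1, res6$p * 6))
})
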