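# builds a CountMatrix whose cells detect exactly the requested gene numbers
counts_with_detected <- function(detected, n_genes = max(detected) + 100) {
  m <- matrix(0L, n_genes, length(detected),
              dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                              sprintf("c%03d", seq_along(detected))))
  for (j in seq_along(detected)) m[seq_len(detected[j]), j] <- 1L
  count_matrix(Matrix::Matrix(m, sparse = TRUE))
}

test_that("barcode calling applies the 10%-of-99th-percentile rule", {
  # derived case: 100 real cells at 1000 UMIs, 900 ambient barcodes at 5
  totals <- setNames(c(rep(1000, 100), rep(5, 900)), sprintf("b%04d", 1:1000))
  kept <- call_barcodes(totals, expected_cells = 100)
  expect_setequal(kept, sprintf("b%04d", 1:100))

  # uniform totals: threshold 0.1c < c keeps everything
  uni <- setNames(rep(50, 20), letters[1:20])
  expect_setequal(call_barcodes(uni, 10), letters[1:20])

  # single barcode above its own scaled percentile
  expect_identical(call_barcodes(c(only = 10), 1), "only")

  expect_warning(call_barcodes(uni, 100), "expected_cells")
  expect_error(call_barcodes(numeric(0), 1), "no barcodes")
})

test_that("detected-gene bounds are inclusive at 400 and 4000", {
  cm <- counts_with_detected(c(399, 400, 4000, 4001), n_genes = 4100)
  kept <- filter_cells_genes(cm, qc_thresholds("single_cell", min_cells_per_gene = 1))
  expect_setequal(colnames(kept$counts), c("c002", "c003"))
})

test_that("the mito+ribo fraction ceiling switches between modes", {
  n_genes <- 1100
  gm <- data.frame(gene_id = sprintf("g%04d", 1:n_genes),
                   is_mito = seq_len(n_genes) <= 30, is_ribo = FALSE)
  # mito UMI shares: 3%, 12%, 27% on totals of ~1000
  m <- matrix(0L, n_genes, 3,
              dimnames = list(gm$gene_id, c("lo", "mid", "hi")))
  m[1:30, "lo"] <- 1L;  m[31:(30 + 970), "lo"] <- 1L      # 30 / 1000 = 3%
  m[1:30, "mid"] <- 4L; m[31:(30 + 880), "mid"] <- 1L     # 120 / 1000 = 12%
  m[1:30, "hi"] <- 9L;  m[31:(30 + 730), "hi"] <- 1L      # 270 / 1000 = 27%
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE), gene_meta = gm)

  sc <- filter_cells_genes(cm, qc_thresholds("single_cell", min_genes = 10,
                                             min_cells_per_gene = 1))
  expect_setequal(colnames(sc$counts), c("lo", "mid"))     # > 20% dropped

  sn <- filter_cells_genes(cm, qc_thresholds("single_nucleus", min_genes = 10,
                                             min_cells_per_gene = 1))
  expect_setequal(colnames(sn$counts), "lo")               # > 5% dropped
})

test_that("gene floor is 10 cells (single-cell) and 5 (single-nucleus), inclusive", {
  n_cells <- 20
  m <- matrix(0L, 3, n_cells,
              dimnames = list(c("in9", "in10", "in5"), sprintf("c%02d", 1:n_cells)))
  m["in9", 1:9] <- 1L
  m["in10", 1:10] <- 1L
  m["in5", 1:5] <- 1L
  filler <- matrix(1L, 500, n_cells,
                   dimnames = list(sprintf("f%03d", 1:500), colnames(m)))
  cm <- count_matrix(Matrix::Matrix(rbind(m, filler), sparse = TRUE))
  sc <- filter_cells_genes(cm, qc_thresholds("single_cell", min_genes = 10))
  expect_true("in10" %in% rownames(sc$counts))
  expect_false("in9" %in% rownames(sc$counts))
  sn <- filter_cells_genes(cm, qc_thresholds("single_nucleus", min_genes = 10))
  expect_true(all(c("in5", "in9", "in10") %in% rownames(sn$counts)))
})

test_that("cell/gene filtering is idempotent and fails when nothing survives", {
  cfg <- separable_config(n_genes = 400, cells = 30, markers = 10)
  sim <- simulate_dataset(cfg, seed = 3)
  thr <- qc_thresholds("single_cell", min_genes = 50)
  once <- filter_cells_genes(sim$counts, thr)
  twice <- filter_cells_genes(once, thr)
  expect_identical(dim(once$counts), dim(twice$counts))
  expect_true(all(once$counts == twice$counts))

  expect_error(
    filter_cells_genes(sim$counts, qc_thresholds("single_cell", min_genes = 399,
                                                 max_genes = 400)),
    "every cell"
  )
})

test_that("log-normalization has its closed-form and invariance properties", {
  m <- matrix(c(0L, 1L, 9999L, 0L, 5L, 5L), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE))
  norm <- normalize_log(cm, scale = 1e4)
  expect_equal(as.numeric(norm["g1", "c1"]), 0)
  expect_equal(as.numeric(norm["g2", "c1"]), log(2))   # 1e4 * 1 / 1e4

  doubled <- count_matrix(Matrix::Matrix(m * 2L, sparse = TRUE))
  expect_equal(as.matrix(normalize_log(doubled)), as.matrix(norm))

  zero <- matrix(c(1L, 0L), 1, 2, dimnames = list("g", c("ok", "empty")))
  expect_error(normalize_log(count_matrix(Matrix::Matrix(zero, sparse = TRUE))),
               "empty")
})

test_that("variable-gene ranking finds planted overdispersed genes", {
  set.seed(11)
  n_genes <- 200
  lam <- rlnorm(n_genes, log(2), 0.6)     # heterogeneous background means
  m <- matrix(rpois(n_genes * 100, rep(lam, 100)), n_genes, 100)
  hot <- seq(5, 185, by = 20)             # bursty genes across the mean range
  for (i in hot) {
    burst <- rbinom(100, 1, 0.25)
    m[i, ] <- rpois(100, lam[i] * 0.75) + burst * rpois(100, 4 * lam[i])
  }
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes), sprintf("c%03d", 1:100))
  cm <- count_matrix(Matrix::Matrix(m, sparse = TRUE))
  norm <- normalize_log(cm)
  top <- select_variable_genes(norm, 10)
  expect_gte(length(intersect(top, sprintf("g%03d", hot))), 8)

  # a constant gene is never selected while varying genes remain
  m2 <- m
  m2[20, ] <- 3L
  norm2 <- normalize_log(count_matrix(Matrix::Matrix(m2, sparse = TRUE)))
  expect_false("g020" %in% select_variable_genes(norm2, 150))

  expect_identical(sort(select_variable_genes(norm, n_genes)),
                   sort(rownames(norm)))
  expect_warning(select_variable_genes(norm, n_genes + 5), "all genes")
})

test_that("covariate regression equals the normal-equations oracle on a toy", {
  set.seed(2)
  norm <- matrix(rnorm(5 * 4), 4, 5,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  cov <- data.frame(total = c(10, 12, 9, 15, 11), frac = c(.1, .2, .15, .05, .12))
  scaled <- regress_and_scale(norm, cov, clip = 10)
  X <- cbind(1, as.matrix(cov))
  for (g in 1:4) {
    beta <- solve(t(X) %*% X, t(X) %*% norm[g, ])
    r <- norm[g, ] - drop(X %*% beta)
    expect_equal(unname(scaled[g, ]), unname((r - mean(r)) / sd(r)), tolerance = 1e-10)
  }
})

test_that("regression handles orthogonal and constant covariates", {
  set.seed(3)
  y <- rnorm(50)
  ortho <- unname(residuals(lm(rnorm(50) ~ y)))   # exactly uncorrelated with y
  norm <- rbind(g1 = y)
  colnames(norm) <- paste0("c", 1:50)
  out <- regress_and_scale(norm, data.frame(v = ortho))
  # zero projection: residuals are the centered values, then unit-scaled
  expect_equal(unname(out["g1", ]),
               unname(scale(residuals(lm(y ~ ortho)))[, 1]), tolerance = 1e-8)

  expect_warning(regress_and_scale(norm, data.frame(v = ortho, k = rep(1, 50))),
                 "constant")
})

test_that("PCA is exact, ordered, and reconstructs the input", {
  set.seed(4)
  line <- rbind(x = 1:40 + rnorm(40, 0, 1e-6), y = 2 * (1:40))
  colnames(line) <- paste0("c", 1:40)
  emb <- run_pca(line - rowMeans(line), n_pcs = 2)
  expect_gt(emb$explained_variance[1], 0.999)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))

  sc <- matrix(rnorm(20 * 30), 20, 30,
               dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
  sc <- sc - rowMeans(sc)
  emb2 <- run_pca(sc, n_pcs = 20)
  recon <- emb2$coordinates %*% t(emb2$loadings)
  expect_equal(unname(recon), unname(t(sc)), tolerance = 1e-6)
  expect_warning(run_pca(sc, n_pcs = 25), "truncated")
})

test_that("graph clustering separates well-separated blobs and is deterministic", {
  set.seed(5)
  blobs <- rbind(cbind(rnorm(120), rnorm(120)), cbind(rnorm(120) + 12, rnorm(120)))
  rownames(blobs) <- paste0("c", 1:240)
  cl <- cluster_cells(blobs, k_neighbors = 20, resolution = 0.1, seed = 1)
  truth <- rep(c("A", "B"), each = 120)
  expect_length(unique(cl$cluster), 2)
  expect_gte(adjusted_rand(cl$cluster, truth), 0.999)

  cl2 <- cluster_cells(blobs, k_neighbors = 20, resolution = 0.1, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  tiny <- cluster_cells(blobs, k_neighbors = 20, resolution = 1e-4, seed = 1)
  expect_length(unique(tiny$cluster), 2)  # disconnected blobs never merge

  expect_error(cluster_cells(blobs[1:10, ], k_neighbors = 10), "smaller")
})

test_that("end-to-end clustering recovers planted cell types", {
  cfg <- separable_config(n_types = 3, n_genes = 300, cells = 30,
                          markers = 40, lfc = 4)
  sim <- simulate_dataset(cfg, seed = 7)
  norm <- normalize_log(sim$counts)
  vg <- select_variable_genes(norm, 150)
  met <- attr(filter_cells_genes(sim$counts, qc_thresholds("single_cell", min_genes = 10,
                                                           min_cells_per_gene = 1)),
              "qc_report")
  scaled <- regress_and_scale(norm[vg, ], met[c("total_umi", "mito_ribo_fraction")])
  emb <- run_pca(scaled, n_pcs = 10)
  # 0.3 on igraph's resolution scale corresponds to coarse typing
  cl <- cluster_cells(emb, k_neighbors = 20, resolution = 0.3, seed = 1)
  expect_gte(adjusted_rand(cl$cluster, sim$counts$cell_meta$truth_type), 0.9)
})

test_that("silhouettes match a brute-force pairwise computation", {
  pts <- matrix(c(0, 0, 0, 1, 1, 0, 5, 5, 5, 6, 6, 5), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("p", 1:6)
  cl <- c(1, 1, 1, 2, 2, 2)
  sil <- silhouette_widths(pts, cl)
  d <- as.matrix(dist(pts))
  for (i in 1:6) {
    own <- setdiff(which(cl == cl[i]), i)
    a <- mean(d[i, own])
    b <- min(sapply(setdiff(unique(cl), cl[i]), function(k) mean(d[i, cl == k])))
    expect_equal(unname(sil[i]), (b - a) / max(a, b), tolerance = 1e-12)
  }
  expect_true(all(sil > 0))
  expect_setequal(silhouette_filter(pts, setNames(cl, rownames(pts))), rownames(pts))
})

test_that("cells nearer a foreign cluster are removed by the silhouette filter", {
  pts <- rbind(matrix(rnorm(40, 0, .2), 20, 2),
               matrix(rnorm(40, 5, .2), 20, 2),
               c(5, 5))  # labeled 1 but sitting inside cluster 2
  rownames(pts) <- paste0("p", 1:41)
  cl <- setNames(c(rep(1, 20), rep(2, 20), 1), rownames(pts))
  kept <- silhouette_filter(pts, cl)
  expect_false("p41" %in% kept)
  expect_length(kept, 40)
})

test_that("singleton clusters get silhouette zero with a warning", {
  pts <- matrix(c(0, 0, 0, 1, 9, 9), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("p", 1:3)
  expect_warning(sil <- silhouette_widths(pts, c(1, 1, 2)), "singleton")
  expect_equal(unname(sil[3]), 0)
})

test_that("sample domination is flagged at and above one half", {
  cl <- setNames(rep("k0", 10), paste0("c", 1:10))
  smp <- setNames(c(rep("s1", 6), rep("s2", 4)), names(cl))
  expect_identical(flag_sample_dominated_clusters(cl, smp), "k0")

  smp5 <- setNames(c(rep("s1", 5), rep("s2", 5)), names(cl))
  expect_identical(flag_sample_dominated_clusters(cl, smp5), "k0")  # boundary

  even <- setNames(rep(c("s1", "s2", "s3", "s4"), length.out = 12), paste0("c", 1:12))
  cl2 <- setNames(rep("k0", 12), names(even))
  expect_length(flag_sample_dominated_clusters(cl2, even), 0)

  one <- setNames(rep("s1", 10), names(cl))
  expect_warning(out <- flag_sample_dominated_clusters(cl, one), "single-sample")
  expect_identical(out, "k0")
})
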