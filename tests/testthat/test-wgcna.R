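# brute-force TOM for the oracle-equivalence checks
tom_bruteforce <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  out
}

test_that("signed adjacency has its closed forms and monotonicity", {
  x <- seq(-1, 1, length.out = 20)
  expr <- cbind(a = x, b = x, c = -x, d = x * 0 + rnorm(20))
  suppressWarnings(adj6 <- signed_adjacency(expr[, 1:3], 6))
  expect_equal(adj6["a", "b"], 1)                      # cor  1 -> 1
  expect_equal(adj6["a", "c"], 0, tolerance = 1e-12)   # cor -1 -> 0
  set.seed(1)
  e2 <- cbind(u = rnorm(2000), v = rnorm(2000))
  a1 <- signed_adjacency(e2, 1); a6 <- signed_adjacency(e2, 6)
  expect_equal(a6["u", "v"], a1["u", "v"]^6, tolerance = 1e-12)
  expect_lt(a6["u", "v"], a1["u", "v"])                # monotone in power
  expect_lt(abs(a6["u", "v"] - 0.5^6), 0.01)           # cor ~ 0 -> (1/2)^6

  const <- cbind(g = rep(1, 20), h = x)
  expect_warning(az <- signed_adjacency(const, 2), "zero-variance")
  expect_equal(az["g", "h"], 0.25)                     # cor treated as 0
})

test_that("topological overlap matches the double-loop oracle to 1e-12", {
  set.seed(7)
  for (rep in 1:3) {
    cc <- cor(matrix(rnorm(50 * 20), 50, 20))
    adj <- ((1 + cc) / 2)^4
    diag(adj) <- 1
    tom <- topological_overlap(adj)$tom
    expect_equal(unname(tom), tom_bruteforce(adj), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
  }

  # 2-gene network: no shared neighbors, TOM equals the adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(topological_overlap(a2)$tom[1, 2], 0.3, tolerance = 1e-12)

  # identical fully-connected rows: maximal overlap
  a3 <- matrix(1, 4, 4)
  expect_equal(unique(as.vector(topological_overlap(a3)$tom)), 1)
})

test_that("soft-threshold selection reaches scale-free fit on modular count data", {
  # regression fixture: simulated counts with three planted modules reach the
  # scale-free target at a low power; Gaussian equicorrelated blocks do not
  # (their connectivity distribution is bimodal, not scale-free)
  sim <- simulate_dataset(module_chain_config(), seed = 2)
  norm <- normalize_log(sim$counts)
  expr <- t(as.matrix(norm[select_variable_genes(norm, 150), ]))
  pw <- pick_soft_threshold(expr)
  expect_true(pw$converged)
  expect_lte(pw$power, 12)
  expect_gte(max(pw$table$rsq[!pw$table$discarded & pw$table$slope < 0]), 0.8)
  # mean connectivity never increases with power
  expect_true(all(diff(pw$table$mean_connectivity) < 0))
})

test_that("pure-noise expression falls back to the best-fit power with a warning", {
  expr <- make_blocks(9, 120, 100, sizes = integer(0))
  expect_warning(pw <- pick_soft_threshold(expr), "falling back")
  expect_false(pw$converged)
  expect_true(pw$power %in% 1:30)
})

test_that("dendrogram cutting recovers planted blocks and greys noise", {
  # two clean 50-gene blocks: exact recovery
  expr2 <- make_blocks(42, 200, 100, c(50, 50))
  tom2 <- topological_overlap(signed_adjacency(expr2, 6))
  asg2 <- cut_modules(tom2$dissim, deep_split = 4)
  truth2 <- rep(c("A", "B"), each = 50)
  expect_length(setdiff(unique(asg2), "grey"), 2)
  expect_gte(rand_index(asg2, truth2), 0.95)

  # 14/20/50 blocks against 216 noise genes: the 14-gene block and the noise
  # are grey, and no emitted module is smaller than min_size
  expr3 <- make_blocks(1, 200, 300, c(14, 20, 50))
  pw <- suppressWarnings(pick_soft_threshold(expr3))
  tom3 <- topological_overlap(signed_adjacency(expr3, pw$power))
  asg3 <- suppressWarnings(cut_modules(tom3$dissim, deep_split = 4, min_size = 15))
  sizes <- table(asg3)[setdiff(unique(asg3), "grey")]
  expect_gte(min(sizes), 15)
  expect_true(all(asg3[1:14] == "grey"))
  expect_true(all(asg3[85:300] == "grey"))

  # pure noise: everything grey, with a warning
  expr4 <- make_blocks(9, 150, 120, integer(0))
  pw4 <- suppressWarnings(pick_soft_threshold(expr4))
  tom4 <- topological_overlap(signed_adjacency(expr4, pw4$power))
  expect_warning(asg4 <- cut_modules(tom4$dissim), "grey")
  expect_true(all(asg4 == "grey"))
})

test_that("finer deep-split never yields fewer modules on the block fixture", {
  expr <- make_blocks(3, 200, 300, c(14, 20, 50))
  tom <- topological_overlap(signed_adjacency(expr, 8))
  n2 <- length(setdiff(unique(suppressWarnings(cut_modules(tom$dissim, deep_split = 2))), "grey"))
  n4 <- length(setdiff(unique(suppressWarnings(cut_modules(tom$dissim, deep_split = 4))), "grey"))
  expect_gte(n4, n2)
})

test_that("eigengenes are unit-norm, oriented, and capture a planted factor", {
  set.seed(5)
  f <- rnorm(300)
  expr <- sapply(1:20, function(i) f + rnorm(300, 0, 0.5))
  colnames(expr) <- paste0("g", 1:20)
  asg <- setNames(rep("M1", 20), colnames(expr))
  me <- module_eigengenes(expr, asg)
  expect_equal(sum(me[, "M1"]^2), 1, tolerance = 1e-10)
  expect_gte(cor(me[, "M1"], rowMeans(scale(expr))), 0)
  expect_gt(abs(cor(me[, "M1"], f)), 0.9)
  # PC1 of a single-factor module explains most of the variance
  ev <- svd(scale(expr))$d^2
  expect_gte(ev[1] / sum(ev), 0.5)

  # perfectly correlated members: eigengene proportional to any member
  expr_perfect <- sapply(1:5, function(i) 2 * f + 3)
  colnames(expr_perfect) <- paste0("p", 1:5)
  me_p <- module_eigengenes(expr_perfect, setNames(rep("M1", 5), colnames(expr_perfect)))
  expect_equal(abs(cor(me_p[, 1], f)), 1, tolerance = 1e-10)
})

test_that("module merging happens exactly at eigengene correlation 0.8", {
  n <- 200
  u <- rep(c(1, -1), length.out = n); u <- (u - mean(u)) / sd(u)
  v <- rep(c(1, 1, -1, -1), length.out = n)
  v <- residuals(lm(v ~ u)); v <- (v - mean(v)) / sd(v)
  make_expr <- function(r) {
    e2 <- r * u + sqrt(1 - r^2) * v
    expr <- cbind(matrix(rep(u, 20), ncol = 20), matrix(rep(e2, 20), ncol = 20))
    colnames(expr) <- sprintf("g%02d", 1:40)
    expr
  }
  asg <- setNames(rep(c("M1", "M2"), each = 20), sprintf("g%02d", 1:40))
  n_after <- vapply(c(0.75, 0.79, 0.80, 0.81, 0.85), function(r) {
    merged <- merge_modules(make_expr(r), asg, cut_height = 0.2)
    length(setdiff(unique(merged$assignment), "grey"))
  }, 0L)
  expect_identical(n_after, c(2L, 2L, 1L, 1L, 1L))

  # cut_height 0 merges only perfectly correlated eigengenes
  merged0 <- merge_modules(make_expr(1), asg, cut_height = 0)
  expect_length(setdiff(unique(merged0$assignment), "grey"), 1)
  merged0b <- merge_modules(make_expr(0.999), asg, cut_height = 0)
  expect_length(setdiff(unique(merged0b$assignment), "grey"), 2)
})

test_that("kME equals gene-eigengene Pearson correlation", {
  set.seed(6)
  expr <- make_blocks(6, 100, 60, c(20, 20))
  asg <- setNames(c(rep("M1", 20), rep("M2", 20), rep("grey", 20)), colnames(expr))
  me <- module_eigengenes(expr, asg)
  kme <- compute_kme(expr, me)
  for (g in c(1, 25, 50)) {
    for (m in 1:2) {
      expect_equal(kme[g, m], cor(expr[, g], me[, m]), tolerance = 1e-12)
    }
  }
  # members correlate more with their own module than with the other
  expect_true(all(kme[1:20, "M1"] > kme[1:20, "M2"]))
  expect_true(all(kme[21:40, "M2"] > kme[21:40, "M1"]))

  expr_z <- cbind(expr, zz = rep(1, 100))
  expect_warning(kz <- compute_kme(expr_z, me), "zero-variance")
  expect_equal(unname(kz["zz", ]), c(0, 0))
})

test_that("the mixed model reduces to the group mean difference without sample variance", {
  set.seed(8)
  n_s <- 8
  sample <- rep(sprintf("s%d", 1:n_s), each = 40)
  grp <- ifelse(as.integer(sub("s", "", sample)) <= 4, "treated", "control")
  y <- rnorm(length(sample), 0, 0.3)   # no sample-level variance at all
  fit <- module_trait_lmm(y, grp, sample)
  ols <- mean(y[grp == "treated"]) - mean(y[grp == "control"])
  expect_equal(fit$beta, ols, tolerance = 1e-6)
})

test_that("a planted sample-level treatment shift is recovered by the mixed model", {
  set.seed(9)
  n_s <- 12
  sample <- rep(sprintf("s%02d", 1:n_s), each = 200)
  grp <- ifelse(as.integer(sub("s", "", sample)) <= 6, "treated", "control")
  b <- rnorm(n_s, 0, 0.05)
  beta_true <- 0.4
  y <- b[as.integer(factor(sample))] + beta_true * (grp == "treated") + rnorm(length(sample))
  fit <- module_trait_lmm(y, grp, sample)
  expect_lt(abs(fit$beta - beta_true) / beta_true, 0.25)
  expect_lt(fit$p, 0.05)
})

test_that("module-module overlap p-values match exhaustive enumeration", {
  universe <- letters[1:12]
  a <- setNames(c(rep("A1", 5), rep("grey", 7)), universe)
  b <- setNames(c(rep("B1", 3), rep("grey", 4), rep("B2", 5)), universe)
  res <- module_overlap_hypergeom(a, b, universe)
  # enumeration: P(overlap >= observed) for drawing |B| genes from 12
  enum_p <- function(size_a, size_b, obs) {
    sum(sapply(obs:min(size_a, size_b), function(k) {
      choose(size_a, k) * choose(12 - size_a, size_b - k)
    })) / choose(12, size_b)
  }
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 enum_p(res$size_a[i], res$size_b[i], res$overlap[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$p_adj, pmin(1, res$p * nrow(res)))

  # identical 15-gene modules in a 1000-gene universe are astronomically unlikely
  uni <- sprintf("u%04d", 1:1000)
  mod <- setNames(c(rep("M", 15), rep("grey", 985)), uni)
  same <- module_overlap_hypergeom(mod, mod, uni)
  expect_lt(same$p, 1e-20)

  # fully disjoint modules: observed overlap 0 gives p = 1
  d1 <- setNames(c(rep("X", 5), rep("grey", 7)), universe)
  d2 <- setNames(c(rep("grey", 5), rep("Y", 5), rep("grey", 2)), universe)
  expect_equal(module_overlap_hypergeom(d1, d2, universe)$p, 1)

  expect_error(module_overlap_hypergeom(a, b, character(0)), "universe")
})
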