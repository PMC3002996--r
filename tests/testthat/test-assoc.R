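test_that("change matrices subtract day 0 on both layers", {
  d <- shared_sim()
  b <- bin_profiles(d$probe_table)
  ch <- build_changes(b, d$expr_table)
  expect_equal(colnames(ch$A), c("day1", "day3", "day5"))
  expect_identical(rownames(ch$A), rownames(ch$E))
  # hand check one gene on one day
  g <- ch$genes[3]
  expr <- average_replicates(d$expr_table)
  e0 <- expr$expression[expr$gene_id == g & expr$day == 0]
  e5 <- expr$expression[expr$gene_id == g & expr$day == 5]
  expect_equal(unname(ch$E[g, "day5"]), e5 - e0)
  m0 <- profile_matrix(b, 0)
  m5 <- profile_matrix(b, 5)
  expect_equal(unname(ch$A[g, "day5"]), mean(m5[g, ]) - mean(m0[g, ]))
  expect_equal(unname(ch$profiles$day5[g, ]), unname(m5[g, ] - m0[g, ]))
  # identical expression on all days -> E all zero
  flat <- d$expr_table
  flat$expression <- ave(flat$expression, flat$gene_id)
  chf <- build_changes(b, flat)
  expect_true(all(abs(chf$E) < 1e-12))
  # mean and median summaries differ on skewed profiles
  chm <- build_changes(b, d$expr_table, summary = "median")
  expect_false(isTRUE(all.equal(ch$A, chm$A)))
})

test_that("correlation matrix hits the exact diagonal for constructed data", {
  d <- shared_sim()
  b <- bin_profiles(d$probe_table)
  ch <- build_changes(b, d$expr_table)
  ch$E <- ch$A
  r <- correlation_matrix(ch)$r
  expect_equal(unname(diag(r)), rep(1, 3))
  ch$E <- -ch$A
  expect_equal(unname(diag(correlation_matrix(ch)$r)), rep(-1, 3))
  # independent columns stay near zero
  set.seed(10)
  ch$A <- matrix(rnorm(10000 * 3), ncol = 3,
                 dimnames = list(NULL, colnames(ch$A)))
  ch$E <- matrix(rnorm(10000 * 3), ncol = 3,
                 dimnames = list(NULL, colnames(ch$E)))
  expect_true(all(abs(correlation_matrix(ch)$r) < 0.03))
})

test_that("zero-variance columns are flagged undefined, not fabricated", {
  ch <- structure(list(
    A = matrix(c(1, 1, 1, 1, 1:4), ncol = 2,
               dimnames = list(NULL, c("day1", "day3"))),
    E = matrix(rnorm(8), ncol = 2,
               dimnames = list(NULL, c("day1", "day3"))),
    days = c(1, 3)), class = "change_matrices")
  r <- correlation_matrix(ch)$r
  expect_true(all(is.na(r["day1", ])))
  expect_true(all(!is.na(r["day3", ])))
})

test_that("joint gene-relabelling permutation finds coupled days extreme", {
  d <- simulate_dataset(sim_config(n_genes = 1000, n_control_probes = 300,
                                   seed = 14))
  b <- bin_profiles(d$probe_table)
  ch <- build_changes(b, d$expr_table)
  rep <- permutation_significance(ch, "pearson", n_perm = 199, seed = 3)
  expect_equal(rep$p_perm["day5", "day5"], 1 / 200)
  expect_error(permutation_significance(ch, n_perm = 0), "n_perm")
  # determinism
  rep2 <- permutation_significance(ch, "pearson", n_perm = 199, seed = 3)
  expect_identical(rep$p_perm, rep2$p_perm)
})

test_that("permutation p-values are roughly uniform on uncoupled data", {
  d <- simulate_dataset(sim_config(n_genes = 300, n_control_probes = 300,
                                   coupling_by_day = c(0, 0, 0, 0), seed = 2))
  b <- bin_profiles(d$probe_table)
  ch <- build_changes(b, d$expr_table)
  ps <- vapply(1:40, function(s) {
    chs <- ch
    set.seed(s)
    chs$E <- ch$E[sample(nrow(ch$E)), , drop = FALSE]
    permutation_significance(chs, "pearson", n_perm = 100,
                             seed = s + 500)$p_perm["day5", "day5"]
  }, 1)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("1-d canonical correlation equals the regression oracle", {
  set.seed(20)
  X <- matrix(rnorm(400 * 14), ncol = 14)
  beta <- rnorm(14)
  y <- drop(X %*% beta) + rnorm(400)
  cc <- cca_1d(X, y)
  r2 <- summary(lm(y ~ X))$r.squared
  expect_equal(cc$rho^2, r2, tolerance = 1e-10)
  # canonical correlation dominates the mean-summary correlation
  expect_gte(cc$rho, abs(cor(rowMeans(X), y)))
  # canonical variate has unit variance
  expect_equal(sd(scale(X, scale = FALSE) %*% cc$weights), 1,
               tolerance = 1e-8)
})

test_that("cca_1d recovers a single informative bin exactly", {
  set.seed(21)
  X <- matrix(rnorm(300 * 14), ncol = 14)
  y <- X[, 7]
  cc <- cca_1d(X, y)
  expect_equal(cc$rho, 1, tolerance = 1e-8)
  w <- cc$weights / cc$weights[7]
  expect_true(all(abs(w[-7]) < 1e-8))
  # independent X, y stay near zero at n = 10000
  Xn <- matrix(rnorm(10000 * 14), ncol = 14)
  expect_lt(cca_1d(Xn, rnorm(10000))$rho, 0.08)
})

test_that("partial correlations match the direct-inversion oracle at lambda 0", {
  set.seed(30)
  # known 3-variable chain: x2 depends on x1, x3 on x2
  n <- 2000
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, 0, 0.6)
  x3 <- 0.7 * x2 + rnorm(n, 0, 0.7)
  X <- cbind(x1, x2, x3)
  res <- shrinkage_pcor(X, lambda = 0)
  omega <- solve(cov(X))
  oracle <- -omega / sqrt(tcrossprod(diag(omega)))
  diag(oracle) <- 1
  expect_equal(unname(res$pcor), unname(oracle), tolerance = 1e-6)
  expect_true(isSymmetric(res$pcor))
  expect_equal(unname(diag(res$pcor)), rep(1, 3))
  # conditioning removes the indirect x1-x3 association
  expect_gt(abs(res$pcor[1, 2]), 0.5)
  expect_lt(abs(res$pcor[1, 3]), 0.1)
})

test_that("shrinkage keeps null partial correlations near zero", {
  set.seed(31)
  X <- matrix(rnorm(5000 * 10), ncol = 10)
  res <- shrinkage_pcor(X)
  off <- res$pcor[upper.tri(res$pcor)]
  expect_true(all(abs(off) < 0.05))
  expect_true(res$lambda >= 0 && res$lambda <= 1)
  # forcing lambda 0 with fewer rows than columns must fail
  expect_error(shrinkage_pcor(matrix(rnorm(10 * 20), 10), lambda = 0),
               "shrinkage")
})

test_that("AR(1) chain edges are recovered with high precision and recall", {
  set.seed(32)
  n <- 5000
  p <- 20
  X <- matrix(0, n, p)
  X[, 1] <- rnorm(n)
  for (k in 2:p) X[, k] <- 0.7 * X[, k - 1] + rnorm(n)
  colnames(X) <- paste0("v", 1:p)
  res <- shrinkage_pcor(X)
  edges <- pcor_edges(res, cutoff = 0.05)
  got <- paste(edges$var_a, edges$var_b)
  truth <- paste(paste0("v", 1:(p - 1)), paste0("v", 2:p))
  precision <- mean(got %in% truth)
  recall <- mean(truth %in% got)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # adjacent pairs dominate non-adjacent ones
  adj <- abs(res$pcor[cbind(1:(p - 1), 2:p)])
  nonadj <- abs(res$pcor[cbind(1:(p - 2), 3:p)])
  expect_gt(min(adj), max(nonadj))
  # lowering the cutoff never adds edges
  stricter <- pcor_edges(res, cutoff = 0.01)
  expect_true(all(paste(stricter$var_a, stricter$var_b) %in% got))
})

test_that("an all-noise matrix yields an empty graph", {
  set.seed(33)
  X <- matrix(rnorm(800 * 8), ncol = 8)
  edges <- pcor_edges(shrinkage_pcor(X), cutoff = 0.05)
  expect_lte(nrow(edges), 1L)
})

test_that("group differences subtract elementwise and check labels", {
  set.seed(34)
  X <- matrix(rnorm(500 * 6), ncol = 6, dimnames = list(NULL, paste0("v", 1:6)))
  a <- shrinkage_pcor(X, group = "diff")
  b <- shrinkage_pcor(X[1:250, ], group = "nondiff")
  expect_true(all(group_difference(a, a) == 0))
  expect_equal(group_difference(a, b), -group_difference(b, a))
  bad <- b
  bad$labels <- paste0("w", 1:6)
  expect_error(group_difference(a, bad), "labels")
})

test_that("stacked profiles carry bin-by-day variable labels", {
  d <- shared_sim()
  b <- bin_profiles(d$probe_table)
  S <- stack_profiles(b)
  expect_equal(ncol(S), 42L)
  expect_equal(colnames(S)[1], "b1.d1")
  expect_equal(colnames(S)[42], "b14.d5")
  expect_equal(nrow(S), length(unique(b$gene_id)))
})
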