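test_that("variable-gene selection ranks by variance with id tie-breaks", {
  m <- expr_matrix(matrix(5, 4, 6, dimnames = list(c("d", "b", "a", "c"),
                                                   sprintf("s%d", 1:6))),
                   unit = "log2TPM1")
  expect_equal(select_variable_genes(m, 4), c("a", "b", "c", "d"))

  vals <- matrix(5, 4, 6, dimnames = list(letters[1:4], sprintf("s%d", 1:6)))
  vals["c", ] <- c(0, 2, 4, 6, 8, 10)
  expect_equal(select_variable_genes(expr_matrix(vals, unit = "log2TPM1"), 1),
               "c")
  expect_warning(out <- select_variable_genes(expr_matrix(vals, unit = "log2TPM1"),
                                              10), "exceeds")
  expect_length(out, 4)
  expect_error(select_variable_genes(tiny_matrix(matrix(1:4, 2, 2)), 1),
               "log2")
})

test_that("planted high-variance genes dominate the selection", {
  set.seed(51)
  n <- 2000
  m <- matrix(rnorm(n * 40, 5, 0.1), n, 40,
              dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:40)))
  m[1:100, ] <- rnorm(100 * 40, 5, 2)
  sel <- select_variable_genes(expr_matrix(pmax(m, 0), unit = "log2TPM1"), 100)
  expect_gte(mean(sel %in% sprintf("g%04d", 1:100)), 0.95)
})

test_that("PCA matches an eigendecomposition oracle and reconstructs", {
  set.seed(52)
  vals <- matrix(abs(rnorm(200, 4, 2)), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10)))
  em <- expr_matrix(vals, unit = "log2TPM1")
  pc <- compute_pca(em)
  # orthogonality of score columns
  cp <- crossprod(pc$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # reconstruction of the centered matrix
  centered <- t(scale(t(vals), center = TRUE, scale = FALSE))
  rec <- pc$loadings %*% t(pc$scores)
  expect_lt(max(abs(t(rec) - t(centered))), 1e-8)
  # eigen oracle on the cell covariance
  S <- stats::cov(t(vals))
  ev <- eigen(S, symmetric = TRUE)
  k <- ncol(pc$scores)
  lam <- pc$scores
  for (j in seq_len(min(3, k))) {
    expect_equal(abs(sum(pc$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_error(compute_pca(subset_expr(em, cells = "c01")), "2 cells")
})

test_that("the disease axis picks the separating component and orients it", {
  set.seed(53)
  n <- 60
  status <- rep(c("control", "case"), each = n / 2)
  sep <- ifelse(status == "case", 3, -3) + rnorm(n, 0, 0.3)
  scores <- cbind(PC1 = rnorm(n, 0, 10), PC2 = sep, PC3 = rnorm(n),
                  PC4 = rnorm(n), PC5 = rnorm(n))
  rownames(scores) <- sprintf("c%02d", 1:n)
  ax <- choose_disease_axis(scores, status)
  expect_equal(ax$component_index, 2)
  expect_lt(mean(ax$score[status == "control"]), mean(ax$score[status == "case"]))
  # sign flip of the input leaves the oriented axis unchanged
  ax2 <- choose_disease_axis(scores * c(1, -1)[(col(scores) == 2) + 1], status)
  ax2b <- choose_disease_axis(`[<-`(scores, , 2, -scores[, 2]), status)
  expect_equal(ax2b$score, ax$score)
  expect_error(choose_disease_axis(scores, rep("case", n)), "statuses")
  # forced override
  ax3 <- choose_disease_axis(scores, status, force_component = 1)
  expect_equal(ax3$component_index, 1)
})

test_that("axis stability returns r = 1 when case cells are all cells", {
  sim <- shared_sim()
  qc <- run_qc(sim$matrix, sim$cells)
  status <- setNames(qc$cells$status, qc$cells$cell_id)
  ax <- compute_disease_axis(qc$matrix, status, n_variable = 200)
  all_case <- setNames(rep("case", ncol(qc$matrix)), colnames(qc$matrix))
  st <- axis_stability(qc$matrix, all_case, ax, n_variable = 200)
  expect_equal(st$max_correlation, 1, tolerance = 1e-6)
  # on the true-axis simulation the case-only axis correlates strongly
  st2 <- axis_stability(qc$matrix, status, ax, n_variable = 200)
  expect_gte(st2$max_correlation, 0.8)
  expect_error(axis_stability(qc$matrix, setNames(rep("control", ncol(qc$matrix)),
                                                  colnames(qc$matrix)), ax),
               "case cells")
})

test_that("shuffled status labels degrade the axis-status correlation", {
  sim <- shared_sim()
  qc <- run_qc(sim$matrix, sim$cells)
  status <- setNames(qc$cells$status, qc$cells$cell_id)
  ax <- compute_disease_axis(qc$matrix, status, n_variable = 200)
  true_cor <- abs(ax$case_control_correlation)
  set.seed(54)
  shuf <- vapply(1:10, function(i) {
    s <- setNames(sample(status), names(status))
    abs(compute_disease_axis(qc$matrix, s, n_variable = 200)$case_control_correlation)
  }, numeric(1))
  expect_gt(true_cor, max(shuf))
})

test_that("switch model basics: half-peak at t0 and a flat fit under k = 0", {
  expect_equal(switch_mean(0.4, mu0 = 3, k = 12, t0 = 0.4), 3)
  set.seed(55)
  t <- runif(40)
  x <- rnorm(40, 5, 0.3)          # constant mean: the null model
  fit <- fit_switch_gene(x, t)
  expect_lt(fit$lrt, 6)           # no systematic switch signal
  expect_gt(fit$p, 0.01)
  expect_error(fit_switch_gene(c(x[1:20], NA), runif(21)), "finite")
  expect_error(fit_switch_gene(x[1:5], t[1:5]), "10 cells")
})

test_that("the optimizer matches the exhaustive grid oracle", {
  set.seed(56)
  n <- 30
  t <- runif(n)
  x <- pmax(switch_mean(t, 3, 12, 0.5) + rnorm(n, 0, 0.3), 0)
  fit <- fit_switch_gene(x, t)
  oracle <- switch_grid_loglik(x, t)
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-3)
})

test_that("switch_de recovers planted genes and BH preserves p-order", {
  sim <- shared_sim()
  qc <- run_qc(sim$matrix, sim$cells)
  status <- setNames(qc$cells$status, qc$cells$cell_id)
  ax <- compute_disease_axis(qc$matrix, status, n_variable = 200)
  core <- sim$truth$switch_params$gene_id
  keep <- c(core, sprintf("G%04d", 101:250))   # core + background subset
  sub <- subset_expr(log2_tpm1(qc$matrix), genes = keep)
  res <- switch_de(sub, ax)
  expect_gte(mean(res$significant[res$gene_id %in% core]), 0.8)
  expect_lte(mean(res$significant[!res$gene_id %in% core]), 0.1)
  # BH q is a monotone transform of p: non-decreasing along the p-order
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-15))
  # direction matches the planted sign
  est_dir <- res$direction[match(core, res$gene_id)]
  true_dir <- sim$truth$switch_params$direction
  expect_gte(mean(est_dir == true_dir, na.rm = TRUE), 0.9)
})

test_that("switch LRT is invariant to affine rescaling of the axis", {
  set.seed(57)
  n <- 40
  t <- runif(n)
  x <- pmax(switch_mean(t, 2.5, -8, 0.45) + rnorm(n, 0, 0.4), 0)
  f1 <- fit_switch_gene(x, t)
  f2 <- fit_switch_gene(x, rescale01(0.2 + 0.6 * t))
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-4)
})
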