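# Small trajectory fixture: cells along a known axis, a handful of switch
# genes, normalized on the full transcriptome.
traj_fixture <- function(seed = 81, n_cells = 60, core = 12) {
  cfg <- sim_config(seed = seed, n_genes = 400, n_cells = n_cells,
                    core_genes = core, n_down = core - 2, n_up = 2,
                    n_spikeins = 10, outlier_pathway_size = 5,
                    n_lowquality = 0, n_blanks = 2)
  sim <- simulate_cells(cfg)
  cells <- sim$cells$cell_id[!sim$cells$is_blank]
  lg <- log2_tpm1(sim$matrix)
  sub <- subset_expr(lg, genes = sim$truth$switch_params$gene_id, cells = cells)
  tt <- setNames(sim$truth$pseudotime$t, sim$truth$pseudotime$cell_id)[cells]
  status <- setNames(sim$cells$status, sim$cells$cell_id)[cells]
  list(sub = sub, truth = sim$truth, t = tt, status = status)
}

test_that("compiled and reference objectives agree to near machine precision", {
  fx <- traj_fixture()
  X <- unclass(fx$sub); Z <- X == 0
  n <- ncol(X); g <- nrow(X)
  set.seed(82)
  par <- c(stats::qlogis(pmin(pmax(runif(n), 0.02), 0.98)),
           as.numeric(cbind(rnorm(g, 1), rnorm(g, 0, 5), rnorm(g),
                            rnorm(g, -1, 0.2))),
           0.5, -0.6)
  pr <- trajectory_priors()
  r <- diseaseaxis:::traj_objective(par, X, Z, pr, grad = TRUE)
  cpp <- diseaseaxis:::.traj_objective_cpp(par, X, Z, pr$t_sd, pr$t0_sd,
                                           pr$k_sd, pr$mu0_sd, pr$beta_sd,
                                           TRUE, TRUE, TRUE)
  expect_equal(r$value, cpp$value, tolerance = 1e-10)
  expect_lt(max(abs(r$gradient - cpp$gradient)), 1e-8)
})

test_that("the analytic gradient matches finite differences", {
  fx <- traj_fixture()
  X <- unclass(fx$sub); Z <- X == 0
  n <- ncol(X); g <- nrow(X)
  set.seed(83)
  par <- c(stats::qlogis(pmin(pmax(runif(n), 0.02), 0.98)),
           as.numeric(cbind(rnorm(g, 1), rnorm(g, 0, 5), rnorm(g),
                            rnorm(g, -1, 0.2))),
           0.5, -0.6)
  pr <- trajectory_priors()
  r <- diseaseaxis:::traj_objective(par, X, Z, pr, grad = TRUE)
  idx <- c(1, 7, n + 2, n + g + 3, n + 2 * g + 1, n + 3 * g + 4,
           n + 4 * g + 1, n + 4 * g + 2)
  for (j in idx) {
    e <- par; e[j] <- e[j] + 1e-6
    fd <- (diseaseaxis:::traj_objective(e, X, Z, pr, grad = FALSE) - r$value) / 1e-6
    expect_equal(unname(r$gradient[j]), fd, tolerance = 1e-3)
  }
})

test_that("label-switching symmetry leaves the posterior unchanged", {
  fx <- traj_fixture()
  genes <- tibble::tibble(mu0 = runif(nrow(fx$sub), 1, 4),
                          k = runif(nrow(fx$sub), -10, 10),
                          t0 = runif(nrow(fx$sub), 0.2, 0.8),
                          sigma = runif(nrow(fx$sub), 0.3, 1))
  t <- pmin(pmax(fx$t, 0.01), 0.99)
  lp1 <- trajectory_log_posterior(fx$sub, t, genes)
  flipped <- dplyr::mutate(genes, t0 = 1 - t0, k = -k)
  lp2 <- trajectory_log_posterior(fx$sub, 1 - t, flipped)
  expect_equal(lp1, lp2, tolerance = 1e-10)
})

test_that("gradient ascent improves the posterior monotonically", {
  fx <- traj_fixture()
  X <- unclass(fx$sub); Z <- X == 0
  pr <- trajectory_priors()
  trace <- numeric()
  fg <- function(par) {
    r <- diseaseaxis:::.traj_objective_cpp(par, X, Z, pr$t_sd, pr$t0_sd,
                                           pr$k_sd, pr$mu0_sd, pr$beta_sd,
                                           TRUE, TRUE, TRUE)
    r
  }
  n <- ncol(X); g <- nrow(X)
  set.seed(84)
  par <- c(stats::qlogis(pmin(pmax(runif(n), 0.02), 0.98)),
           as.numeric(cbind(rnorm(g, 1), rnorm(g, 0, 5), rnorm(g),
                            rnorm(g, -1, 0.2))),
           0.5, -0.6)
  # wrap to record every accepted objective value
  fg_rec <- function(par) { r <- fg(par); r }
  run <- diseaseaxis:::gradient_ascent(par, fg_rec, max_iter = 200)
  expect_gte(run$value, fg(par)$value)
  # re-run collecting the accepted trajectory step by step
  cur <- par
  vals <- fg(cur)$value
  for (i in 1:25) {
    r <- diseaseaxis:::gradient_ascent(cur, fg, max_iter = 1)
    vals <- c(vals, r$value)
    cur <- r$par
  }
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("pseudotime and switch parameters are recovered jointly", {
  fx <- traj_fixture(seed = 85, n_cells = 80, core = 15)
  axis0 <- setNames(fx$t + rnorm(length(fx$t), 0, 0.15), names(fx$t))
  m <- fit_trajectory(fx$sub, axis0, n_restarts = 3, seed = 1)
  m <- anchor_direction(m, fx$status)
  tau <- stats::cor(fx$t[m$pseudotime$cell_id], m$pseudotime$t,
                    method = "kendall")
  expect_gte(abs(tau), 0.8)
  sp <- fx$truth$switch_params
  est <- m$genes[match(sp$gene_id, m$genes$gene_id), ]
  expect_gte(mean(sign(est$k) == sign(sp$k)), 0.9)
  expect_true(all(m$pseudotime$t >= 0 & m$pseudotime$t <= 1))
  expect_true(all(est$mu0 >= 0) && all(est$sigma > 0))
  # best restart dominates all others
  expect_equal(m$log_posterior, max(m$restarts$log_posterior))
})

test_that("fits are deterministic given the seed", {
  fx <- traj_fixture(seed = 86, n_cells = 40, core = 8)
  axis0 <- setNames(fx$t, names(fx$t))
  a <- fit_trajectory(fx$sub, axis0, n_restarts = 2, seed = 4)
  b <- fit_trajectory(fx$sub, axis0, n_restarts = 2, seed = 4)
  expect_identical(a$pseudotime, b$pseudotime)
  expect_identical(a$genes, b$genes)
})

test_that("monotone noiseless genes order cells by expression rank", {
  n <- 30
  t_true <- seq(0.02, 0.98, length.out = n)
  expr <- vapply(seq_len(5), function(i) switch_mean(t_true, 3, 6, 0.5),
                 numeric(n))
  mm <- t(expr) + 1e-6
  dimnames(mm) <- list(sprintf("g%d", 1:5), sprintf("c%02d", 1:n))
  m <- expr_matrix(mm, unit = "log2TPM1")
  set.seed(3)
  init <- setNames(runif(n), colnames(m))
  fit <- fit_trajectory(m, init, n_restarts = 4, seed = 2)
  tau <- stats::cor(fit$pseudotime$t, unclass(m)[1, ], method = "kendall")
  expect_gte(abs(tau), 0.95)
})

test_that("anchoring flips by the exact model symmetry only when needed", {
  fx <- traj_fixture(seed = 87, n_cells = 50, core = 8)
  m <- fit_trajectory(fx$sub, setNames(fx$t, names(fx$t)),
                      n_restarts = 2, seed = 3)
  anchored <- anchor_direction(m, fx$status)
  ctrl <- mean(anchored$pseudotime$t[fx$status[anchored$pseudotime$cell_id] == "control"])
  case <- mean(anchored$pseudotime$t[fx$status[anchored$pseudotime$cell_id] == "case"])
  expect_lte(ctrl, case)
  # an anchored model is returned unchanged
  again <- anchor_direction(anchored, fx$status)
  expect_equal(again$pseudotime, anchored$pseudotime)
  # the flip preserves the posterior exactly
  lp1 <- trajectory_log_posterior(fx$sub, pmin(pmax(m$pseudotime$t, 1e-6), 1 - 1e-6),
                                  m$genes, m$beta0, m$beta1)
  lp2 <- trajectory_log_posterior(fx$sub,
                                  pmin(pmax(1 - m$pseudotime$t, 1e-6), 1 - 1e-6),
                                  dplyr::mutate(m$genes, t0 = 1 - t0, k = -k),
                                  m$beta0, m$beta1)
  expect_equal(lp1, lp2, tolerance = 1e-8)
})

test_that("disabling dropout recovers the plain Gaussian fit on zero-free data", {
  set.seed(88)
  n <- 40
  t_true <- runif(n)
  expr <- rbind(
    switch_mean(t_true, 3, 8, 0.4) + rnorm(n, 0, 0.2) + 3,
    switch_mean(t_true, 2, -6, 0.6) + rnorm(n, 0, 0.2) + 3,
    switch_mean(t_true, 4, 10, 0.5) + rnorm(n, 0, 0.2) + 3,
    switch_mean(t_true, 3, -9, 0.5) + rnorm(n, 0, 0.2) + 3,
    switch_mean(t_true, 2.5, 7, 0.3) + rnorm(n, 0, 0.2) + 3)
  dimnames(expr) <- list(sprintf("g%d", 1:5), sprintf("c%02d", 1:n))
  m <- expr_matrix(expr, unit = "log2TPM1")
  init <- setNames(t_true, colnames(m))
  plain <- fit_trajectory(m, init, n_restarts = 1, seed = 5, dropout = FALSE)
  fixed <- fit_trajectory(m, init, n_restarts = 1, seed = 5, dropout = TRUE,
                          optimize_beta = FALSE, beta_init = c(-30, 0))
  expect_equal(plain$pseudotime$t, fixed$pseudotime$t, tolerance = 1e-6)
  expect_equal(plain$genes$t0, fixed$genes$t0, tolerance = 1e-6)
})

test_that("genes are ordered by switch time with documented tie-breaks", {
  model <- structure(list(
    pseudotime = tibble::tibble(cell_id = c("a", "b"), t = c(0.2, 0.8)),
    genes = tibble::tibble(gene_id = c("gB", "gA", "gC"),
                           mu0 = c(2, 2, 2), k = c(5, -3, 4),
                           t0 = c(0.8, 0.2, 0.8), sigma = c(1, 1, 1)),
    anchored = TRUE), class = "trajectory_model")
  ord <- order_genes_by_switch(model)
  expect_equal(ord$gene_id, c("gA", "gB", "gC"))
  expect_equal(ord$direction, c("down", "up", "up"))
  expect_equal(ord$tertile, c("early", "mid", "late"))
  model$anchored <- FALSE
  expect_error(order_genes_by_switch(model), "anchor")
})

test_that("early-planted genes land in the early tertile of the fit", {
  fx <- traj_fixture(seed = 89, n_cells = 80, core = 15)
  m <- fit_trajectory(fx$sub, setNames(fx$t, names(fx$t)),
                      n_restarts = 3, seed = 6)
  m <- anchor_direction(m, fx$status)
  ord <- order_genes_by_switch(m)
  sp <- fx$truth$switch_params
  early_true <- sp$gene_id[rank(sp$t0, ties.method = "first") <= 5]
  expect_gte(mean(ord$tertile[match(early_true, ord$gene_id)] == "early"), 0.6)
})
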