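test_that("simulation is bit-reproducible from its seed", {
  a <- simulate_cells(sim_config(seed = 4, n_genes = 200, n_cells = 30,
                                 core_genes = 10, n_down = 8, n_up = 2,
                                 n_spikeins = 15, outlier_pathway_size = 5,
                                 n_lowquality = 2))
  b <- simulate_cells(sim_config(seed = 4, n_genes = 200, n_cells = 30,
                                 core_genes = 10, n_down = 8, n_up = 2,
                                 n_spikeins = 15, outlier_pathway_size = 5,
                                 n_lowquality = 2))
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth$pseudotime, b$truth$pseudotime)
  c <- simulate_cells(sim_config(seed = 5, n_genes = 200, n_cells = 30,
                                 core_genes = 10, n_down = 8, n_up = 2,
                                 n_spikeins = 15, outlier_pathway_size = 5,
                                 n_lowquality = 2))
  expect_false(identical(unclass(a$matrix), unclass(c$matrix)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_cells = 0), "at least one")
  expect_error(sim_config(core_genes = 10, n_down = 5, n_up = 3))
  expect_error(sim_config(n_genes = 50, core_genes = 60, n_down = 52, n_up = 8))
  expect_error(simulate_bulk(shared_sim()$truth,
                             sim_config(bulk_replicates = 0)))
})

test_that("gene classes partition the gene universe", {
  sim <- shared_sim()
  gc <- sim$truth$gene_classes
  expect_equal(nrow(gc), nrow(sim$matrix))
  expect_setequal(unique(gc$class),
                  c("core_down", "core_up", "outlier_pathway", "background",
                    "spikein"))
  expect_equal(sum(gc$class == "core_down"), 26)
  expect_equal(sum(gc$class == "core_up"), 4)
  # no outlier donor -> no outlier_pathway class
  donors <- tibble::tibble(id = c("A", "B"), status = c("control", "case"),
                           is_outlier = FALSE)
  sim2 <- simulate_cells(sim_config(seed = 2, n_genes = 100, n_cells = 20,
                                    core_genes = 5, n_down = 4, n_up = 1,
                                    donors = donors, n_lowquality = 0))
  expect_equal(sum(sim2$truth$gene_classes$class == "outlier_pathway"), 0)
})

test_that("dropout depends on the mean only through beta1", {
  # beta0 chosen so a mid-expression gene (log2 level ~6.5) drops out at
  # rate 0.3 in both settings; only the slope differs
  base_cfg <- function(b1) {
    sim_config(seed = 8, n_genes = 400, n_cells = 80, core_genes = 2,
               n_down = 1, n_up = 1, n_spikeins = 10, n_lowquality = 0,
               outlier_pathway_size = 2,
               dropout_coefs = c(beta0 = stats::qlogis(0.3) - 6.5 * b1,
                                 beta1 = b1))
  }
  zero_frac_vs_mean <- function(sim) {
    gc <- sim$truth$gene_classes
    bg <- gc$gene_id[gc$class == "background"]
    m <- unclass(sim$matrix)[bg, !blank_mask(sim$matrix)]
    zf <- rowMeans(m == 0)
    suppressWarnings(stats::cor(sim$truth$baseline_log2[bg], zf,
                                method = "spearman"))
  }
  flat <- zero_frac_vs_mean(simulate_cells(base_cfg(0)))
  sloped <- zero_frac_vs_mean(simulate_cells(base_cfg(-1)))
  expect_lt(sloped, -0.5)        # strong mean-dependence when beta1 < 0
  expect_gt(flat, -0.2)          # none beyond NB sampling when beta1 = 0
})

test_that("spike-ins carry technical noise matching the NB variance law", {
  sim <- simulate_technical_counts(n_genes = 1, n_cells = 200, n_spikeins = 1,
                                   gene_mean = 100, dispersion = 0.1, seed = 3)
  x <- unclass(sim$matrix)[1, ]
  cv2 <- stats::var(x) / mean(x)^2
  expect_lt(abs(cv2 - (1 / 100 + 0.1)) / (1 / 100 + 0.1), 0.2)
})

test_that("spike-in expression is independent of pseudotime", {
  # on the count scale: TPM couples spike-ins to the cells compositionally,
  # so independence holds for spike-in counts, not per-cell proportions
  sim <- shared_sim()
  sp <- rownames(sim$matrix)[spikein_mask(sim$matrix)]
  tt <- setNames(sim$truth$pseudotime$t, sim$truth$pseudotime$cell_id)
  # no spike-in shows a significant trend after Bonferroni correction
  pvals <- vapply(utils::tail(sp, 10), function(g) {
    x <- log2(unclass(sim$matrix)[g, names(tt)] + 1)
    summary(stats::lm(x ~ tt))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(min(stats::p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("pseudotime distributions separate cases from controls", {
  sim <- shared_sim()
  pt <- sim$truth$pseudotime
  expect_lt(mean(pt$t[pt$status == "control"]), mean(pt$t[pt$status == "case"]))
  expect_true(all(pt$t >= 0 & pt$t <= 1))
})

test_that("bulk replicates share expectations and cases drop core_down genes", {
  cfg <- sim_config(seed = 6, n_genes = 2000, n_cells = 60, core_genes = 20,
                    n_down = 16, n_up = 4, n_lowquality = 0)
  sim <- simulate_cells(cfg)
  bulk <- simulate_bulk(sim$truth, cfg)
  expect_equal(nrow(bulk$samples), 12)
  expect_setequal(unique(bulk$samples$replicate), 1:2)
  m <- unclass(bulk$matrix)
  r1 <- m[, bulk$samples$sample_id[bulk$samples$replicate == 1]]
  r2 <- m[, bulk$samples$sample_id[bulk$samples$replicate == 2]]
  ratios <- rowMeans(r1) / pmax(rowMeans(r2), 1)
  expect_lt(abs(stats::median(ratios[rowMeans(r1) > 50]) - 1), 0.05)

  down <- sim$truth$switch_params$gene_id[sim$truth$switch_params$k < 0]
  ctrl <- bulk$samples$sample_id[bulk$samples$status == "control"]
  case <- bulk$samples$sample_id[bulk$samples$status == "case"]
  expect_gt(mean(rowMeans(m[down, ctrl]) > rowMeans(m[down, case])), 0.9)

  one <- simulate_bulk(sim$truth, sim_config(seed = 6, bulk_replicates = 1))
  expect_equal(unique(one$samples$replicate), 1L)
})

test_that("simulated networks are symmetric with exchangeable nulls", {
  genes <- sprintf("g%02d", 1:40)
  net <- simulate_network(genes[1:8], genes[9:12], genes,
                          planted_effect = 0, seed = 2)
  expect_equal(nrow(net), choose(40, 2))
  expect_equal(network_weight(net, "g01", "g02"),
               network_weight(net, "g02", "g01"))
  expect_true(all(net$weight >= 0))
  # exchangeable under zero effect: class medians agree loosely
  w_core <- network_weight(net, t(utils::combn(genes[1:8], 2))[, 1],
                           t(utils::combn(genes[1:8], 2))[, 2])
  w_bg <- network_weight(net, t(utils::combn(genes[13:40], 2))[, 1],
                         t(utils::combn(genes[13:40], 2))[, 2])
  expect_gt(rank_sum_p(w_core, w_bg, "two.sided"), 0.01)
  expect_error(simulate_network(genes[1:2], genes[3], c(genes, genes[1])),
               "duplicate")
})

test_that("a simulation writes and reads back from disk", {
  dir <- withr::local_tempdir()
  sim <- simulate_cells(sim_config(seed = 9, n_genes = 80, n_cells = 15,
                                   core_genes = 4, n_down = 3, n_up = 1,
                                   n_spikeins = 8, outlier_pathway_size = 3,
                                   n_lowquality = 1, n_blanks = 2))
  write_simulation(sim, dir, format = "mtx")
  back <- read_matrix(file.path(dir, "matrix"), format = "mtx")
  expect_equal(unclass(back), unclass(sim$matrix))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$planted_removal), 1)
})
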