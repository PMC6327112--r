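make_bulk <- function(n_genes, mu, dispersion = 0.05, lfc_idx = integer(),
                      lfc = 0, seed = 1, n_per = 3) {
  set.seed(seed)
  mu <- rep_len(mu, n_genes)
  mu_case <- mu
  mu_case[lfc_idx] <- mu[lfc_idx] * 2^lfc
  counts <- cbind(
    matrix(rnbinom(n_genes * n_per, 1 / dispersion, mu = rep(mu, n_per)),
           n_genes, n_per),
    matrix(rnbinom(n_genes * n_per, 1 / dispersion, mu = rep(mu_case, n_per)),
           n_genes, n_per))
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           sprintf("s%d", seq_len(2 * n_per)))
  samples <- tibble::tibble(sample_id = colnames(counts),
                            donor = sprintf("d%d", seq_len(2 * n_per)),
                            status = rep(c("control", "case"), each = n_per),
                            replicate = 1L)
  list(counts = counts, samples = samples)
}

test_that("size factors follow median-of-ratios with exact scaling examples", {
  m <- matrix(rep(c(10, 100, 50, 7), 6), 4, 6,
              dimnames = list(letters[1:4], sprintf("s%d", 1:6)))
  expect_equal(unname(estimate_size_factors(m)), rep(1, 6))
  m2 <- m; m2[, 3] <- m2[, 3] * 2
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf), c(1, 1, 2, 1, 1, 1))
  # no common nonzero gene: total-count fallback with warning
  m3 <- rbind(c(10, 0), c(0, 10))
  colnames(m3) <- c("a", "b"); rownames(m3) <- c("g1", "g2")
  expect_warning(sf3 <- estimate_size_factors(m3), "fallback|total")
  expect_equal(unname(sf3), c(1, 1))
})

test_that("size factors recover simulated library scalings within 5 percent", {
  set.seed(61)
  mu <- rexp(3000, 1 / 300) + 10
  scal <- c(0.5, 0.8, 1, 1.25, 2, 1)
  counts <- vapply(scal, function(s) rnbinom(3000, 20, mu = mu * s),
                   numeric(3000))
  dimnames(counts) <- list(sprintf("g%04d", 1:3000), sprintf("s%d", 1:6))
  sf <- estimate_size_factors(counts)
  rel <- sf / scal
  expect_lt(max(abs(rel / stats::median(rel) - 1)), 0.05)
})

test_that("a gene with identical counts everywhere gives zero LFC, p near 1", {
  # identical libraries: unit size factors, so every gene is exactly flat
  set.seed(62)
  col <- rnbinom(50, 20, mu = 200) + 1
  counts <- matrix(col, 50, 6, dimnames = list(sprintf("g%04d", 1:50),
                                               sprintf("s%d", 1:6)))
  samples <- tibble::tibble(sample_id = colnames(counts),
                            donor = sprintf("d%d", 1:6),
                            status = rep(c("control", "case"), each = 3),
                            replicate = 1L)
  res <- suppressWarnings(run_bulk_de(counts, samples))
  expect_equal(res$log2fc, rep(0, 50), tolerance = 1e-8)
  expect_true(all(res$p > 0.9))
  # all-zero genes are excluded from testing and from the BH family
  counts[2, ] <- 0
  res2 <- suppressWarnings(run_bulk_de(counts, samples))
  expect_equal(res2$status_col[2], "filtered_all_zero")
  expect_true(is.na(res2$p[2]))
})

test_that("swapping status labels negates every LFC exactly", {
  d <- make_bulk(100, 150, lfc_idx = 1:10, lfc = 1.5, seed = 63)
  res <- suppressWarnings(run_bulk_de(d$counts, d$samples))
  flipped <- dplyr::mutate(d$samples,
                           status = ifelse(status == "case", "control", "case"))
  res2 <- suppressWarnings(run_bulk_de(d$counts, flipped))
  expect_equal(res$log2fc, -res2$log2fc, tolerance = 1e-10)
})

test_that("doubling one library's counts leaves LFCs invariant", {
  d <- make_bulk(200, 150, lfc_idx = 1:20, lfc = 2, seed = 64)
  res <- suppressWarnings(run_bulk_de(d$counts, d$samples))
  c2 <- d$counts; c2[, 1] <- c2[, 1] * 2
  res2 <- suppressWarnings(run_bulk_de(c2, d$samples))
  expect_lt(max(abs(res$log2fc - res2$log2fc), na.rm = TRUE), 1e-6)
})

test_that("planted fold changes are recovered and FDR thresholds nest", {
  d <- make_bulk(1500, 200, lfc_idx = 1:150, lfc = 2, seed = 65)
  res <- suppressWarnings(run_bulk_de(d$counts, d$samples))
  expect_gte(mean(abs(res$log2fc[1:150] - 2) < 0.5), 0.9)
  hits1 <- res$gene_id[!is.na(res$q) & res$q < 0.01]
  hits5 <- res$gene_id[!is.na(res$q) & res$q < 0.05]
  expect_true(all(hits1 %in% hits5))
})

test_that("null simulations keep the p < 0.05 fraction near nominal", {
  fr <- vapply(1:5, function(s) {
    d <- make_bulk(800, rexp(800, 1 / 200) + 20, seed = 70 + s)
    res <- suppressWarnings(run_bulk_de(d$counts, d$samples))
    mean(res$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(fr), 0.02)
  expect_lte(mean(fr), 0.08)
})

test_that("replicate covariates enter the design and donors can be excluded", {
  cfg <- sim_config(seed = 66, n_genes = 400, n_cells = 60, core_genes = 20,
                    n_down = 16, n_up = 4, n_lowquality = 0)
  sim <- simulate_cells(cfg)
  bulk <- simulate_bulk(sim$truth, cfg)
  res <- suppressWarnings(run_bulk_de(bulk$matrix, bulk$samples,
                                      exclude_donor = "GBA3"))
  core <- sim$truth$switch_params$gene_id
  expect_gte(mean(res$significant[res$gene_id %in% core]), 0.8)
  # excluded donor changes the fit inputs
  res_all <- suppressWarnings(run_bulk_de(bulk$matrix, bulk$samples))
  expect_false(isTRUE(all.equal(res$log2fc, res_all$log2fc)))
  # aliased design errors informatively
  bad <- dplyr::mutate(bulk$samples, replicate = ifelse(status == "case", 1, 2))
  expect_error(suppressWarnings(run_bulk_de(bulk$matrix, bad)), "aliased")
})

test_that("direction and magnitude agree with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  d <- make_bulk(300, 250, lfc_idx = 1:30, lfc = 2, seed = 67)
  res <- suppressWarnings(run_bulk_de(d$counts, d$samples))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    d$counts, S4Vectors::DataFrame(condition = factor(d$samples$status,
                                                      levels = c("control", "case"))),
    ~ condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds)
  cc <- stats::cor(res$log2fc, dres$log2FoldChange, use = "complete.obs")
  expect_gt(cc, 0.95)
  hits_mine <- res$q < 0.05 & !is.na(res$q)
  hits_deseq <- !is.na(dres$padj) & dres$padj < 0.05
  expect_gt(mean(hits_mine[1:30]), 0.8)
  expect_gt(sum(hits_mine & hits_deseq) / max(sum(hits_deseq), 1), 0.6)
})
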