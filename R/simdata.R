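#' Configuration for the synthetic single-cell study
#'
#' Builds the parameter object controlling [simulate_cells()],
#' [simulate_bulk()] and [simulate_network()]. Defaults emulate the study
#' design the pipeline targets: ~150 dopamine-neuron-like cells from six
#' donors (three control, three case), one outlier case donor carrying a
#' coherently upregulated pathway module, a latent disease axis along which
#' 60 genes switch (52 down, 8 up), negative-binomial counts with
#' mean-dependent dropout, ERCC-style spike-ins carrying purely technical
#' noise, blank wells, and bulk samples with technical replicates.
#'
#' @param n_cells Number of real (non-blank) cells.
#' @param n_genes Number of endogenous genes (the housekeeping reference
#'   gene is added on top).
#' @param n_spikeins Number of spike-in rows.
#' @param n_blanks Number of blank wells.
#' @param donors Tibble with columns `id`, `status` (`"control"`/`"case"`),
#'   `is_outlier`; exactly one case donor is flagged as outlier by default.
#' @param core_genes,n_down,n_up Size and direction split of the planted
#'   switch-gene set; `n_down + n_up` must equal `core_genes`.
#' @param switch_params_range List of length-2 ranges for `mu0` (half-peak
#'   expression, log2 units), `k` (activation strength magnitude) and `t0`
#'   (switch point on the unit axis).
#' @param pseudotime_dist Per-status Beta parameters on \[0,1\]; controls
#'   concentrate early, cases late, with partial overlap.
#' @param nb_dispersion Negative-binomial dispersion of single-cell counts
#'   (variance = mean + dispersion * mean^2).
#' @param dropout_coefs `c(beta0, beta1)` of the logistic dropout model:
#'   P(dropout) = sigmoid(beta0 + beta1 * log2-mean). `beta1 < 0` makes
#'   low-mean genes drop out more.
#' @param outlier_pathway_size Number of genes coherently shifted in the
#'   outlier donor's cells.
#' @param outlier_logfc log2 shift of the outlier pathway in outlier cells.
#' @param bulk_replicates Technical replicates per donor in the bulk stage.
#' @param bulk_dispersion NB dispersion of the bulk counts.
#' @param bulk_depth Expected total counts per bulk library.
#' @param n_lowquality Number of planted low-quality cells whose reference
#'   gene signal is ablated (the blank-threshold QC rule must catch exactly
#'   these).
#' @param ambient_rate Poisson rate of flat ambient debris counts per gene
#'   in blank wells.
#' @param reference_gene Housekeeping reference gene id used by QC.
#' @param n_plates Number of plates cells are spread over.
#' @param library_depth Expected total counts per cell; realized depths
#'   vary log-normally with sd `efficiency_sd`.
#' @param efficiency_sd Log-normal sd of per-well depth/capture efficiency.
#' @param baseline_log2 Mean/sd/range of the baseline log2(TPM+1)
#'   expression of background genes (background genes are rescaled so the
#'   expected transcriptome totals one million TPM units).
#' @param spikein_log2_range Range of spike-in log2(TPM+1) levels.
#' @param seed Integer seed; all outputs are reproducible from it.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 150,
                       n_genes = 2000,
                       n_spikeins = 40,
                       n_blanks = 6,
                       donors = NULL,
                       core_genes = 60, n_down = 52, n_up = 8,
                       switch_params_range = list(mu0 = c(2, 5),
                                                  k = c(6, 15),
                                                  t0 = c(0.25, 0.75)),
                       pseudotime_dist = list(control = c(2, 5),
                                              case = c(5, 2)),
                       nb_dispersion = 0.1,
                       dropout_coefs = c(beta0 = 2, beta1 = -1),
                       outlier_pathway_size = 20,
                       outlier_logfc = 2,
                       bulk_replicates = 2,
                       bulk_dispersion = 0.05,
                       bulk_depth = 5e6,
                       n_lowquality = 12,
                       ambient_rate = 0.1,
                       reference_gene = "GAPDH",
                       n_plates = 2,
                       library_depth = 5e5,
                       efficiency_sd = 0.1,
                       baseline_log2 = list(mean = 6.5, sd = 1.5,
                                            range = c(3.5, 11)),
                       spikein_log2_range = c(1, 9),
                       seed = 1L) {
  if (is.null(donors)) {
    donors <- tibble::tibble(
      id = c("CTRL1", "CTRL2", "CTRL3", "GBA1", "GBA2", "GBA3"),
      status = rep(c("control", "case"), each = 3),
      is_outlier = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  }
  donors <- tibble::as_tibble(donors)
  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_spikeins = n_spikeins,
              n_blanks = n_blanks, donors = donors,
              core_genes = core_genes, n_down = n_down, n_up = n_up,
              switch_params_range = switch_params_range,
              pseudotime_dist = pseudotime_dist,
              nb_dispersion = nb_dispersion,
              dropout_coefs = dropout_coefs,
              outlier_pathway_size = outlier_pathway_size,
              outlier_logfc = outlier_logfc,
              bulk_replicates = bulk_replicates,
              bulk_dispersion = bulk_dispersion,
              bulk_depth = bulk_depth,
              n_lowquality = n_lowquality,
              ambient_rate = ambient_rate,
              reference_gene = reference_gene,
              n_plates = n_plates,
              library_depth = library_depth,
              efficiency_sd = efficiency_sd,
              baseline_log2 = baseline_log2,
              spikein_log2_range = spikein_log2_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1 || n_genes < 1) {
      stop("configuration error: need at least one cell and one gene",
           call. = FALSE)
    }
    stopifnot(n_down + n_up == core_genes,
              core_genes < n_genes,
              n_spikeins >= 0, n_blanks >= 0, n_lowquality >= 0,
              nb_dispersion > 0,
              all(unlist(pseudotime_dist) > 0),
              all(c("id", "status", "is_outlier") %in% names(donors)),
              all(donors$status %in% c("control", "case")))
    if (outlier_pathway_size + core_genes + 1 > n_genes) {
      stop("configuration error: gene classes exceed n_genes", call. = FALSE)
    }
  })
  invisible(cfg)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sigmoidal switch mean on the log2 scale
#'
#' mean(t) = 2 * mu0 * sigmoid(k * (t - t0)); at t = t0 the mean equals mu0
#' (half the plateau), k's sign gives direction and its magnitude abruptness.
#'
#' @param t Pseudotime(s) in \[0,1\].
#' @param mu0 Half-peak expression (log2 units), non-negative.
#' @param k Signed activation strength.
#' @param t0 Switch point.
#' @return Numeric vector of means.
#' @export
switch_mean <- function(t, mu0, k, t0) 2 * mu0 * sigmoid(k * (t - t0))

#' Simulate a single-cell experiment with ground truth
#'
#' Draws per-cell pseudotimes from per-status Beta laws, builds log2-scale
#' expected expression (sigmoidal in pseudotime for core genes, constant for
#' background, shifted in the outlier donor's cells for the outlier pathway,
#' constant across cells for spike-ins), converts to count means via
#' `2^x - 1`, samples negative-binomial counts, and applies mean-dependent
#' logistic dropout to endogenous genes (the reference housekeeping gene and
#' spike-ins are exempt: the former is guaranteed detectable in intact
#' cells, the latter carry technical noise only). Blank wells receive flat
#' ambient debris plus the full spike-in mix; planted low-quality cells have
#' the reference gene ablated.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (counts [expr_matrix()]), `cells`
#'   (annotation tibble) and `truth` (a `sim_truth` list: `pseudotime`,
#'   `gene_classes`, `switch_params`, `planted_removal`, `outlier_donor`).
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  # --- gene universe ---------------------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_core <- cfg$core_genes
  core_ids <- gene_ids[seq_len(n_core)]
  outlier_ids <- gene_ids[n_core + seq_len(cfg$outlier_pathway_size)]
  spike_ids <- if (cfg$n_spikeins > 0) sprintf("ERCC-%05d", seq_len(cfg$n_spikeins)) else character()
  all_ids <- c(gene_ids, cfg$reference_gene, spike_ids)

  classes <- rep("background", cfg$n_genes)
  classes[seq_len(n_core)] <- c(rep("core_down", cfg$n_down), rep("core_up", cfg$n_up))
  if (!any(cfg$donors$is_outlier)) {
    outlier_ids <- character()
  } else {
    classes[n_core + seq_len(cfg$outlier_pathway_size)] <- "outlier_pathway"
  }
  gene_classes <- tibble::tibble(
    gene_id = all_ids,
    class = c(classes, "background", rep("spikein", length(spike_ids))))

  # --- per-gene parameters ---------------------------------------------
  bl <- cfg$baseline_log2
  base <- pmin(pmax(stats::rnorm(cfg$n_genes, bl$mean, bl$sd), bl$range[1]), bl$range[2])
  rng <- cfg$switch_params_range
  mu0 <- stats::runif(n_core, rng$mu0[1], rng$mu0[2])
  kmag <- stats::runif(n_core, rng$k[1], rng$k[2])
  sgn <- c(rep(-1, cfg$n_down), rep(1, cfg$n_up))
  k <- sgn * kmag
  t0 <- stats::runif(n_core, rng$t0[1], rng$t0[2])
  switch_params <- tibble::tibble(gene_id = core_ids, mu0 = mu0, k = k, t0 = t0,
                                  direction = ifelse(k < 0, "down", "up"))
  spike_log2 <- if (length(spike_ids)) {
    seq(cfg$spikein_log2_range[1], cfg$spikein_log2_range[2],
        length.out = length(spike_ids))
  } else numeric()

  # --- cells ------------------------------------------------------------
  donors <- cfg$donors
  donor_of <- rep(donors$id, length.out = cfg$n_cells)
  status_of <- donors$status[match(donor_of, donors$id)]
  cell_ids <- sprintf("cell_%03d", seq_len(cfg$n_cells))
  blank_ids <- if (cfg$n_blanks > 0) sprintf("blank_%02d", seq_len(cfg$n_blanks)) else character()
  pt <- numeric(cfg$n_cells)
  for (s in c("control", "case")) {
    idx <- status_of == s
    ab <- cfg$pseudotime_dist[[s]]
    pt[idx] <- stats::rbeta(sum(idx), ab[1], ab[2])
  }
  outlier_donor <- donors$id[donors$is_outlier][1]
  is_outlier_cell <- !is.na(outlier_donor) & donor_of == outlier_donor

  plates <- sprintf("P%d", rep(seq_len(cfg$n_plates), length.out = cfg$n_cells + cfg$n_blanks))
  wells <- sprintf("W%03d", seq_len(cfg$n_cells + cfg$n_blanks))

  # --- expected log2(TPM+1), genes x cells ------------------------------
  # The latent scale is log2(TPM+1): expected TPM = 2^lam - 1. Background
  # genes are rescaled once so the expected transcriptome totals ~1e6 TPM
  # units, making realized log2(TPM+1) match the planted lam.
  n_all <- length(all_ids)
  ref_log2 <- 15
  lam <- matrix(0, n_all, cfg$n_cells, dimnames = list(all_ids, cell_ids))
  lam[gene_ids, ] <- matrix(base, cfg$n_genes, cfg$n_cells)
  for (i in seq_len(n_core)) {
    lam[core_ids[i], ] <- switch_mean(pt, mu0[i], k[i], t0[i])
  }
  if (length(outlier_ids) && any(is_outlier_cell)) {
    lam[outlier_ids, is_outlier_cell] <-
      lam[outlier_ids, is_outlier_cell] + cfg$outlier_logfc
  }
  lam[cfg$reference_gene, ] <- ref_log2
  if (length(spike_ids)) lam[spike_ids, ] <- matrix(spike_log2, length(spike_ids), cfg$n_cells)

  tau <- pmax(2^lam - 1, 0)
  bg_rows <- setdiff(gene_ids, core_ids)
  fixed_budget <- mean(colSums(tau[c(core_ids, cfg$reference_gene, spike_ids), ,
                                   drop = FALSE]))
  c_bg <- (1e6 - fixed_budget) / mean(colSums(tau[bg_rows, , drop = FALSE]))
  tau[bg_rows, ] <- tau[bg_rows, , drop = FALSE] * c_bg
  lam <- log2(tau + 1)
  base <- log2((2^base - 1) * c_bg + 1)   # post-calibration baseline truth

  # --- counts: NB + dropout --------------------------------------------
  depth <- cfg$library_depth * exp(stats::rnorm(cfg$n_cells, 0, cfg$efficiency_sd))
  mu_counts <- sweep(tau, 2L, depth / 1e6, `*`)
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu_counts), size = size, mu = mu_counts),
                   n_all, cfg$n_cells, dimnames = dimnames(mu_counts))
  b <- cfg$dropout_coefs
  # endogenous genes only: the reference housekeeping gene and spike-ins
  # are exempt from dropout
  droppable <- gene_ids
  p_drop <- sigmoid(b[1] + b[2] * lam[droppable, , drop = FALSE])
  keep <- matrix(stats::rbinom(length(p_drop), 1L, 1 - p_drop),
                 nrow(p_drop), ncol(p_drop))
  counts[droppable, ] <- counts[droppable, , drop = FALSE] * keep

  # --- planted low-quality cells ---------------------------------------
  planted <- character()
  if (cfg$n_lowquality > 0) {
    planted <- sort(sample(cell_ids, min(cfg$n_lowquality, cfg$n_cells)))
    counts[cfg$reference_gene, planted] <- 0L
  }

  # --- blank wells -------------------------------------------------------
  if (cfg$n_blanks > 0) {
    bl_counts <- matrix(stats::rpois(n_all * cfg$n_blanks, cfg$ambient_rate),
                        n_all, cfg$n_blanks, dimnames = list(all_ids, blank_ids))
    # trace of the abundant housekeeping transcript is always present in debris
    bl_counts[cfg$reference_gene, ] <- 1L + stats::rpois(cfg$n_blanks, 0.5)
    if (length(spike_ids)) {
      bl_counts[spike_ids, ] <- matrix(
        stats::rnbinom(length(spike_ids) * cfg$n_blanks, size = size,
                       mu = pmax(2^spike_log2 - 1, 0) * cfg$library_depth / 1e6),
        length(spike_ids), cfg$n_blanks)
    }
    counts <- cbind(counts, bl_counts)
  }

  cells <- tibble::tibble(
    cell_id = c(cell_ids, blank_ids),
    donor_id = c(donor_of, rep(NA_character_, cfg$n_blanks)),
    status = c(status_of, rep(NA_character_, cfg$n_blanks)),
    plate = plates,
    well = wells,
    is_blank = c(rep(FALSE, cfg$n_cells), rep(TRUE, cfg$n_blanks)))

  mat <- expr_matrix(counts, unit = "counts",
                     spikein = all_ids %in% spike_ids,
                     blank = cells$is_blank)

  truth <- structure(list(
    pseudotime = tibble::tibble(cell_id = cell_ids, t = pt,
                                donor_id = donor_of, status = status_of),
    gene_classes = gene_classes,
    switch_params = switch_params,
    planted_removal = planted,
    outlier_donor = outlier_donor,
    baseline_log2 = stats::setNames(c(base, ref_log2),
                                    c(gene_ids, cfg$reference_gene)),
    spikein_log2 = stats::setNames(spike_log2, spike_ids),
    config = cfg), class = "sim_truth")

  list(matrix = mat, cells = cells, truth = truth)
}

#' Simulate donor-level bulk RNA-seq with technical replicates
#'
#' Each donor's expected bulk profile is the average of its cells' expected
#' count profiles (no dropout: bulk RNA does not suffer single-cell capture
#' loss), scaled to bulk depth; technical replicates are independent
#' negative-binomial resamples of the same expectation.
#'
#' @param truth A `sim_truth` from [simulate_cells()].
#' @param config The same [sim_config()].
#' @return A list with `matrix` (counts [expr_matrix()], genes x samples)
#'   and `samples` (tibble: `sample_id`, `donor`, `status`, `replicate`).
#' @export
simulate_bulk <- function(truth, config) {
  validate_sim_config(config)
  if (config$bulk_replicates < 1) stop("bulk_replicates must be >= 1", call. = FALSE)
  set.seed(config$seed + 1L)
  cfg <- config
  pt <- truth$pseudotime
  sp <- truth$switch_params
  gene_ids <- names(truth$baseline_log2)
  donors <- cfg$donors

  profiles <- vapply(donors$id, function(d) {
    tcells <- pt$t[pt$donor_id == d]
    lam <- matrix(truth$baseline_log2, length(gene_ids), length(tcells))
    rownames(lam) <- gene_ids
    for (i in seq_len(nrow(sp))) {
      lam[sp$gene_id[i], ] <- switch_mean(tcells, sp$mu0[i], sp$k[i], sp$t0[i])
    }
    if (!is.na(truth$outlier_donor) && d == truth$outlier_donor) {
      path <- truth$gene_classes$gene_id[truth$gene_classes$class == "outlier_pathway"]
      lam[path, ] <- lam[path, , drop = FALSE] + cfg$outlier_logfc
    }
    rowMeans(pmax(2^lam - 1, 0))   # expected TPM profile
  }, numeric(length(gene_ids)))

  samples <- tidyr::expand_grid(donor = donors$id,
                                replicate = seq_len(cfg$bulk_replicates))
  samples <- dplyr::mutate(samples,
                           status = donors$status[match(.data$donor, donors$id)],
                           sample_id = sprintf("%s_rep%d", .data$donor, .data$replicate))
  samples <- dplyr::select(samples, "sample_id", "donor", "status", "replicate")

  mu <- profiles[, samples$donor, drop = FALSE] * cfg$bulk_depth / 1e6
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$bulk_dispersion, mu = mu),
                   nrow(mu), ncol(mu),
                   dimnames = list(gene_ids, samples$sample_id))
  list(matrix = expr_matrix(counts, unit = "counts"), samples = samples)
}

#' Simulate a weighted gene similarity network with planted convergence
#'
#' Every unordered pair of distinct genes receives a log-normal weight;
#' pairs within the core set, between core and PD genes, and within the PD
#' set have their log-weights shifted upward by `planted_effect`
#' (`planted_effect = 0` gives fully exchangeable weights).
#'
#' @param core,pd_genes,all_genes Character vectors; `core` and `pd_genes`
#'   must be subsets of `all_genes` and `all_genes` duplicate-free.
#' @param planted_effect Shift of the log-weights of the linked classes.
#' @param seed Integer seed.
#' @param log_sd Baseline log-weight standard deviation.
#' @return A `gene_network` edge list over all pairs of `all_genes`.
#' @export
simulate_network <- function(core, pd_genes, all_genes, planted_effect = 0,
                             seed = 1L, log_sd = 1) {
  if (anyDuplicated(all_genes)) stop("duplicate genes in all_genes", call. = FALSE)
  stopifnot(all(core %in% all_genes), all(pd_genes %in% all_genes))
  set.seed(as.integer(seed))
  n <- length(all_genes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- all_genes[pairs[, 1]]
  b <- all_genes[pairs[, 2]]
  in_core_a <- a %in% core; in_core_b <- b %in% core
  in_pd_a <- a %in% pd_genes; in_pd_b <- b %in% pd_genes
  shift <- planted_effect * ((in_core_a & in_core_b) |
                             (in_pd_a & in_pd_b) |
                             (in_core_a & in_pd_b) | (in_pd_a & in_core_b))
  w <- exp(stats::rnorm(length(a), 0, log_sd) + shift)
  gene_network(tibble::tibble(gene_a = pmin(a, b), gene_b = pmax(a, b),
                              weight = w),
               genes = all_genes)
}

#' Simulate purely technical counts with optional planted biological noise
#'
#' Spike-in rows and endogenous rows are drawn from the same
#' negative-binomial technical model (constant mean per gene across cells);
#' an optional fraction of endogenous genes receives extra per-cell
#' log-normal biological variability with squared coefficient of variation
#' `bio_cv2`. Used for over-dispersion calibration and power studies.
#'
#' @param n_genes,n_cells,n_spikeins Dimensions.
#' @param gene_mean Mean count of endogenous genes (scalar or per gene).
#' @param spike_log2_range Range of spike-in log2 mean counts.
#' @param dispersion NB dispersion.
#' @param bio_frac Fraction of endogenous genes given biological noise.
#' @param bio_cv2 Squared CV of the multiplicative biological factor.
#' @param seed Integer seed.
#' @return List with `matrix` (counts [expr_matrix()]) and `bio_genes`
#'   (character vector of genes carrying planted biological noise).
#' @export
simulate_technical_counts <- function(n_genes = 500, n_cells = 150,
                                      n_spikeins = 40, gene_mean = 50,
                                      spike_log2_range = c(1, 9),
                                      dispersion = 0.1,
                                      bio_frac = 0, bio_cv2 = 0, seed = 1L) {
  set.seed(as.integer(seed))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  spike_ids <- sprintf("ERCC-%05d", seq_len(n_spikeins))
  spike_mu <- 2^seq(spike_log2_range[1], spike_log2_range[2], length.out = n_spikeins)
  mu <- c(rep_len(gene_mean, n_genes), spike_mu)
  mu_mat <- matrix(mu, n_genes + n_spikeins, n_cells)
  bio_genes <- character()
  if (bio_frac > 0 && bio_cv2 > 0) {
    n_bio <- max(1L, round(bio_frac * n_genes))
    bio_idx <- seq_len(n_bio)
    bio_genes <- gene_ids[bio_idx]
    sdlog <- sqrt(log1p(bio_cv2))
    fac <- matrix(stats::rlnorm(n_bio * n_cells, -sdlog^2 / 2, sdlog), n_bio, n_cells)
    mu_mat[bio_idx, ] <- mu_mat[bio_idx, , drop = FALSE] * fac
  }
  counts <- matrix(stats::rnbinom(length(mu_mat), size = 1 / dispersion, mu = mu_mat),
                   nrow(mu_mat), n_cells,
                   dimnames = list(c(gene_ids, spike_ids),
                                   sprintf("cell_%03d", seq_len(n_cells))))
  mat <- expr_matrix(counts, unit = "counts",
                     spikein = c(rep(FALSE, n_genes), rep(TRUE, n_spikeins)))
  list(matrix = mat, bio_genes = bio_genes)
}

#' Write a simulated dataset to disk
#'
#' Writes the count matrix (MatrixMarket triple), the cell annotation, and
#' the ground truth as JSON.
#'
#' @param sim Result of [simulate_cells()].
#' @param outdir Output directory (created if missing).
#' @param format Matrix format, `"mtx"` or `"tsv"`.
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    write_matrix(sim$matrix, file.path(outdir, "matrix"), format = "mtx")
  } else {
    write_matrix(sim$matrix, file.path(outdir, "matrix.tsv"), format = "tsv")
  }
  readr::write_tsv(sim$cells, file.path(outdir, "cells.tsv"), progress = FALSE)
  truth <- sim$truth
  truth$config$donors <- as.data.frame(truth$config$donors)
  jsonlite::write_json(
    list(pseudotime = truth$pseudotime, gene_classes = truth$gene_classes,
         switch_params = truth$switch_params,
         planted_removal = truth$planted_removal,
         outlier_donor = truth$outlier_donor),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
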