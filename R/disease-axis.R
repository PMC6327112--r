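#' Select the most variable genes in log expression space
#'
#' @param matrix An [expr_matrix()] with unit `"log2TPM1"`.
#' @param n Number of genes to keep (default 500). If `n` exceeds the gene
#'   count all genes are returned with a warning.
#' @param exclude_spikeins Drop spike-in rows before ranking (default TRUE).
#' @return Character vector of gene ids, ranked by decreasing variance,
#'   ties broken by gene id.
#' @export
select_variable_genes <- function(matrix, n = 500, exclude_spikeins = TRUE) {
  if (expr_unit(matrix) != "log2TPM1") {
    stop("select_variable_genes expects log2(TPM+1) values", call. = FALSE)
  }
  m <- unclass(matrix)
  if (exclude_spikeins) m <- m[!spikein_mask(matrix), , drop = FALSE]
  v <- apply(m, 1L, stats::var)
  if (n > length(v)) {
    warning("n exceeds gene count; returning all ", length(v), " genes")
    n <- length(v)
  }
  ord <- order(-v, rownames(m))
  rownames(m)[ord][seq_len(n)]
}

#' Principal component analysis of cells
#'
#' Centered, unscaled PCA of the cells-by-genes matrix (genes as features).
#'
#' @param matrix An [expr_matrix()], typically restricted to variable genes.
#' @return List: `scores` (cells x components), `loadings` (genes x
#'   components), `var_explained` (proportion per component, non-increasing).
#' @export
compute_pca <- function(matrix) {
  if (ncol(matrix) < 2) stop("need at least 2 cells for PCA", call. = FALSE)
  if (nrow(matrix) < 2) stop("need at least 2 genes for PCA", call. = FALSE)
  pc <- stats::prcomp(t(unclass(matrix)), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = ve)
}

#' Choose the case-control disease axis among leading components
#'
#' Among the first `K` principal components, selects the one maximizing the
#' absolute point-biserial correlation between component score and
#' case/control status, then orients it so the control-cell mean score is
#' below the case-cell mean. The component index can be forced (the
#' published analysis fixed its axis to the second component of its data).
#'
#' @param scores Cells-by-components score matrix from [compute_pca()].
#' @param status Character vector per cell, `"control"` or `"case"`.
#' @param K Number of leading components searched (default 5).
#' @param force_component Optional integer overriding the search.
#' @return A `disease_axis`: list with `component_index`, `score` (named
#'   per-cell, oriented), `orientation` (+1/-1 applied to the raw
#'   component), `case_control_correlation`.
#' @export
choose_disease_axis <- function(scores, status, K = 5, force_component = NULL) {
  stopifnot(length(status) == nrow(scores))
  if (!all(c("control", "case") %in% status)) {
    stop("both statuses must be present to define the axis", call. = FALSE)
  }
  ind <- as.numeric(status == "case")
  K <- min(K, ncol(scores))
  cors <- vapply(seq_len(K), function(j) stats::cor(scores[, j], ind), numeric(1))
  idx <- if (is.null(force_component)) which.max(abs(cors)) else as.integer(force_component)
  s <- scores[, idx]
  orientation <- if (mean(s[status == "control"]) <= mean(s[status == "case"])) 1 else -1
  s <- s * orientation
  structure(list(component_index = idx,
                 score = stats::setNames(s, rownames(scores)),
                 orientation = orientation,
                 case_control_correlation = unname(stats::cor(scores[, idx], ind)),
                 candidate_correlations = cors),
            class = "disease_axis")
}

#' Variable-gene PCA and axis selection in one call
#'
#' @param matrix An [expr_matrix()] (counts or log2(TPM+1); converted).
#' @param status Per-cell status vector aligned to the matrix columns.
#' @param n_variable Number of variable genes (default 500).
#' @param K Leading components searched (default 5).
#' @param force_component Optional override of the component index.
#' @return A `disease_axis` with attributes `variable_genes` and `pca`.
#' @export
compute_disease_axis <- function(matrix, status, n_variable = 500, K = 5,
                                 force_component = NULL) {
  lg <- log2_tpm1(matrix)
  vg <- select_variable_genes(lg, n = n_variable)
  pca <- compute_pca(subset_expr(lg, genes = vg))
  axis <- choose_disease_axis(pca$scores, status, K = K,
                              force_component = force_component)
  attr(axis, "variable_genes") <- vg
  attr(axis, "pca") <- pca
  axis
}

#' Continuity check: recompute the axis on case cells alone
#'
#' Re-selects variable genes and recomputes PCA within case cells only,
#' then reports, over the first `K` case-only components, the maximum
#' absolute Pearson correlation with the full-data axis scores restricted
#' to case cells. A high value indicates the axis reflects continuous
#' within-case variation, not a case-control batch split.
#'
#' @param matrix The full [expr_matrix()].
#' @param status Per-cell status aligned to the matrix columns.
#' @param axis A `disease_axis` from [compute_disease_axis()].
#' @param K Components searched on the case-only PCA.
#' @param n_variable Variable genes re-selected within cases.
#' @return List: `max_correlation`, `best_component`, `correlations` tibble.
#' @export
axis_stability <- function(matrix, status, axis, K = 5, n_variable = 500) {
  case_cells <- colnames(matrix)[status == "case"]
  if (length(case_cells) < 3) stop("need at least 3 case cells", call. = FALSE)
  lg <- log2_tpm1(subset_expr(matrix, cells = case_cells))
  vg <- select_variable_genes(lg, n = min(n_variable, nrow(lg)))
  pca <- compute_pca(subset_expr(lg, genes = vg))
  ref <- axis$score[case_cells]
  K <- min(K, ncol(pca$scores))
  cors <- vapply(seq_len(K), function(j) stats::cor(ref, pca$scores[, j]), numeric(1))
  tibble_out <- tibble::tibble(component = seq_len(K), r = cors)
  list(max_correlation = max(abs(cors)),
       best_component = which.max(abs(cors)),
       correlations = tibble_out)
}

#' Rescale axis scores to the unit interval
#' @param score Numeric vector.
#' @return The affinely rescaled vector in \[0,1\].
#' @export
rescale01 <- function(score) {
  r <- range(score)
  if (r[1] == r[2]) return(stats::setNames(rep(0.5, length(score)), names(score)))
  (score - r[1]) / (r[2] - r[1])
}

# Negative profiled log-likelihood machinery for the sigmoid switch model.
# Mean curve: mu(t) = 2 * mu0 * sigmoid(k * (t - t0)); Gaussian residuals.
switch_rss <- function(par, x, t) {
  mu <- switch_mean(t, par[1], par[2], par[3])
  sum((x - mu)^2)
}

gauss_loglik <- function(rss, n) {
  sigma2 <- rss / n
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Fit the sigmoidal switch model to one gene
#'
#' Maximum-likelihood fit of mean(t) = 2 * mu0 * sigmoid(k * (t - t0)) with
#' Gaussian residuals, by multi-start bounded quasi-Newton optimization
#' (starts on a t0 grid with both activation signs, plus a flat start), and
#' a likelihood-ratio test against the constant-mean model (2 extra
#' parameters, chi-squared reference with df = 2).
#'
#' @param x Per-cell expression (log2(TPM+1)) for one gene.
#' @param t Axis scores rescaled to \[0,1\], aligned with `x`.
#' @param t0_grid Multi-start grid for the switch point.
#' @param k_init Magnitude of the initial activation strength.
#' @return A one-row tibble: `mu0`, `k`, `t0`, `sigma`, `loglik`, `lrt`,
#'   `p`, `direction`.
#' @export
fit_switch_gene <- function(x, t, t0_grid = seq(0.1, 0.9, by = 0.1), k_init = 5) {
  if (length(x) < 10) stop("need at least 10 cells", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(t))) {
    stop("non-finite expression or axis values", call. = FALSE)
  }
  n <- length(x)
  mu0_start <- max(mean(x) , 1e-3)
  starts <- rbind(
    expand.grid(mu0 = mu0_start, k = c(-k_init, k_init), t0 = t0_grid),
    c(mu0 = mu0_start, k = 0, t0 = 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), switch_rss, x = x, t = t,
                            method = "L-BFGS-B",
                            lower = c(0, -200, 0), upper = c(Inf, 200, 1)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("switch fit failed for all starts", call. = FALSE)
  rss1 <- best$value
  rss0 <- sum((x - mean(x))^2)
  ll1 <- gauss_loglik(max(rss1, 1e-12), n)
  ll0 <- gauss_loglik(max(rss0, 1e-12), n)
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  par <- best$par
  tibble::tibble(mu0 = par[1], k = par[2], t0 = par[3],
                 sigma = sqrt(max(rss1, 1e-12) / n),
                 loglik = ll1, lrt = lrt, p = p,
                 direction = ifelse(par[2] >= 0, "up", "down"))
}

#' Grid-search log-likelihood oracle for the switch model
#'
#' Exhaustively scans (k, t0) on a fixed-resolution lattice, with the
#' linear amplitude mu0 and the residual scale sigma profiled out by their
#' closed-form conditional maximum-likelihood values at each lattice point,
#' then re-scans exhaustively on successively 10x finer local lattices
#' around the incumbent (`refine` levels). Pure search — independent of
#' the quasi-Newton fit path; intended as a verification oracle.
#'
#' @param x,t As in [fit_switch_gene()].
#' @param k_range,resolution Initial sweep for k (default -30..30 at 0.01).
#' @param t0_range Initial sweep range for t0 (default 0..1, same
#'   resolution).
#' @param refine Number of 10x local refinement passes (default 2).
#' @return List: `loglik`, `mu0`, `k`, `t0`, `sigma` at the search optimum.
#' @export
switch_grid_loglik <- function(x, t, k_range = c(-30, 30), t0_range = c(0, 1),
                               resolution = 0.01, refine = 2) {
  n <- length(x)
  sxx <- sum(x^2)
  scan <- function(ks, t0s) {
    best <- list(rss = Inf)
    for (t0 in t0s) {
      # s2: cells x k-grid matrix of 2*sigmoid(k*(t - t0))
      s2 <- 2 / (1 + exp(-outer(t - t0, ks)))
      num <- colSums(x * s2)
      den <- colSums(s2^2)
      mu0 <- pmax(num / pmax(den, 1e-300), 0)
      rss <- sxx - 2 * mu0 * num + mu0^2 * den
      j <- which.min(rss)
      if (rss[j] < best$rss) {
        best <- list(rss = rss[j], mu0 = mu0[j], k = ks[j], t0 = t0)
      }
    }
    best
  }
  res <- resolution
  best <- scan(seq(k_range[1], k_range[2], by = res),
               seq(t0_range[1], t0_range[2], by = res))
  for (lvl in seq_len(refine)) {
    fine <- res / 10
    # k and t0 trade off: re-scan a generous k window at each t0 refinement
    best <- scan(seq(best$k - max(1, 100 * res), best$k + max(1, 100 * res),
                     by = fine),
                 seq(max(t0_range[1], best$t0 - res),
                     min(t0_range[2], best$t0 + res), by = fine))
    res <- fine
  }
  list(loglik = gauss_loglik(max(best$rss, 1e-12), n),
       mu0 = best$mu0, k = best$k, t0 = best$t0,
       sigma = sqrt(max(best$rss, 1e-12) / n))
}

#' Switch-like differential expression along the disease axis
#'
#' Applies [fit_switch_gene()] to every endogenous gene against the axis
#' scores rescaled to \[0,1\], with Benjamini-Hochberg correction across
#' tested genes. Genes whose fit fails are recorded and skipped.
#'
#' @param matrix An [expr_matrix()] (converted to log2(TPM+1)).
#' @param axis A `disease_axis`, or a named numeric vector of scores.
#' @param fdr FDR threshold reported in the `significant` column.
#' @return A `switch_de_result` tibble: `gene_id`, `mu0`, `k`, `t0`,
#'   `sigma`, `loglik`, `lrt`, `p`, `q`, `direction`, `significant`.
#' @export
switch_de <- function(matrix, axis, fdr = 0.05) {
  score <- if (inherits(axis, "disease_axis")) axis$score else axis
  lg <- log2_tpm1(matrix)
  sp <- spikein_mask(lg)
  m <- unclass(lg)[!sp, names(score), drop = FALSE]
  t <- rescale01(score)
  rows <- vector("list", nrow(m))
  failed <- character()
  for (i in seq_len(nrow(m))) {
    fit <- try(fit_switch_gene(m[i, ], t), silent = TRUE)
    if (inherits(fit, "try-error")) {
      failed <- c(failed, rownames(m)[i])
      next
    }
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)[i]), fit)
  }
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  class(out) <- c("switch_de_result", class(out))
  attr(out, "failed_genes") <- failed
  attr(out, "fdr") <- fdr
  out
}
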