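#' Median-of-ratios size factors
#'
#' Per sample, the median over all-nonzero genes of the ratio of the
#' sample's count to the gene's geometric mean; when no gene is nonzero in
#' every sample, total-count ratios are used with a warning. Factors are
#' rescaled to median 1, so scaling one library by c yields a factor of
#' exactly c against unit factors for the rest.
#'
#' @param counts Matrix or [expr_matrix()] of counts (genes x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- unclass(counts)
  nz <- rowSums(m > 0) == ncol(m)
  if (!any(nz)) {
    warning("no gene nonzero in all samples; falling back to total-count ratios")
    f <- colSums(m)
    f <- f / mean(f)
  } else {
    logm <- log(m[nz, , drop = FALSE])
    loggeo <- rowMeans(logm)
    f <- apply(logm, 2L, function(col) exp(stats::median(col - loggeo)))
  }
  f <- f / stats::median(f)
  stats::setNames(f, colnames(m))
}

# Per-gene NB dispersion on size-factor-normalized counts: method of
# moments against fitted means from a Poisson-family fit of the same
# design, with residual-df correction, then log-linear shrinkage toward
# the mean-dispersion trend (equal weight to gene estimate and trend).
# Working on normalized counts makes the whole fit depend on the data only
# through counts/size-factor, so rescaling any one library is compensated
# exactly.
estimate_dispersions <- function(m, design, sf,
                                 floor = 1e-8, ceiling = 10) {
  n <- ncol(m)
  p <- ncol(design)
  q <- sweep(m, 2L, sf, `/`)
  raw <- numeric(nrow(m))
  base_mean <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- q[i, ]
    fit <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::poisson()))
    mu <- fit$fitted.values
    base_mean[i] <- mean(y)
    num <- sum((y - mu)^2) * n / (n - p) - sum(mu)
    den <- sum(mu^2)
    raw[i] <- if (den > 0) num / den else NA_real_
  }
  raw_cl <- pmin(pmax(raw, floor), ceiling)
  usable <- is.finite(raw) & raw > floor & base_mean > 0
  if (sum(usable) >= 10) {
    tr <- stats::lm(log(raw_cl[usable]) ~ log(base_mean[usable]))
    trend <- exp(stats::coef(tr)[1] + stats::coef(tr)[2] * log(pmax(base_mean, 1e-8)))
  } else {
    trend <- rep(stats::median(raw_cl[is.finite(raw_cl)]), nrow(m))
  }
  shrunk <- exp(0.5 * log(raw_cl) + 0.5 * log(pmin(pmax(trend, floor), ceiling)))
  list(dispersion = pmin(pmax(shrunk, floor), ceiling),
       raw = raw, trend = trend, base_mean = base_mean)
}

#' Case-control differential expression on bulk counts
#'
#' A transparent negative-binomial log-linear model per gene:
#' mean = size_factor * exp(b0 + b_status + b_replicate), with
#' median-of-ratios size factors, moment dispersion estimates shrunk
#' toward a log-linear mean-dispersion trend, and a Wald test on the
#' status coefficient referred to a t distribution with residual degrees
#' of freedom. All-zero genes are excluded from testing and from the BH
#' family; a donor blacklist removes that donor's samples before fitting.
#'
#' @param counts Matrix or [expr_matrix()] of bulk counts.
#' @param samples Tibble with `sample_id`, `donor`, `status`
#'   (`"control"`/`"case"`), `replicate`.
#' @param fdr FDR threshold reported in `significant`.
#' @param exclude_donor Optional donor ids removed before fitting.
#' @return A `bulk_de_result` tibble: `gene_id`, `base_mean`, `log2fc`
#'   (case vs control), `se`, `stat`, `p`, `q`, `status_col`
#'   (`"tested"`/`"filtered_all_zero"`), `significant`.
#' @export
run_bulk_de <- function(counts, samples, fdr = 0.05, exclude_donor = NULL) {
  m <- unclass(counts)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "donor", "status", "replicate") %in% names(samples)))
  if (!is.null(exclude_donor)) {
    keep <- !samples$donor %in% exclude_donor
    samples <- samples[keep, , drop = FALSE]
  }
  m <- m[, samples$sample_id, drop = FALSE]
  if (length(unique(samples$status)) < 2) {
    stop("both statuses must be present", call. = FALSE)
  }
  status <- factor(samples$status, levels = c("control", "case"))
  replicate <- factor(samples$replicate)
  if (nlevels(replicate) > 1) {
    design <- stats::model.matrix(~ status + replicate)
  } else {
    design <- stats::model.matrix(~ status)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix rank-deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  sf <- estimate_size_factors(m)
  all_zero <- rowSums(m) == 0
  tested_m <- m[!all_zero, , drop = FALSE]
  disp <- estimate_dispersions(tested_m, design, sf)
  df_resid <- ncol(tested_m) - ncol(design)
  qn <- sweep(tested_m, 2L, sf, `/`)
  res <- purrr::map(seq_len(nrow(tested_m)), function(i) {
    y <- qn[i, ]
    theta <- 1 / disp$dispersion[i]
    fit <- suppressWarnings(try(stats::glm(
      y ~ 0 + design,
      family = MASS::negative.binomial(theta = theta)), silent = TRUE))
    if (inherits(fit, "try-error")) {
      return(tibble::tibble(log2fc = NA_real_, se = NA_real_,
                            stat = NA_real_, p = NA_real_))
    }
    sm <- summary(fit, dispersion = 1)
    co <- sm$coefficients
    row <- grep("statuscase", rownames(co))
    b <- co[row, 1] / log(2)
    se <- co[row, 2] / log(2)
    stat <- co[row, 1] / co[row, 2]
    p <- 2 * stats::pt(abs(stat), df = max(df_resid, 1), lower.tail = FALSE)
    tibble::tibble(log2fc = b, se = se, stat = stat, p = p)
  })
  res <- dplyr::bind_rows(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  out_tested <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(tested_m),
                   base_mean = disp$base_mean,
                   dispersion = disp$dispersion),
    res)
  out_zero <- tibble::tibble(gene_id = rownames(m)[all_zero],
                             base_mean = 0, dispersion = NA_real_,
                             log2fc = NA_real_, se = NA_real_,
                             stat = NA_real_, p = NA_real_, q = NA_real_)
  out <- dplyr::bind_rows(
    dplyr::mutate(out_tested, status_col = "tested"),
    dplyr::mutate(out_zero, status_col = "filtered_all_zero"))
  out <- out[match(rownames(m), out$gene_id), , drop = FALSE]
  out$significant <- !is.na(out$q) & out$q < fdr
  class(out) <- c("bulk_de_result", class(out))
  attr(out, "fdr") <- fdr
  attr(out, "size_factors") <- sf
  out
}
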