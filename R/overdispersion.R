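#' Spike-in size-factor normalization
#'
#' Divides each cell's counts by its spike-in total (rescaled to mean 1
#' across cells), isolating technical scaling; configurable to endogenous
#' totals when spike-ins are unavailable.
#'
#' @param matrix Counts [expr_matrix()].
#' @param method `"spikein"` (default) or `"endogenous"`.
#' @return List: `matrix` (normalized values, unit kept as `"counts"` scale)
#'   and `size_factors` (named per cell).
#' @export
normalize_by_size_factors <- function(matrix, method = c("spikein", "endogenous")) {
  method <- match.arg(method)
  sp <- spikein_mask(matrix)
  totals <- if (method == "spikein") {
    if (!any(sp)) stop("no spike-ins present for spike-in normalization", call. = FALSE)
    colSums(unclass(matrix)[sp, , drop = FALSE])
  } else {
    colSums(unclass(matrix)[!sp, , drop = FALSE])
  }
  if (any(totals == 0)) stop("cells with zero normalization total", call. = FALSE)
  sf <- totals / mean(totals)
  norm <- sweep(unclass(matrix), 2L, sf, `/`)
  list(matrix = expr_matrix(norm, unit = expr_unit(matrix),
                            spikein = attr(matrix, "spikein"),
                            blank = attr(matrix, "blank")),
       size_factors = stats::setNames(sf, colnames(matrix)))
}

#' Fit the technical mean-CV2 relationship from spike-ins
#'
#' Fits CV2 = a1 / mean + alpha by iteratively reweighted least squares over
#' spike-ins with mean normalized count at or above `mean_floor` (weights
#' inversely proportional to the squared fitted CV2, two reweighting
#' passes). A negative asymptote `alpha` is clamped to zero and `a1` refit.
#'
#' With `normalize = "loo"` (the default, for raw counts), each spike-in is
#' normalized by per-cell leave-one-out spike-in totals — the totals of the
#' *other* spike-ins — so its CV2 carries the same size-factor noise that
#' endogenous genes inherit when they are normalized by the full spike-in
#' totals; normalizing a spike-in by a total containing itself would
#' self-suppress its variance and understate the technical line. Use
#' `normalize = "none"` for a matrix that is already on its final scale.
#'
#' @param matrix Counts [expr_matrix()] containing spike-in rows.
#' @param mean_floor Minimum mean normalized count for a spike-in to enter
#'   the fit (default 1).
#' @param normalize `"loo"` (leave-one-out spike-in size factors) or
#'   `"none"`.
#' @return A `technical_noise_fit`: list with `a1`, `alpha`,
#'   `n_spikeins_used`, `mean_floor`, and the spike-in `table` (tibble:
#'   gene, mean, cv2, fitted).
#' @export
fit_technical_noise <- function(matrix, mean_floor = 1,
                                normalize = c("loo", "none")) {
  normalize <- match.arg(normalize)
  sp <- spikein_mask(matrix)
  if (!any(sp)) stop("no spike-in rows in matrix", call. = FALSE)
  m <- unclass(matrix)[sp, , drop = FALSE]
  if (normalize == "loo") {
    if (sum(sp) < 2) stop("leave-one-out normalization needs >= 2 spike-ins",
                          call. = FALSE)
    totals <- colSums(m)
    loo <- sweep(-m, 2L, totals, `+`)          # totals minus the row itself
    if (any(loo <= 0)) stop("cells with zero leave-one-out spike-in total",
                            call. = FALSE)
    loo <- loo / rowMeans(loo)                 # per-row factors, mean 1
    m <- m / loo
  }
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  eligible <- mu >= mean_floor
  if (sum(eligible) < 10) {
    stop("fewer than 10 spike-ins with mean >= ", mean_floor,
         "; reduce mean_floor", call. = FALSE)
  }
  mu_e <- mu[eligible]
  cv2 <- v[eligible] / mu_e^2
  x <- 1 / mu_e
  if (stats::sd(x) == 0) {
    stop("all eligible spike-ins share one mean: design is rank-deficient",
         call. = FALSE)
  }
  w <- rep(1, length(x))
  fit_once <- function(w, with_alpha = TRUE) {
    if (with_alpha) {
      co <- stats::coef(stats::lm(cv2 ~ x, weights = w))
      c(a1 = unname(co[2]), alpha = unname(co[1]))
    } else {
      c(a1 = sum(w * x * cv2) / sum(w * x^2), alpha = 0)
    }
  }
  co <- fit_once(w)
  for (i in 1:2) {
    fitted <- pmax(co["a1"] * x + co["alpha"], 1e-8)
    w <- 1 / fitted^2
    co <- fit_once(w)
  }
  if (co["alpha"] < 0) {
    co <- fit_once(w, with_alpha = FALSE)
  }
  structure(list(a1 = unname(co["a1"]), alpha = unname(co["alpha"]),
                 n_spikeins_used = sum(eligible), mean_floor = mean_floor,
                 table = tibble::tibble(gene_id = rownames(m)[eligible],
                                        mean = unname(mu_e), cv2 = unname(cv2),
                                        fitted = unname(co["a1"] / mu_e + co["alpha"]))),
            class = "technical_noise_fit")
}

#' Predicted technical CV2 at a given mean
#' @param fit A `technical_noise_fit`.
#' @param mean Mean normalized expression.
#' @return Numeric vector of technical CV2 values.
#' @export
technical_cv2 <- function(fit, mean) fit$a1 / mean + fit$alpha

#' Test endogenous genes for over-dispersion beyond technical noise
#'
#' For each endogenous gene with mean normalized count at or above the
#' fit's `mean_floor`, the statistic (n - 1) * CV2_g / technical_cv2(mean_g)
#' is referred to the upper tail of a chi-squared distribution with n - 1
#' degrees of freedom (the sampling law of a sample CV2 under the technical
#' null); Benjamini-Hochberg q-values are computed across tested genes
#' only. A gene is flagged over-dispersed when q < `fdr`.
#'
#' @param matrix Counts [expr_matrix()]; size-factor normalized by
#'   spike-ins internally unless `normalize = FALSE`.
#' @param fit A `technical_noise_fit` (fitted on the same normalization).
#' @param fdr Flagging threshold on q (default 0.05).
#' @param normalize Whether to spike-in normalize internally.
#' @return An `overdispersion_result` tibble: `gene_id`, `mean`, `cv2`,
#'   `technical_cv2`, `statistic`, `df`, `p`, `q`, `over_dispersed`
#'   (untested genes carry NA p/q and FALSE flag).
#' @export
test_overdispersion <- function(matrix, fit, fdr = 0.05, normalize = TRUE) {
  if (!inherits(fit, "technical_noise_fit")) {
    stop("`fit` must come from fit_technical_noise()", call. = FALSE)
  }
  if (ncol(matrix) < 3) stop("need at least 3 cells", call. = FALSE)
  if (normalize) matrix <- normalize_by_size_factors(matrix)$matrix
  sp <- spikein_mask(matrix)
  m <- unclass(matrix)[!sp, , drop = FALSE]
  n <- ncol(m)
  mu <- rowMeans(m)
  cv2 <- apply(m, 1L, stats::var) / mu^2
  tested <- mu >= fit$mean_floor & is.finite(cv2)
  tech <- technical_cv2(fit, mu)
  statistic <- ifelse(tested, (n - 1) * cv2 / tech, NA_real_)
  p <- ifelse(tested, stats::pchisq(statistic, df = n - 1, lower.tail = FALSE),
              NA_real_)
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  res <- tibble::tibble(gene_id = rownames(m), mean = unname(mu),
                        cv2 = unname(cv2), technical_cv2 = unname(tech),
                        statistic = unname(statistic), df = n - 1,
                        p = unname(p), q = unname(q),
                        over_dispersed = !is.na(q) & q < fdr)
  class(res) <- c("overdispersion_result", class(res))
  attr(res, "fdr") <- fdr
  res
}

#' Rank pathway genes by case-group differential expression
#'
#' Wilcoxon rank-sum test per pathway gene on log2(TPM+1) expression
#' between two cell groups, sorted by ascending p, ties broken by absolute
#' median difference (descending) then gene id.
#'
#' @param matrix An [expr_matrix()]; converted to log2(TPM+1) internally.
#' @param group_a,group_b Cell-id vectors (both non-empty).
#' @param pathway_genes Genes to test (absent genes dropped with warning).
#' @return Tibble: `gene_id`, `p`, `direction` (`"up"` if group_a median
#'   higher), `median_diff` (group_a - group_b), ordered as described.
#' @export
rank_pathway_genes <- function(matrix, group_a, group_b, pathway_genes) {
  if (!length(group_a) || !length(group_b)) {
    stop("both cell groups must be non-empty", call. = FALSE)
  }
  genes <- intersect(pathway_genes, rownames(matrix))
  if (length(genes) < length(pathway_genes)) {
    warning("dropping pathway genes absent from matrix: ",
            paste(setdiff(pathway_genes, genes), collapse = ", "))
  }
  if (!length(genes)) {
    return(tibble::tibble(gene_id = character(), p = numeric(),
                          direction = character(), median_diff = numeric()))
  }
  lg <- unclass(log2_tpm1(matrix))
  rows <- purrr::map(genes, function(g) {
    xa <- lg[g, group_a]; xb <- lg[g, group_b]
    md <- stats::median(xa) - stats::median(xb)
    p <- rank_sum_p(xa, xb, alternative = "two.sided")
    tibble::tibble(gene_id = g, p = p,
                   direction = ifelse(md >= 0, "up", "down"),
                   median_diff = md)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$p, dplyr::desc(abs(.data$median_diff)), .data$gene_id)
}

#' Rank-sum p-value with explicit tie handling
#'
#' Exact Wilcoxon rank-sum p when the pooled sample is tie-free and smaller
#' than 50 observations; otherwise the tie-corrected normal approximation.
#' Fully tied data (zero variance) yield p = 0.5 one-sided and p = 1
#' two-sided.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return The p-value.
#' @export
rank_sum_p <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n < 50) {
    p_greater <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p_less <- stats::pwilcox(U, n1, n2)
    return(switch(alternative,
                  greater = p_greater,
                  less = p_less,
                  two.sided = min(1, 2 * min(p_greater, p_less))))
  }
  tie_tab <- table(r)
  correction <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - correction / (n * (n - 1)))
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    return(switch(alternative, two.sided = 1, 0.5))
  }
  sd <- sqrt(sigma2)
  switch(alternative,
         greater = stats::pnorm((U - mu - 0.5) / sd, lower.tail = FALSE),
         less = stats::pnorm((U - mu + 0.5) / sd),
         two.sided = min(1, 2 * stats::pnorm((abs(U - mu) - 0.5) / sd,
                                             lower.tail = FALSE)))
}
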