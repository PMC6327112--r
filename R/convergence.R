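#' Gamma maximum-likelihood fit by Newton iteration on the shape
#'
#' Solves the profile score equation log(shape) - digamma(shape) =
#' log(mean) - mean(log values) by Newton steps (initialized at the
#' classical Thom approximation); the rate is then mean-matched in closed
#' form, so mean = shape / rate holds exactly at the MLE. Zeros are
#' excluded before fitting, with their count recorded.
#'
#' @param values Positive reals (>= 10 strictly positive values required;
#'   zeros dropped and counted, negatives are an error).
#' @param tol Convergence tolerance on the score (default 1e-10).
#' @return A `gamma_fit`: list with `shape`, `rate`, `n_values`,
#'   `n_zero_dropped`, `loglik`.
#' @export
fit_gamma <- function(values, tol = 1e-10) {
  if (any(values < 0)) stop("negative values are not gamma-distributed", call. = FALSE)
  n_zero <- sum(values == 0)
  x <- values[values > 0]
  if (length(x) < 10) stop("need at least 10 strictly positive values", call. = FALSE)
  if (stats::sd(x) == 0) stop("all values equal: gamma MLE is degenerate", call. = FALSE)
  m <- mean(x)
  s <- log(m) - mean(log(x))
  # Thom's initializer, then Newton on f(a) = log(a) - digamma(a) - s
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:100) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    a <- a_new
    if (abs(f) < tol) break
  }
  rate <- a / m
  structure(list(shape = a, rate = rate, n_values = length(x),
                 n_zero_dropped = n_zero,
                 loglik = sum(stats::dgamma(x, shape = a, rate = rate, log = TRUE))),
            class = "gamma_fit")
}

#' Expression-matched inclusion weights from gamma density ratios
#'
#' For each candidate gene mean m, the un-normalized inclusion weight is
#' the ratio of the core-fit gamma density to the background-fit gamma
#' density at m, computed in log space and clamped to exp(+/-700).
#' Zero means receive weight 0.
#'
#' @param means Named numeric candidate gene means (core genes excluded by
#'   the caller).
#' @param core_fit,bg_fit `gamma_fit` objects.
#' @return Named numeric weights, finite and non-negative.
#' @export
inclusion_weights <- function(means, core_fit, bg_fit) {
  w <- numeric(length(means))
  pos <- means > 0
  lw <- stats::dgamma(means[pos], core_fit$shape, core_fit$rate, log = TRUE) -
    stats::dgamma(means[pos], bg_fit$shape, bg_fit$rate, log = TRUE)
  w[pos] <- exp(pmin(pmax(lw, -700), 700))
  stats::setNames(w, names(means))
}

#' Sample an expression-matched background gene set
#'
#' Draws `n` distinct genes without replacement, with selection probability
#' proportional to the un-normalized inclusion weight (successive weighted
#' draws). Reproducible from `seed`.
#'
#' @param weights Named non-negative weights per candidate gene.
#' @param n Sample size (default 1000).
#' @param seed Integer seed.
#' @return A `background_sample`: list with `genes` (character), `weights`
#'   (the input), `n`, `seed`.
#' @export
sample_background <- function(weights, n = 1000, seed = 1L) {
  pos <- weights > 0
  if (sum(pos) < n) {
    stop("only ", sum(pos), " candidates with positive weight; ",
         "reduce n below that", call. = FALSE)
  }
  set.seed(as.integer(seed))
  ids <- names(weights)[pos]
  g <- sample(ids, size = n, replace = FALSE, prob = weights[pos])
  structure(list(genes = g, weights = weights, n = n, seed = as.integer(seed)),
            class = "background_sample")
}

#' Known Parkinson's disease genes used as the positive-control class
#'
#' @param file Optional path to a newline-separated gene list that replaces
#'   the default entirely.
#' @return Character vector of gene symbols (12 by default).
#' @export
default_pd_genes <- function(file = NULL) {
  if (!is.null(file)) {
    g <- readLines(file)
    return(g[nzchar(g)])
  }
  c("SNCA", "PARK2", "PARK7", "LRRK2", "UCHL1", "GBA",
    "PINK1", "ATP13A2", "HTRA2", "PLA2G6", "VPS35", "EIF4G1")
}

# All unordered within-class or between-class pair weights.
class_pair_weights <- function(network, genes_a, genes_b = NULL, zero_fill = TRUE) {
  if (is.null(genes_b)) {
    if (length(genes_a) < 2) return(numeric())
    idx <- utils::combn(genes_a, 2)
    a <- idx[1, ]; b <- idx[2, ]
  } else {
    grid <- expand.grid(a = genes_a, b = genes_b, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    a <- grid$a; b <- grid$b
  }
  w <- network_weight(network, a, b, zero_fill = zero_fill)
  w[!is.na(w)]
}

#' Compare link weights between gene classes on a similarity network
#'
#' Assembles the weight multisets of all unordered pairs within and
#' between the core, sampled-background and PD gene classes (overlapping
#' genes are removed from the lower-priority class and logged; missing
#' edges contribute weight 0 under `zero_fill`, else are excluded), and
#' runs one-sided rank-sum tests for the three claims: core-core links
#' outweigh background-background; core-PD links outweigh background-PD;
#' PD-PD links outweigh background-background (positive control).
#'
#' @param network A `gene_network`.
#' @param core Character vector of core genes.
#' @param background A `background_sample` or character vector.
#' @param pd_genes PD gene list (default [default_pd_genes()]).
#' @param zero_fill Treat absent edges as weight 0 (default TRUE).
#' @return A `link_comparison` tibble: `comparison`, `n_links_1`,
#'   `n_links_2`, `median_1`, `median_2`, `p`, `direction`; attribute
#'   `overlaps` records genes removed from a class.
#' @export
compare_links <- function(network, core, background,
                          pd_genes = default_pd_genes(), zero_fill = TRUE) {
  bg <- if (inherits(background, "background_sample")) background$genes else background
  overlaps <- list(bg_in_core = intersect(bg, core),
                   pd_in_core = intersect(pd_genes, core),
                   bg_in_pd = intersect(bg, pd_genes))
  bg <- setdiff(bg, union(core, pd_genes))
  pd <- setdiff(pd_genes, core)
  classes <- list(core = unique(core), bg = unique(bg), pd = unique(pd))
  w_cc <- class_pair_weights(network, classes$core, zero_fill = zero_fill)
  w_bb <- class_pair_weights(network, classes$bg, zero_fill = zero_fill)
  w_cp <- class_pair_weights(network, classes$core, classes$pd, zero_fill = zero_fill)
  w_bp <- class_pair_weights(network, classes$bg, classes$pd, zero_fill = zero_fill)
  w_pp <- class_pair_weights(network, classes$pd, zero_fill = zero_fill)
  specs <- list(
    list(name = "core-core vs bg-bg", w1 = w_cc, w2 = w_bb),
    list(name = "core-PD vs bg-PD", w1 = w_cp, w2 = w_bp),
    list(name = "PD-PD vs bg-bg", w1 = w_pp, w2 = w_bb))
  rows <- purrr::map(specs, function(sp) {
    if (!length(sp$w1) || !length(sp$w2)) {
      warning("empty class in comparison ", sp$name, "; skipped")
      return(NULL)
    }
    tibble::tibble(comparison = sp$name,
                   n_links_1 = length(sp$w1), n_links_2 = length(sp$w2),
                   median_1 = stats::median(sp$w1),
                   median_2 = stats::median(sp$w2),
                   p = rank_sum_p(sp$w1, sp$w2, alternative = "greater"),
                   direction = "greater")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("link_comparison", class(out))
  attr(out, "overlaps") <- overlaps
  out
}

#' Expression-matched convergence test, end to end
#'
#' Fits gamma laws to the mean log2(TPM+1) of the core set and of all other
#' genes, computes inclusion weights, samples the matched background, and
#' compares network link weights between classes.
#'
#' @param matrix An [expr_matrix()] (converted to log2(TPM+1)).
#' @param core Core gene ids.
#' @param network A `gene_network`.
#' @param pd_genes PD gene list.
#' @param n_background Background sample size (default 1000).
#' @param seed Integer seed.
#' @param zero_fill Passed to [compare_links()].
#' @return List: `core_fit`, `bg_fit`, `weights`, `sample`, `comparison`.
#' @export
run_convergence <- function(matrix, core, network,
                            pd_genes = default_pd_genes(),
                            n_background = 1000, seed = 1L, zero_fill = TRUE) {
  lg <- log2_tpm1(matrix)
  m <- unclass(lg)[!spikein_mask(lg), , drop = FALSE]
  means <- rowMeans(m)
  core <- intersect(core, names(means))
  core_fit <- fit_gamma(means[core])
  other <- means[setdiff(names(means), core)]
  bg_fit <- fit_gamma(other)
  w <- inclusion_weights(other, core_fit, bg_fit)
  samp <- sample_background(w, n = min(n_background, sum(w > 0)), seed = seed)
  comp <- compare_links(network, core, samp, pd_genes, zero_fill = zero_fill)
  list(core_fit = core_fit, bg_fit = bg_fit, weights = w,
       sample = samp, comparison = comp)
}
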