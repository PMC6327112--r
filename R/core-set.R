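#' Consensus clustering of cells
#'
#' A reduced consensus scheme over distance metrics and spectral
#' dimensionalities: for each of three cell-cell distances (Euclidean,
#' Pearson, Spearman) and each leading-eigenvector count d in `d_range`,
#' the distance matrix is embedded via its first d principal components
#' and k-means is run with a fixed per-run seed. The
#' consensus matrix is the mean co-assignment over the runs; final labels
#' cut a complete-linkage hierarchical clustering of 1 - consensus at k.
#' Deterministic given `seed`.
#'
#' @param matrix An [expr_matrix()] with unit `"log2TPM1"`.
#' @param k Number of clusters (`k = 1` returns a single label).
#' @param d_range Eigenvector counts (default 4:7, truncated to n - 1).
#' @param seed Integer seed.
#' @param nstart k-means restarts per run.
#' @return List: `labels` (named integer per cell), `consensus`
#'   (cells x cells), `k`.
#' @export
consensus_cluster <- function(matrix, k, d_range = 4:7, seed = 1L, nstart = 10) {
  if (expr_unit(matrix) != "log2TPM1") {
    stop("consensus_cluster expects log2(TPM+1) values", call. = FALSE)
  }
  n <- ncol(matrix)
  if (k > n) stop("k exceeds the number of cells", call. = FALSE)
  cells <- colnames(matrix)
  if (k == 1) {
    return(list(labels = stats::setNames(rep(1L, n), cells),
                consensus = matrix(1, n, n, dimnames = list(cells, cells)),
                k = 1L))
  }
  m <- t(unclass(matrix))
  dists <- list(
    euclidean = as.matrix(stats::dist(m)),
    pearson = 1 - stats::cor(t(m)),
    spearman = 1 - stats::cor(t(m), method = "spearman"))
  d_range <- d_range[d_range <= n - 1]
  if (!length(d_range)) d_range <- min(2L, n - 1L)
  co <- matrix(0, n, n, dimnames = list(cells, cells))
  runs <- 0L
  run_seed <- as.integer(seed)
  for (dn in names(dists)) {
    # spectral embedding: principal components of the distance matrix
    ev <- stats::prcomp(dists[[dn]], center = TRUE, scale. = FALSE)
    for (d in d_range) {
      emb <- ev$x[, seq_len(d), drop = FALSE]
      run_seed <- run_seed + 1L
      set.seed(run_seed)
      km <- stats::kmeans(emb, centers = k, nstart = nstart, iter.max = 100)
      lab <- km$cluster
      co <- co + outer(lab, lab, `==`)
      runs <- runs + 1L
    }
  }
  consensus <- co / runs
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "complete")
  labels <- stats::cutree(hc, k = k)
  list(labels = stats::setNames(as.integer(labels), cells),
       consensus = consensus, k = as.integer(k))
}

#' Choose k by maximal mean silhouette
#'
#' Runs [consensus_cluster()] for each candidate k and returns the k whose
#' labels maximize the mean silhouette width on the Euclidean distance.
#'
#' @param matrix An [expr_matrix()] with unit `"log2TPM1"`.
#' @param k_range Candidate cluster counts (default 2:5).
#' @param seed Integer seed.
#' @return List: `k`, `silhouettes` tibble, and the winning clustering.
#' @export
choose_k <- function(matrix, k_range = 2:5, seed = 1L) {
  D <- stats::dist(t(unclass(matrix)))
  fits <- purrr::map(k_range, function(k) consensus_cluster(matrix, k, seed = seed))
  sil <- vapply(fits, function(f) {
    s <- cluster::silhouette(f$labels, D)
    mean(s[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)
  list(k = k_range[best],
       silhouettes = tibble::tibble(k = k_range, mean_silhouette = sil),
       clustering = fits[[best]])
}

#' One-vs-rest AUROC
#'
#' Area under the ROC curve for separating `positive` observations from the
#' rest by the values in `x`, computed from rank sums (ties counted half).
#'
#' @param x Numeric scores.
#' @param positive Logical, same length.
#' @return AUROC in \[0,1\] (1 = positives all larger).
#' @export
auroc <- function(x, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Detect discriminating marker genes for a clustering
#'
#' For each gene and each cluster, the one-vs-rest AUROC is computed; the
#' best-separating cluster is reported with the AUROC folded to >= 0.5 and
#' a rank-sum p-value for that split. A gene is a marker when its folded
#' AUROC exceeds `auroc_cut` and its p-value is below `p_cut`.
#'
#' @param matrix An [expr_matrix()] with unit `"log2TPM1"`.
#' @param labels Named integer cluster labels (>= 2 clusters).
#' @param auroc_cut,p_cut Marker thresholds (defaults 0.85 / 0.01).
#' @return A `cluster_markers` tibble: `gene_id`, `cluster`, `auroc`, `p`,
#'   `is_marker`.
#' @export
detect_markers <- function(matrix, labels, auroc_cut = 0.85, p_cut = 0.01) {
  labels <- labels[colnames(matrix)]
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("need at least 2 clusters", call. = FALSE)
  sizes <- table(labels)
  usable <- ks[sizes[as.character(ks)] > 1]
  if (length(usable) < length(ks)) {
    warning("skipping singleton clusters: ",
            paste(setdiff(ks, usable), collapse = ", "))
  }
  m <- unclass(matrix)[!spikein_mask(matrix), , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    best <- list(a = -Inf, cluster = NA_integer_, pos = NULL)
    for (cl in usable) {
      pos <- labels == cl
      a <- auroc(x, pos)
      a_fold <- max(a, 1 - a)
      if (a_fold > best$a) best <- list(a = a_fold, cluster = cl, pos = pos)
    }
    p <- rank_sum_p(x[best$pos], x[!best$pos], alternative = "two.sided")
    tibble::tibble(gene_id = rownames(m)[i], cluster = best$cluster,
                   auroc = best$a, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$is_marker <- out$auroc > auroc_cut & out$p < p_cut
  class(out) <- c("cluster_markers", class(out))
  out
}

#' Three-way core-gene-set intersection
#'
#' The core set is the intersection of (1) bulk DE genes at `fdr_bulk`,
#' (2) switch-DE genes along the axis at `fdr_switch`, and (3) cluster
#' marker genes; each member is assigned the shared direction of its bulk
#' log2 fold change and switch activation sign — genes on which the two
#' disagree are excluded and logged.
#'
#' @param bulk A `bulk_de_result`.
#' @param switch A `switch_de_result`.
#' @param markers A `cluster_markers`.
#' @param fdr_bulk,fdr_switch FDR thresholds (defaults 0.05).
#' @return A `core_gene_set` tibble: `gene_id`, `direction`, `in_bulk`,
#'   `in_switch`, `in_markers` (all TRUE by construction), with attributes
#'   `excluded_direction_mismatch` and `summary` (total/n_down/n_up).
#' @export
intersect_core_set <- function(bulk, switch, markers,
                               fdr_bulk = 0.05, fdr_switch = 0.05) {
  set_b <- bulk$gene_id[!is.na(bulk$q) & bulk$q < fdr_bulk]
  set_s <- switch$gene_id[!is.na(switch$q) & switch$q < fdr_switch]
  set_m <- markers$gene_id[markers$is_marker]
  inter <- Reduce(intersect, list(set_b, set_s, set_m))
  bdir <- ifelse(bulk$log2fc[match(inter, bulk$gene_id)] >= 0, "up", "down")
  sdir <- switch$direction[match(inter, switch$gene_id)]
  agree <- bdir == sdir
  excluded <- inter[!agree]
  core <- inter[agree]
  out <- tibble::tibble(gene_id = core,
                        direction = bdir[agree],
                        in_bulk = TRUE, in_switch = TRUE, in_markers = TRUE)
  out <- dplyr::arrange(out, .data$gene_id)
  if (nrow(out) == 0) warning("empty core set")
  class(out) <- c("core_gene_set", class(out))
  attr(out, "excluded_direction_mismatch") <- excluded
  attr(out, "summary") <- c(total = nrow(out),
                            n_down = sum(out$direction == "down"),
                            n_up = sum(out$direction == "up"))
  out
}
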