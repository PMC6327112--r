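#' Read and write expression matrices
#'
#' Matrices travel either as a dense TSV (genes in rows, first column
#' `gene_id`) or as a MatrixMarket triple: `matrix.mtx`, `genes.tsv`
#' (gene_id, spikein flag) and `cells.tsv` (cell_id, blank flag). The unit
#' tag is stored alongside as a one-line `unit` file for mtx, and as an
#' attribute comment line for TSV is avoided: the caller supplies it.
#'
#' @param path For `tsv`: the matrix file. For `mtx`: the directory holding
#'   `matrix.mtx`, `genes.tsv`, `cells.tsv` (and optionally `unit`).
#' @param format `"tsv"` or `"mtx"`.
#' @param unit Unit tag for TSV input (mtx stores its own).
#' @param spikein,blank Optional masks for TSV input.
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        unit = "counts", spikein = NULL, blank = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    return(expr_matrix(m, unit = unit, spikein = spikein, blank = blank))
  }
  mtx <- file.path(path, "matrix.mtx")
  genes <- readr::read_tsv(file.path(path, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(file.path(path, "cells.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(Matrix::readMM(mtx))
  if (nrow(m) != nrow(genes)) {
    stop("genes axis mismatch: matrix has ", nrow(m), " rows but genes.tsv has ",
         nrow(genes), call. = FALSE)
  }
  if (ncol(m) != nrow(cells)) {
    stop("cells axis mismatch: matrix has ", ncol(m), " columns but cells.tsv has ",
         nrow(cells), call. = FALSE)
  }
  rownames(m) <- genes$gene_id
  colnames(m) <- cells$cell_id
  unit_file <- file.path(path, "unit")
  u <- if (file.exists(unit_file)) readLines(unit_file, n = 1L) else unit
  expr_matrix(m, unit = u,
              spikein = if ("spikein" %in% names(genes)) genes$spikein else NULL,
              blank = if ("blank" %in% names(cells)) cells$blank else NULL)
}

#' @rdname read_matrix
#' @param x An [expr_matrix()] to write.
#' @export
write_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
    tab <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)), tab)
    readr::write_tsv(tab, path, progress = FALSE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                  file.path(path, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene_id = rownames(x),
                                  spikein = spikein_mask(x)),
                   file.path(path, "genes.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = colnames(x),
                                  blank = blank_mask(x)),
                   file.path(path, "cells.tsv"), progress = FALSE)
  writeLines(expr_unit(x), file.path(path, "unit"))
  invisible(path)
}

#' Read / write a weighted gene-gene network edge list
#'
#' Edge lists are TSVs with columns `gene_a`, `gene_b`, `weight`. Weights
#' must be non-negative; self-loops are rejected. The network is undirected:
#' each unordered pair appears once.
#'
#' @param path TSV path.
#' @return A `gene_network`: a tibble of edges with a `genes` attribute
#'   listing the node universe.
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_network(edges)
}

#' @rdname read_network
#' @param network A `gene_network`.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(tibble::as_tibble(network), path, progress = FALSE)
  invisible(path)
}

#' Construct a gene network from an edge table
#'
#' @param edges Tibble/data.frame with `gene_a`, `gene_b`, `weight`.
#' @param genes Optional node universe (defaults to genes seen in edges).
#' @return A `gene_network` tibble.
#' @export
gene_network <- function(edges, genes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops not allowed", call. = FALSE)
  if (any(edges$weight < 0)) stop("negative edge weight", call. = FALSE)
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b), sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges for the same gene pair", call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(edges, genes = genes, class = c("gene_network", class(edges)))
}

#' Look up edge weights for unordered gene pairs
#'
#' @param network A `gene_network`.
#' @param a,b Equal-length character vectors of gene ids.
#' @param zero_fill If `TRUE` (default) absent edges return weight 0, else `NA`.
#' @return Numeric vector of weights.
#' @export
network_weight <- function(network, a, b, zero_fill = TRUE) {
  key <- paste(pmin(network$gene_a, network$gene_b),
               pmax(network$gene_a, network$gene_b), sep = "\r")
  q <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  w <- network$weight[match(q, key)]
  if (zero_fill) w[is.na(w)] <- 0
  w
}

#' Read a GMT-style gene-set file
#'
#' One set per line: set id, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}
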