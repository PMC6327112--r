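#' Gene-by-cell expression matrix with spike-in and blank-well masks
#'
#' `expr_matrix()` wraps a numeric gene-by-cell (or gene-by-sample) matrix
#' together with the metadata every downstream stage needs: the unit the
#' values are expressed in, a per-gene spike-in mask and a per-cell blank-well
#' mask. All pipeline stages consume and return this container.
#'
#' @param values Numeric matrix, genes in rows, cells/samples in columns.
#'   Must have unique, non-empty dimnames and non-negative values.
#' @param unit One of `"counts"`, `"TPM"`, `"log2TPM1"`.
#' @param spikein Logical vector, one entry per gene, `TRUE` for spike-in
#'   (e.g. ERCC) rows. Defaults to all `FALSE`.
#' @param blank Logical vector, one entry per column, `TRUE` for blank wells.
#'   Defaults to all `FALSE`.
#'
#' @return An object of class `expr_matrix`: the matrix with `unit`,
#'   `spikein` and `blank` attributes.
#' @export
expr_matrix <- function(values, unit = c("counts", "TPM", "log2TPM1"),
                        spikein = NULL, blank = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix must have at least one gene and one cell",
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and cell colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate cell ids", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (is.null(spikein)) spikein <- rep(FALSE, nrow(values))
  if (is.null(blank)) blank <- rep(FALSE, ncol(values))
  stopifnot(length(spikein) == nrow(values), length(blank) == ncol(values))
  structure(values,
            unit = unit,
            spikein = as.logical(spikein),
            blank = as.logical(blank),
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells [%s]; %d spike-ins, %d blanks\n",
              nrow(x), ncol(x), expr_unit(x),
              sum(spikein_mask(x)), sum(blank_mask(x))))
  invisible(x)
}

#' Accessors for expr_matrix metadata
#'
#' @param x An [expr_matrix()].
#' @return `expr_unit()` the unit tag; `spikein_mask()` a named logical per
#'   gene; `blank_mask()` a named logical per cell.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @rdname expr_unit
#' @export
spikein_mask <- function(x) stats::setNames(attr(x, "spikein"), rownames(x))

#' @rdname expr_unit
#' @export
blank_mask <- function(x) stats::setNames(attr(x, "blank"), colnames(x))

#' Subset an expr_matrix keeping its masks aligned
#'
#' @param x An [expr_matrix()].
#' @param genes,cells Character vectors (ids) or indices; `NULL` keeps all.
#' @return An [expr_matrix()] restricted to the requested axes.
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x)) else cells
  if (is.character(gi)) {
    missing <- setdiff(gi, rownames(x))
    if (length(missing)) {
      stop("genes absent from matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    gi <- match(gi, rownames(x))
  }
  if (is.character(ci)) {
    missing <- setdiff(ci, colnames(x))
    if (length(missing)) {
      stop("cells absent from matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ci <- match(ci, colnames(x))
  }
  expr_matrix(unclass(x)[gi, ci, drop = FALSE], unit = expr_unit(x),
              spikein = attr(x, "spikein")[gi], blank = attr(x, "blank")[ci])
}

#' TPM normalization with unit gene lengths
#'
#' Rescales every column to sum to one million. Gene lengths are taken as
#' one for all genes, so for these data TPM coincides with counts per
#' million; users quantifying real data with per-gene lengths should divide
#' counts by effective lengths first. Columns with zero total are left
#' all-zero and reported in the `zero_cells` attribute.
#'
#' @param counts An [expr_matrix()] with unit `"counts"` (any non-negative
#'   unit is accepted; the result is tagged `"TPM"`).
#' @return An [expr_matrix()] with unit `"TPM"`; attribute `zero_cells`
#'   lists all-zero columns.
#' @export
tpm_normalize <- function(counts) {
  totals <- colSums(counts)
  zero <- totals == 0
  scale <- ifelse(zero, 0, 1e6 / totals)
  tpm <- sweep(unclass(counts), 2L, scale, `*`)
  out <- expr_matrix(tpm, unit = "TPM", spikein = attr(counts, "spikein"),
                     blank = attr(counts, "blank"))
  attr(out, "zero_cells") <- colnames(counts)[zero]
  out
}

#' Log-transform a TPM matrix to log2(TPM + 1)
#'
#' @param x An [expr_matrix()] with unit `"TPM"` or `"counts"` (counts are
#'   TPM-normalized first).
#' @return An [expr_matrix()] with unit `"log2TPM1"`.
#' @export
log2_tpm1 <- function(x) {
  if (expr_unit(x) == "log2TPM1") return(x)
  if (expr_unit(x) == "counts") x <- tpm_normalize(x)
  expr_matrix(log2(unclass(x) + 1), unit = "log2TPM1",
              spikein = attr(x, "spikein"), blank = attr(x, "blank"))
}

#' Check that a cell annotation table covers a matrix
#'
#' @param x An [expr_matrix()].
#' @param cells A tibble with columns `cell_id`, `donor_id`, `status`,
#'   `plate`, `well`, `is_blank`.
#' @return The annotation, row-ordered to match the matrix columns.
#' @export
align_annotation <- function(x, cells) {
  req <- c("cell_id", "donor_id", "status", "plate", "well", "is_blank")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stop("annotation missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in annotation", call. = FALSE)
  missing <- setdiff(colnames(x), cells$cell_id)
  if (length(missing)) {
    stop("cells axis mismatch; annotation missing cell ids: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cells[match(colnames(x), cells$cell_id), , drop = FALSE]
}
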