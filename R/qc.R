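#' Blank-well reference-gene cell filter
#'
#' Implements the blank-threshold rule: the retention threshold is the
#' maximum expression of a reference housekeeping gene (GAPDH by default)
#' over blank wells, on the log2(TPM+1) scale; any non-blank cell whose
#' reference expression falls strictly below that threshold is removed.
#' Cells exactly at the threshold are retained ("below" is read strictly).
#' Blank wells themselves are always excluded from downstream analysis.
#'
#' @param matrix An [expr_matrix()]; converted to log2(TPM+1) if needed.
#' @param cells Cell annotation tibble (see [align_annotation()]).
#' @param reference_gene Reference gene id.
#' @return A list: `retained` and `removed` cell-id vectors (non-blank
#'   cells only), `threshold` (log2(TPM+1) value; `-Inf` when there are no
#'   blank wells, with a warning), and `scale` (`"log2TPM1"`).
#' @export
filter_blank_reference <- function(matrix, cells, reference_gene = "GAPDH") {
  cells <- align_annotation(matrix, cells)
  if (!reference_gene %in% rownames(matrix)) {
    stop("reference gene ", reference_gene, " absent from matrix", call. = FALSE)
  }
  lg <- log2_tpm1(matrix)
  expr <- unclass(lg)[reference_gene, ]
  blank <- cells$is_blank
  if (!any(blank)) {
    warning("no blank wells: threshold is -Inf, no cells removed")
    threshold <- -Inf
  } else {
    threshold <- max(expr[blank])
  }
  nonblank <- cells$cell_id[!blank]
  below <- expr[nonblank] < threshold
  list(retained = nonblank[!below],
       removed = nonblank[below],
       threshold = unname(threshold),
       scale = "log2TPM1")
}

#' Flag plates with depressed housekeeping expression
#'
#' Computes, per plate, the median log2(TPM+1) of a housekeeping gene panel
#' over the plate's non-blank cells, and flags plates whose median lies
#' below `z_cut` robust z-scores (median/MAD across plates) from the
#' across-plate median. A user blacklist overrides the statistics.
#'
#' @param matrix An [expr_matrix()].
#' @param cells Cell annotation tibble.
#' @param housekeeping_genes Character vector of gene ids (>= 1 present).
#' @param z_cut Robust z threshold (flag when z < z_cut; default -2).
#' @param blacklist Plates to flag unconditionally.
#' @return Tibble: `plate`, `median_hk`, `z`, `flagged`, `reason`.
#' @export
flag_plates <- function(matrix, cells, housekeeping_genes,
                        z_cut = -2, blacklist = character()) {
  cells <- align_annotation(matrix, cells)
  hk <- intersect(housekeeping_genes, rownames(matrix))
  if (!length(hk)) stop("no housekeeping gene present in matrix", call. = FALSE)
  lg <- log2_tpm1(matrix)
  keep <- !cells$is_blank
  expr <- unclass(lg)[hk, cells$cell_id[keep], drop = FALSE]
  plate_of <- cells$plate[keep]
  plates <- sort(unique(cells$plate))
  med <- vapply(plates, function(p) {
    stats::median(expr[, plate_of == p, drop = FALSE])
  }, numeric(1))
  if (length(plates) < 2) {
    warning("single plate: nothing can be flagged statistically")
    z <- rep(NA_real_, length(plates))
  } else {
    center <- stats::median(med)
    s <- stats::mad(med)
    z <- if (s == 0) rep(0, length(med)) else (med - center) / s
  }
  stat_flag <- !is.na(z) & z < z_cut
  black <- plates %in% blacklist
  tibble::tibble(plate = plates, median_hk = unname(med), z = unname(z),
                 flagged = stat_flag | black,
                 reason = dplyr::case_when(black ~ "blacklist",
                                           stat_flag ~ "low_housekeeping",
                                           TRUE ~ ""))
}

#' Flag outlier cells by robust per-plate feature deviation
#'
#' A transparent, auditable stand-in for trained-classifier cell QC: three
#' features are computed per non-blank cell — log10 total counts, log10
#' detected genes, and spike-in count fraction — and a cell is removed when
#' any feature lies more than `k_mad` median-absolute-deviations from its
#' plate's median (global medians/MADs are used, with a warning, for plates
#' with fewer than 5 cells). A zero MAD keeps exact-median cells: features
#' with no spread never trigger removal.
#'
#' @param matrix An [expr_matrix()] with counts.
#' @param cells Cell annotation tibble.
#' @param k_mad MAD multiplier (default 3).
#' @return Tibble: `cell_id`, features, `keep`, `reasons`
#'   (comma-separated among `low_total`, `high_total`, `low_detected`,
#'   `high_detected`, `low_spike_frac`, `high_spike_frac`).
#' @export
flag_outlier_cells <- function(matrix, cells, k_mad = 3) {
  if (expr_unit(matrix) != "counts") stop("counts unit required", call. = FALSE)
  cells <- align_annotation(matrix, cells)
  nonblank <- !cells$is_blank
  m <- unclass(matrix)[, cells$cell_id[nonblank], drop = FALSE]
  sp <- spikein_mask(matrix)
  total <- colSums(m)
  detected <- colSums(m > 0)
  spike_frac <- if (any(sp)) colSums(m[sp, , drop = FALSE]) / pmax(total, 1) else rep(0, ncol(m))
  feats <- cbind(log_total = log10(total + 1),
                 log_detected = log10(detected + 1),
                 spike_frac = spike_frac)
  plate_of <- cells$plate[nonblank]
  tab <- table(plate_of)
  small <- names(tab)[tab < 5]
  if (length(small)) {
    warning("plates with < 5 cells use global MADs: ",
            paste(small, collapse = ", "))
  }
  reasons <- rep("", ncol(m))
  for (j in seq_len(ncol(feats))) {
    f <- feats[, j]
    ctr <- stats::ave(f, plate_of, FUN = stats::median)
    scl <- stats::ave(f, plate_of, FUN = stats::mad)
    g_ctr <- stats::median(f); g_scl <- stats::mad(f)
    use_global <- plate_of %in% small
    ctr[use_global] <- g_ctr; scl[use_global] <- g_scl
    dev <- f - ctr
    out_lo <- scl > 0 & dev < -k_mad * scl
    out_hi <- scl > 0 & dev > k_mad * scl
    nm <- c("total", "detected", "spike_frac")[j]
    reasons[out_lo] <- paste0(reasons[out_lo], ifelse(nzchar(reasons[out_lo]), ",", ""),
                              "low_", nm)
    reasons[out_hi] <- paste0(reasons[out_hi], ifelse(nzchar(reasons[out_hi]), ",", ""),
                              "high_", nm)
  }
  tibble::tibble(cell_id = colnames(m),
                 log_total = unname(feats[, 1]),
                 log_detected = unname(feats[, 2]),
                 spike_frac = unname(feats[, 3]),
                 keep = !nzchar(reasons),
                 reasons = reasons)
}

#' Run the full cell QC stage
#'
#' Applies, in order: plate flagging, the blank-threshold reference-gene
#' rule, and the robust outlier-cell rule (each computed on the cells
#' surviving the previous step). Returns a per-cell report and the retained
#' matrix.
#'
#' @param matrix Counts [expr_matrix()].
#' @param cells Cell annotation tibble.
#' @param reference_gene Reference gene for the blank rule.
#' @param housekeeping_genes Panel for plate flagging (defaults to the
#'   reference gene).
#' @param k_mad,z_cut,plate_blacklist Passed through.
#' @return A list: `report` (tibble `cell_id`, `kept`, `reasons`),
#'   `matrix` (retained cells, blanks dropped), `cells` (their annotation),
#'   `threshold` (blank rule threshold), `plates` (plate table).
#' @export
run_qc <- function(matrix, cells, reference_gene = "GAPDH",
                   housekeeping_genes = reference_gene,
                   k_mad = 3, z_cut = -2, plate_blacklist = character()) {
  cells <- align_annotation(matrix, cells)
  plates <- flag_plates(matrix, cells, housekeeping_genes,
                        z_cut = z_cut, blacklist = plate_blacklist)
  bad_plates <- plates$plate[plates$flagged]
  reasons <- stats::setNames(rep("", nrow(cells)), cells$cell_id)
  reasons[cells$is_blank] <- "blank_well"
  on_bad <- !cells$is_blank & cells$plate %in% bad_plates
  reasons[on_bad] <- "flagged_plate"

  keep1 <- cells$cell_id[!cells$is_blank & !on_bad]
  sub1_cells <- dplyr::filter(cells, .data$cell_id %in% keep1 | .data$is_blank)
  sub1 <- subset_expr(matrix, cells = sub1_cells$cell_id)
  blank_res <- filter_blank_reference(sub1, sub1_cells, reference_gene)
  reasons[blank_res$removed] <- "below_blank_reference"

  keep2 <- blank_res$retained
  sub2_cells <- dplyr::filter(cells, .data$cell_id %in% keep2)
  sub2 <- subset_expr(matrix, cells = keep2)
  out <- flag_outlier_cells(sub2, sub2_cells, k_mad = k_mad)
  removed3 <- out$cell_id[!out$keep]
  reasons[removed3] <- paste0("outlier:", out$reasons[match(removed3, out$cell_id)])

  kept <- cells$cell_id[!nzchar(reasons)]
  report <- tibble::tibble(cell_id = cells$cell_id,
                           kept = !nzchar(reasons),
                           reasons = unname(reasons))
  final_cells <- dplyr::filter(cells, .data$cell_id %in% kept)
  list(report = report,
       matrix = subset_expr(matrix, cells = kept),
       cells = final_cells,
       threshold = blank_res$threshold,
       plates = plates)
}
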