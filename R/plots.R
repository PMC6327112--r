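#' Plot the technical noise fit over spike-ins
#'
#' Mean-CV2 scatter of the spike-ins with the fitted technical
#' relationship, both axes log-scaled.
#'
#' @param fit A `technical_noise_fit`.
#' @param result Optional `overdispersion_result` to overlay endogenous
#'   genes colored by flag.
#' @return A ggplot object.
#' @export
plot_technical_noise <- function(fit, result = NULL) {
  p <- ggplot2::ggplot(fit$table, ggplot2::aes(x = .data$mean, y = .data$cv2))
  if (!is.null(result)) {
    genes <- dplyr::filter(result, !is.na(.data$q))
    p <- p + ggplot2::geom_point(
      data = genes,
      ggplot2::aes(color = .data$over_dispersed), size = 0.5, alpha = 0.5)
  }
  p +
    ggplot2::geom_point(shape = 17, color = "red3") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red3") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean normalized count", y = expression(CV^2),
                  color = "over-dispersed") +
    ggplot2::theme_bw()
}

#' Plot cells along the disease axis
#'
#' @param axis A `disease_axis`.
#' @param status Named per-cell status vector.
#' @return A ggplot object.
#' @export
plot_axis <- function(axis, status) {
  d <- tidy(axis)
  d$status <- status[d$cell_id]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$status)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "disease axis score", y = "cells") +
    ggplot2::theme_bw()
}

#' Plot one gene's expression along the axis with its fitted switch curve
#'
#' @param matrix An [expr_matrix()] (converted to log2(TPM+1)).
#' @param gene Gene id.
#' @param t Named pseudotime/axis scores in \[0,1\].
#' @param fit One-row switch fit (from [fit_switch_gene()] or a
#'   `switch_de_result` row).
#' @return A ggplot object.
#' @export
plot_switch_gene <- function(matrix, gene, t, fit) {
  lg <- log2_tpm1(matrix)
  d <- tibble::tibble(t = t[colnames(lg)], x = unclass(lg)[gene, ])
  curve <- tibble::tibble(t = seq(0, 1, length.out = 200))
  curve$mu <- switch_mean(curve$t, fit$mu0, fit$k, fit$t0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$mu), color = "blue") +
    ggplot2::labs(x = "pseudotime", y = "log2(TPM + 1)", title = gene) +
    ggplot2::theme_bw()
}

#' Plot gene switch points along the anchored trajectory
#'
#' @param model An anchored `trajectory_model`.
#' @return A ggplot object: genes ordered by switch point, colored by
#'   direction.
#' @export
plot_gene_order <- function(model) {
  d <- order_genes_by_switch(model)
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t0, y = .data$gene_id,
                                  color = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "switch point t0", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot link-weight distributions behind a class comparison
#'
#' @param network A `gene_network`.
#' @param core,background,pd_genes Gene classes as in [compare_links()].
#' @param zero_fill Treat absent edges as zero.
#' @return A ggplot object (log1p weight densities by class pair).
#' @export
plot_link_comparison <- function(network, core, background,
                                 pd_genes = default_pd_genes(),
                                 zero_fill = TRUE) {
  bg <- if (inherits(background, "background_sample")) background$genes else background
  bg <- setdiff(bg, union(core, pd_genes))
  pd <- setdiff(pd_genes, core)
  sets <- list("core-core" = class_pair_weights(network, core, zero_fill = zero_fill),
               "bg-bg" = class_pair_weights(network, bg, zero_fill = zero_fill),
               "core-PD" = class_pair_weights(network, core, pd, zero_fill = zero_fill),
               "bg-PD" = class_pair_weights(network, bg, pd, zero_fill = zero_fill),
               "PD-PD" = class_pair_weights(network, pd, zero_fill = zero_fill))
  d <- dplyr::bind_rows(purrr::imap(sets, function(w, nm) {
    tibble::tibble(pair = nm, weight = w)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = log1p(.data$weight), color = .data$pair)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log(1 + link weight)", y = "density") +
    ggplot2::theme_bw()
}
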