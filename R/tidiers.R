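#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the spike-in technical noise fit
#' @param x A `technical_noise_fit`.
#' @param ... Unused.
#' @return Per-spike-in tibble: `gene_id`, `mean`, `cv2`, `fitted`.
#' @export
tidy.technical_noise_fit <- function(x, ...) x$table

#' @rdname tidy.technical_noise_fit
#' @return For `glance()`: one-row tibble with `a1`, `alpha`,
#'   `n_spikeins_used`, `mean_floor`.
#' @export
glance.technical_noise_fit <- function(x, ...) {
  tibble::tibble(a1 = x$a1, alpha = x$alpha,
                 n_spikeins_used = x$n_spikeins_used, mean_floor = x$mean_floor)
}

#' Tidy a fitted trajectory model
#' @param x A `trajectory_model`.
#' @param ... Unused.
#' @return Per-gene tibble of switch parameters.
#' @export
tidy.trajectory_model <- function(x, ...) x$genes

#' @rdname tidy.trajectory_model
#' @return For `glance()`: one-row tibble with `log_posterior`,
#'   `n_restarts`, `beta0`, `beta1`, `anchored`.
#' @export
glance.trajectory_model <- function(x, ...) {
  tibble::tibble(log_posterior = x$log_posterior,
                 n_restarts = nrow(x$restarts),
                 beta0 = x$beta0, beta1 = x$beta1, anchored = x$anchored)
}

#' Tidy a gamma fit
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @return One-row tibble: `shape`, `rate`, `mean`, `n_values`,
#'   `n_zero_dropped`, `loglik`.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(shape = x$shape, rate = x$rate, mean = x$shape / x$rate,
                 n_values = x$n_values, n_zero_dropped = x$n_zero_dropped,
                 loglik = x$loglik)
}

#' Tidy a disease axis
#' @param x A `disease_axis`.
#' @param ... Unused.
#' @return Per-cell tibble: `cell_id`, `score`.
#' @export
tidy.disease_axis <- function(x, ...) {
  tibble::tibble(cell_id = names(x$score), score = unname(x$score))
}

#' @rdname tidy.disease_axis
#' @export
glance.disease_axis <- function(x, ...) {
  tibble::tibble(component_index = x$component_index,
                 orientation = x$orientation,
                 case_control_correlation = x$case_control_correlation)
}
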