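# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# Tiny expression matrix with explicit values and optional masks.
tiny_matrix <- function(values, unit = "counts", spikein = NULL, blank = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  }
  expr_matrix(values, unit = unit, spikein = spikein, blank = blank)
}

# Annotation table matching a matrix, with sensible defaults.
tiny_cells <- function(mat, status = NULL, plate = NULL, blank = NULL) {
  n <- ncol(mat)
  if (is.null(blank)) blank <- as.logical(blank_mask(mat))
  tibble::tibble(
    cell_id = colnames(mat),
    donor_id = ifelse(blank, NA_character_, paste0("d", rep(1:2, length.out = n))),
    status = ifelse(blank, NA_character_,
                    if (is.null(status)) rep(c("control", "case"), length.out = n) else status),
    plate = if (is.null(plate)) rep("P1", n) else plate,
    well = sprintf("W%03d", seq_len(n)),
    is_blank = blank)
}

# Spike-in matrix whose per-row sample CV^2 is exactly a1/mean + alpha:
# each row is an affine transform of a fixed zero-mean, unit-variance
# pattern, so mean and variance are exact by construction.
exact_cv2_spikes <- function(means, a1, alpha, n_cells = 24) {
  z <- scale(seq_len(n_cells))[, 1]        # exact mean 0, sd 1, bounded
  m <- t(vapply(means, function(mu) {
    cv2 <- a1 / mu + alpha
    mu + sqrt(cv2) * mu * z
  }, numeric(n_cells)))
  stopifnot(all(m >= 0))                   # construction must stay exact
  rownames(m) <- sprintf("ERCC-%03d", seq_along(means))
  colnames(m) <- sprintf("c%02d", seq_len(n_cells))
  expr_matrix(m, unit = "counts", spikein = rep(TRUE, length(means)))
}

# A small default simulation shared by several tests (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cells(sim_config(seed = 11, n_genes = 600,
                                          n_cells = 90, n_spikeins = 30,
                                          core_genes = 30, n_down = 26,
                                          n_up = 4, outlier_pathway_size = 10,
                                          n_lowquality = 6))
    }
    cache
  }
})
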