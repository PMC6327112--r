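#' Priors for the switch-like trajectory factor model
#'
#' Defaults: pseudotimes t ~ Normal(0.5, 1) truncated to \[0,1\]; switch
#' points t0 ~ Normal(0.5, 0.1^2) truncated to \[0,1\]; activation
#' strengths k ~ Normal(0, 50^2); half-peak expression mu0 ~
#' half-Normal(0, 10^2); dropout coefficients ~ Normal(0, 10^2).
#'
#' @param t_sd,t0_sd,k_sd,mu0_sd,beta_sd Prior standard deviations.
#' @return A named list of prior standard deviations.
#' @export
trajectory_priors <- function(t_sd = 1, t0_sd = 0.1, k_sd = 50,
                              mu0_sd = 10, beta_sd = 10) {
  list(t_sd = t_sd, t0_sd = t0_sd, k_sd = k_sd, mu0_sd = mu0_sd,
       beta_sd = beta_sd)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
logit <- function(p) log(p / (1 - p))

# Unpack the flat parameter vector used by the optimizer.
# Layout: u (n cells), then per gene (a, k, v, ls), then beta0, beta1.
traj_unpack <- function(par, n, g) {
  u <- par[seq_len(n)]
  rest <- matrix(par[n + seq_len(4 * g)], nrow = g, ncol = 4)
  list(u = u, a = rest[, 1], k = rest[, 2], v = rest[, 3], ls = rest[, 4],
       beta0 = par[n + 4 * g + 1], beta1 = par[n + 4 * g + 2])
}

# Log posterior and gradient of the zero-inflated sigmoid factor model.
# X: genes x cells log2(TPM+1); Z: zero indicator matrix.
traj_objective <- function(par, X, Z, priors, dropout = TRUE,
                           optimize_beta = TRUE, grad = FALSE) {
  n <- ncol(X); g <- nrow(X)
  p <- traj_unpack(par, n, g)
  t <- stats::plogis(p$u)
  t0 <- stats::plogis(p$v)
  mu0 <- softplus(p$a)
  sigma <- exp(p$ls)
  eta_s <- sweep(outer(p$k, t), 1L, p$k * t0, `-`)   # k_g * (t_n - t0_g)
  s <- stats::plogis(eta_s)
  M <- 2 * mu0 * s
  R <- X - M
  NZ <- 1 - Z
  ll_norm <- -0.5 * log(2 * pi) - p$ls - 0.5 * (R / sigma)^2
  if (dropout) {
    eta_d <- p$beta0 + p$beta1 * M
    log_p <- stats::plogis(eta_d, log.p = TRUE)
    log_q <- stats::plogis(-eta_d, log.p = TRUE)
    ll <- sum(Z * log_p + NZ * (log_q + ll_norm))
    pd <- stats::plogis(eta_d)
  } else {
    ll <- sum(ll_norm)
    pd <- NULL
  }
  lp <- ll -
    sum((t - 0.5)^2) / (2 * priors$t_sd^2) -
    sum((t0 - 0.5)^2) / (2 * priors$t0_sd^2) -
    sum(p$k^2) / (2 * priors$k_sd^2) -
    sum(mu0^2) / (2 * priors$mu0_sd^2)
  if (dropout && optimize_beta) {
    lp <- lp - (p$beta0^2 + p$beta1^2) / (2 * priors$beta_sd^2)
  }
  if (!grad) return(lp)

  # dL/dM
  if (dropout) {
    G <- Z * (1 - pd) * p$beta1 + NZ * (-pd * p$beta1 + R / sigma^2)
  } else {
    G <- R / sigma^2
  }
  dm_dmu0 <- 2 * s
  ss1 <- s * (1 - s)
  tmt0 <- sweep(matrix(t, g, n, byrow = TRUE), 1L, t0, `-`)
  dm_dk <- 2 * mu0 * ss1 * tmt0
  common <- 2 * mu0 * p$k * ss1              # dm/dt_n and -dm/dt0
  g_mu0 <- rowSums(G * dm_dmu0) - mu0 / priors$mu0_sd^2
  g_a <- g_mu0 * stats::plogis(p$a)
  g_k <- rowSums(G * dm_dk) - p$k / priors$k_sd^2
  g_t0 <- -rowSums(G * common) - (t0 - 0.5) / priors$t0_sd^2
  g_v <- g_t0 * t0 * (1 - t0)
  g_t <- colSums(G * common) - (t - 0.5) / priors$t_sd^2
  g_u <- g_t * t * (1 - t)
  if (dropout) {
    g_ls <- rowSums(NZ * (-1 + (R / sigma)^2))
  } else {
    g_ls <- rowSums(-1 + (R / sigma)^2)
  }
  if (dropout && optimize_beta) {
    DB <- Z * (1 - pd) - NZ * pd
    g_b0 <- sum(DB) - p$beta0 / priors$beta_sd^2
    g_b1 <- sum(DB * M) - p$beta1 / priors$beta_sd^2
  } else {
    g_b0 <- 0; g_b1 <- 0
  }
  list(value = lp,
       gradient = c(g_u, as.numeric(cbind(g_a, g_k, g_v, g_ls)), g_b0, g_b1))
}

#' Log posterior of a trajectory model at given parameters
#'
#' Evaluates the zero-inflated sigmoid factor model's log posterior for an
#' explicit parameter set; used to verify model symmetries.
#'
#' @param matrix An [expr_matrix()] with unit `"log2TPM1"` (genes x cells).
#' @param t Per-cell pseudotimes in (0,1), aligned to columns.
#' @param genes Tibble with `mu0`, `k`, `t0`, `sigma` aligned to rows.
#' @param beta0,beta1 Dropout coefficients.
#' @param priors See [trajectory_priors()].
#' @param dropout Include the dropout component.
#' @return The scalar log posterior.
#' @export
trajectory_log_posterior <- function(matrix, t, genes, beta0 = -2, beta1 = -0.5,
                                     priors = trajectory_priors(),
                                     dropout = TRUE) {
  X <- unclass(matrix)
  eps <- 1e-9
  par <- c(logit(pmin(pmax(t, eps), 1 - eps)),
           as.numeric(cbind(log(expm1(pmax(genes$mu0, 1e-8))),
                            genes$k,
                            logit(pmin(pmax(genes$t0, eps), 1 - eps)),
                            log(genes$sigma))),
           beta0, beta1)
  traj_objective(par, X, X == 0, priors, dropout = dropout, grad = FALSE)
}

# Quasi-Newton gradient ascent with Armijo backtracking line search;
# monotone by construction (a step is only taken when it improves the
# posterior by the Armijo fraction of the predicted gain). Directions come
# from a limited-memory BFGS two-loop recursion on the gradient history,
# falling back to the raw gradient whenever the quasi-Newton direction is
# not an ascent direction.
gradient_ascent <- function(par, fg, max_iter = 5000, tol = 1e-8,
                            c_armijo = 1e-4, memory = 10) {
  res <- fg(par)
  f <- res$value
  g <- res$gradient
  S <- list(); Y <- list()
  gamma <- 1
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (!is.finite(f)) break
    # two-loop recursion (maximization: use +g, curvature pairs s, y = g_new - g)
    q <- g
    m <- length(S)
    alpha_i <- numeric(m)
    if (m > 0) {
      for (i in m:1) {
        rho_i <- 1 / sum(Y[[i]] * S[[i]])
        alpha_i[i] <- rho_i * sum(S[[i]] * q)
        q <- q - alpha_i[i] * Y[[i]]
      }
      q <- gamma * q
      for (i in 1:m) {
        rho_i <- 1 / sum(Y[[i]] * S[[i]])
        beta_i <- rho_i * sum(Y[[i]] * q)
        q <- q + (alpha_i[i] - beta_i) * S[[i]]
      }
    } else {
      q <- q / max(sqrt(sum(q^2)), 1)
    }
    d <- q
    slope <- sum(g * d)
    if (slope <= 0) { d <- g; slope <- sum(g * g) }
    if (slope == 0) break
    step <- 1
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- par + step * d
      res_new <- try(fg(cand), silent = TRUE)
      if (!inherits(res_new, "try-error") && is.finite(res_new$value) &&
          res_new$value >= f + c_armijo * step * slope) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    s_vec <- cand - par
    y_vec <- res_new$gradient - g   # for -f minimization: y = -(g_new) - (-g)
    sy <- -sum(s_vec * y_vec)       # curvature in minimization convention
    if (sy > 1e-10) {
      S <- c(S, list(s_vec)); Y <- c(Y, list(-y_vec))
      if (length(S) > memory) { S <- S[-1]; Y <- Y[-1] }
      gamma <- sy / sum(y_vec^2)
    }
    rel <- (res_new$value - f) / (abs(f) + 1e-12)
    par <- cand
    f <- res_new$value
    g <- res_new$gradient
    if (rel < tol) break
  }
  list(par = par, value = f, iterations = iter)
}

# Coarse per-gene initialization given pseudotimes: small grid over
# (k, t0) with mu0 profiled on the nonzero observations.
init_gene_params <- function(X, Z, t, k_grid = c(-15, -10, -6, -3, 3, 6, 10, 15),
                             t0_grid = seq(0.1, 0.9, by = 0.1)) {
  g <- nrow(X)
  out <- matrix(0, g, 4)
  for (i in seq_len(g)) {
    x <- X[i, ]
    use <- !Z[i, ]
    if (sum(use) < 3) { out[i, ] <- c(max(mean(x), 0.1), 1, 0.5, 1); next }
    best <- NULL
    for (k in k_grid) for (t0 in t0_grid) {
      s2 <- 2 * stats::plogis(k * (t[use] - t0))
      den <- sum(s2^2)
      mu0 <- if (den > 0) max(sum(x[use] * s2) / den, 0) else 0
      rss <- sum((x[use] - mu0 * s2)^2)
      if (is.null(best) || rss < best$rss) best <- list(rss = rss, mu0 = mu0, k = k, t0 = t0)
    }
    sigma <- sqrt(max(best$rss / sum(use), 0.01))
    out[i, ] <- c(max(best$mu0, 0.05), best$k, best$t0, sigma)
  }
  colnames(out) <- c("mu0", "k", "t0", "sigma")
  out
}

#' Joint MAP fit of pseudotimes and switch parameters
#'
#' Fits the zero-inflated sigmoid factor model: an observation is zero with
#' probability sigmoid(beta0 + beta1 * mean), and otherwise Gaussian around
#' mean = 2 * mu0_g * sigmoid(k_g * (t_n - t0_g)). All per-cell pseudotimes
#' and per-gene switch parameters (plus the shared dropout coefficients)
#' are inferred together by maximum a posteriori gradient ascent with
#' Armijo backtracking, under the priors of [trajectory_priors()].
#' Restart 0 initializes pseudotimes at the rescaled disease axis; further
#' restarts jitter them. Deterministic given `seed`.
#'
#' @param matrix An [expr_matrix()] restricted to the core genes, with unit
#'   `"log2TPM1"` (>= 5 genes, >= 20 cells). TPM-normalize on the full
#'   transcriptome *before* subsetting to the gene panel; handing counts
#'   directly is accepted but then the TPM denominator is the panel only.
#' @param init_axis A `disease_axis`, or named numeric initial scores.
#' @param n_restarts Number of restarts (default 10).
#' @param seed Integer seed.
#' @param priors See [trajectory_priors()].
#' @param dropout Model dropout (default TRUE).
#' @param optimize_beta Optimize the dropout coefficients (default TRUE);
#'   when FALSE `beta_init` is held fixed.
#' @param beta_init Initial (or fixed) dropout coefficients.
#' @param max_iter,tol Convergence controls (relative log-posterior change).
#' @param engine `"cpp"` (compiled objective/gradient, default) or `"r"`
#'   (reference implementation; identical results, slower).
#' @return A `trajectory_model`: list with `pseudotime` (tibble `cell_id`,
#'   `t`), `genes` (tibble `gene_id`, `mu0`, `k`, `t0`, `sigma`), `beta0`,
#'   `beta1`, `log_posterior`, `restarts` (diagnostics tibble), `anchored`.
#' @export
fit_trajectory <- function(matrix, init_axis, n_restarts = 10, seed = 1L,
                           priors = trajectory_priors(), dropout = TRUE,
                           optimize_beta = TRUE, beta_init = c(0.5, -0.6),
                           max_iter = 5000, tol = 1e-8,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  lg <- log2_tpm1(matrix)
  X <- unclass(lg)
  if (nrow(X) < 5) stop("need at least 5 genes", call. = FALSE)
  if (ncol(X) < 20) stop("need at least 20 cells", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite expression values", call. = FALSE)
  Z <- X == 0
  n <- ncol(X); g <- nrow(X)
  score <- if (inherits(init_axis, "disease_axis")) init_axis$score else init_axis
  t_axis <- pmin(pmax(rescale01(score[colnames(X)]), 0.02), 0.98)
  set.seed(as.integer(seed))
  eps <- 1e-6
  fg <- if (engine == "cpp") {
    function(par) .traj_objective_cpp(par, X, Z, priors$t_sd, priors$t0_sd,
                                      priors$k_sd, priors$mu0_sd,
                                      priors$beta_sd, dropout, optimize_beta,
                                      TRUE)
  } else {
    function(par) traj_objective(par, X, Z, priors, dropout = dropout,
                                 optimize_beta = optimize_beta, grad = TRUE)
  }
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    t_init <- if (r == 1) t_axis else {
      pmin(pmax(t_axis + stats::rnorm(n, 0, 0.2), 0.02), 0.98)
    }
    gp <- init_gene_params(X, Z, t_init)
    par <- c(logit(t_init),
             as.numeric(cbind(log(expm1(pmax(gp[, "mu0"], 1e-6))),
                              gp[, "k"],
                              logit(pmin(pmax(gp[, "t0"], eps), 1 - eps)),
                              log(pmax(gp[, "sigma"], 0.05)))),
             beta_init[1], beta_init[2])
    fit <- gradient_ascent(par, fg, max_iter = max_iter, tol = tol)
    runs[[r]] <- fit
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  if (!any(is.finite(values))) {
    stop("no restart converged to a finite log posterior; diagnostics: ",
         paste(round(values, 3), collapse = ", "), call. = FALSE)
  }
  best <- runs[[which.max(values)]]
  p <- traj_unpack(best$par, n, g)
  model <- structure(list(
    pseudotime = tibble::tibble(cell_id = colnames(X), t = stats::plogis(p$u)),
    genes = tibble::tibble(gene_id = rownames(X),
                           mu0 = softplus(p$a), k = p$k,
                           t0 = stats::plogis(p$v), sigma = exp(p$ls)),
    beta0 = if (dropout) p$beta0 else -Inf,
    beta1 = if (dropout) p$beta1 else 0,
    log_posterior = best$value,
    restarts = tibble::tibble(restart = seq_len(n_restarts) - 1L,
                              log_posterior = values,
                              iterations = vapply(runs, `[[`, numeric(1), "iterations")),
    priors = priors, dropout = dropout, seed = as.integer(seed),
    anchored = FALSE), class = "trajectory_model")
  model
}

#' Anchor the trajectory direction at the control-like end
#'
#' If control cells have a larger mean pseudotime than case cells, applies
#' the model's exact label-switching symmetry t -> 1 - t, t0 -> 1 - t0,
#' k -> -k, which leaves the posterior unchanged, so that the axis proceeds
#' from control-like to disease-like cells.
#'
#' @param model A `trajectory_model`.
#' @param status Named per-cell status vector (`"control"`/`"case"`).
#' @return The anchored `trajectory_model`.
#' @export
anchor_direction <- function(model, status) {
  status <- status[model$pseudotime$cell_id]
  if (!all(c("control", "case") %in% status)) {
    stop("both statuses must be present", call. = FALSE)
  }
  m_ctrl <- mean(model$pseudotime$t[status == "control"])
  m_case <- mean(model$pseudotime$t[status == "case"])
  if (m_ctrl > m_case) {
    model$pseudotime$t <- 1 - model$pseudotime$t
    model$genes$t0 <- 1 - model$genes$t0
    model$genes$k <- -model$genes$k
  }
  model$anchored <- TRUE
  model
}

#' Order genes by their switch point along the axis
#'
#' @param model An anchored `trajectory_model`.
#' @return Tibble sorted ascending by `t0` (ties broken by gene id):
#'   `gene_id`, `t0`, `direction` (sign of k), `k`, `tertile`
#'   (`"early"`/`"mid"`/`"late"` by t0 rank).
#' @export
order_genes_by_switch <- function(model) {
  if (!isTRUE(model$anchored)) {
    stop("anchor the model with anchor_direction() first", call. = FALSE)
  }
  out <- dplyr::arrange(model$genes, .data$t0, .data$gene_id)
  n <- nrow(out)
  tert <- cut(seq_len(n), breaks = c(0, n / 3, 2 * n / 3, n),
              labels = c("early", "mid", "late"))
  tibble::tibble(gene_id = out$gene_id, t0 = out$t0,
                 direction = ifelse(out$k >= 0, "up", "down"),
                 k = out$k, tertile = as.character(tert))
}

#' Serialize a trajectory model to JSON
#' @param model A `trajectory_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(model, path) {
  jsonlite::write_json(
    list(pseudotime = model$pseudotime, genes = model$genes,
         beta0 = model$beta0, beta1 = model$beta1,
         log_posterior = model$log_posterior, seed = model$seed,
         restarts = model$restarts, anchored = model$anchored),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
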