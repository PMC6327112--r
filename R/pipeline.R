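#' Build a pipeline configuration
#'
#' One structured configuration drives [run_pipeline()]: stage toggles,
#' per-stage parameters and an explicit seed for every random stage. The
#' configuration round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param outdir Output directory for all stage files.
#' @param seed Master seed; stage seeds default to offsets of it.
#' @param sim A [sim_config()] for the simulate stage (seeded from `seed`
#'   unless supplied).
#' @param stages Character vector of enabled stages, in any order; they
#'   always execute in the fixed order simulate, qc, overdispersion,
#'   disease_axis, bulk_de, core_set, pseudotime_switch, convergence.
#' @param qc,overdispersion,disease_axis,bulk_de,core_set,pseudotime,convergence
#'   Per-stage parameter lists; see Details for defaults.
#'
#' @details Stage parameter defaults: qc uses the GAPDH blank rule with
#'   `k_mad = 3`, `z_cut = -2`; overdispersion tests at 5% FDR with
#'   `mean_floor = 1`; disease_axis uses 500 variable genes and searches 5
#'   components; bulk_de tests at 5% FDR excluding the outlier donor;
#'   core_set intersects at 5%/5% with silhouette-chosen k; pseudotime runs
#'   10 restarts; convergence samples 1000 background genes against a
#'   simulated network with planted effect 1.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            sim = NULL,
                            stages = c("simulate", "qc", "overdispersion",
                                       "disease_axis", "bulk_de", "core_set",
                                       "pseudotime_switch", "convergence"),
                            qc = list(), overdispersion = list(),
                            disease_axis = list(), bulk_de = list(),
                            core_set = list(), pseudotime = list(),
                            convergence = list()) {
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  defaults <- list(
    qc = list(reference_gene = "GAPDH", k_mad = 3, z_cut = -2,
              plate_blacklist = character()),
    overdispersion = list(fdr = 0.05, mean_floor = 1),
    disease_axis = list(n_variable = 500, K = 5, force_component = NULL,
                        fdr_switch = 0.05),
    bulk_de = list(fdr = 0.05, exclude_donor = "GBA3"),
    core_set = list(fdr_bulk = 0.05, fdr_switch = 0.05, k = NULL,
                    k_range = 2:5, seed = seed + 10L),
    pseudotime = list(n_restarts = 10, seed = seed + 20L),
    convergence = list(n_background = 1000, seed = seed + 30L,
                       planted_effect = 1, network_seed = seed + 40L,
                       zero_fill = TRUE))
  merge_stage <- function(name, user) utils::modifyList(defaults[[name]], user)
  structure(list(outdir = outdir, seed = seed, stages = stages, sim = sim,
                 qc = merge_stage("qc", qc),
                 overdispersion = merge_stage("overdispersion", overdispersion),
                 disease_axis = merge_stage("disease_axis", disease_axis),
                 bulk_de = merge_stage("bulk_de", bulk_de),
                 core_set = merge_stage("core_set", core_set),
                 pseudotime = merge_stage("pseudotime", pseudotime),
                 convergence = merge_stage("convergence", convergence)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$donors <- as.data.frame(cfg$sim$donors)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- cfg$sim
  sim$donors <- dplyr::bind_rows(lapply(
    seq_along(sim$donors$id),
    function(i) tibble::tibble(id = sim$donors$id[i],
                               status = sim$donors$status[i],
                               is_outlier = sim$donors$is_outlier[i])))
  sim_args <- sim[setdiff(names(sim), character())]
  sim_obj <- do.call(sim_config, sim_args)
  pipeline_config(outdir = cfg$outdir, seed = cfg$seed, sim = sim_obj,
                  stages = cfg$stages,
                  qc = cfg$qc, overdispersion = cfg$overdispersion,
                  disease_axis = cfg$disease_axis, bulk_de = cfg$bulk_de,
                  core_set = cfg$core_set, pseudotime = cfg$pseudotime,
                  convergence = cfg$convergence)
}

stage_order <- c("simulate", "qc", "overdispersion", "disease_axis",
                 "bulk_de", "core_set", "pseudotime_switch", "convergence")

stage_deps <- list(
  qc = "simulate", overdispersion = "qc", disease_axis = "qc",
  bulk_de = "simulate",
  core_set = c("bulk_de", "disease_axis"),
  pseudotime_switch = c("core_set", "disease_axis"),
  convergence = c("core_set"))

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in the fixed order simulate, qc,
#' overdispersion, disease_axis, bulk_de, core_set, pseudotime_switch,
#' convergence, handing results between stages as plain files under
#' `config$outdir`. Every output file is recorded in a manifest with its
#' MD5 content hash; a rerun from the same configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with `stages` (per-stage summary list),
#'   `manifest` (tibble `file`, `md5`), `seeds`, `warnings`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  enabled <- intersect(stage_order, config$stages)
  for (st in enabled) {
    miss <- setdiff(stage_deps[[st]], enabled)
    if (st %in% names(stage_deps) && length(miss)) {
      stop("stage ", st, " requires enabling: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stages <- list()
  files <- character()
  env <- new.env(parent = emptyenv())

  withCallingHandlers({
    if ("simulate" %in% enabled) {
      env$sim <- simulate_cells(config$sim)
      env$bulk <- simulate_bulk(env$sim$truth, config$sim)
      write_simulation(env$sim, file.path(outdir, "sim"))
      write_matrix(env$bulk$matrix, file.path(outdir, "bulk_counts.tsv"), "tsv")
      readr::write_tsv(env$bulk$samples, file.path(outdir, "bulk_samples.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, "sim", c("matrix/matrix.mtx",
                                                   "matrix/genes.tsv",
                                                   "matrix/cells.tsv",
                                                   "matrix/unit",
                                                   "cells.tsv", "truth.json")),
                 file.path(outdir, c("bulk_counts.tsv", "bulk_samples.tsv")))
      stages$simulate <- list(n_cells = ncol(env$sim$matrix),
                              n_genes = nrow(env$sim$matrix),
                              seed = config$sim$seed)
    }
    if ("qc" %in% enabled) {
      p <- config$qc
      env$qc <- run_qc(env$sim$matrix, env$sim$cells,
                       reference_gene = p$reference_gene,
                       k_mad = p$k_mad, z_cut = p$z_cut,
                       plate_blacklist = p$plate_blacklist)
      readr::write_tsv(env$qc$report, file.path(outdir, "qc_report.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, "qc_report.tsv"))
      stages$qc <- list(retained = sum(env$qc$report$kept),
                        removed = sum(!env$qc$report$kept),
                        threshold = env$qc$threshold)
    }
    if ("overdispersion" %in% enabled) {
      p <- config$overdispersion
      fit <- fit_technical_noise(env$qc$matrix, mean_floor = p$mean_floor)
      env$overdispersion <- test_overdispersion(env$qc$matrix, fit,
                                                fdr = p$fdr, normalize = TRUE)
      readr::write_tsv(env$overdispersion, file.path(outdir, "overdispersion.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, "overdispersion.tsv"))
      stages$overdispersion <- list(
        n_tested = sum(!is.na(env$overdispersion$q)),
        n_flagged = sum(env$overdispersion$over_dispersed),
        a1 = fit$a1, alpha = fit$alpha)
    }
    if ("disease_axis" %in% enabled) {
      p <- config$disease_axis
      status <- stats::setNames(env$qc$cells$status, env$qc$cells$cell_id)
      env$axis <- compute_disease_axis(env$qc$matrix, status,
                                       n_variable = p$n_variable, K = p$K,
                                       force_component = p$force_component)
      env$switch <- switch_de(env$qc$matrix, env$axis, fdr = p$fdr_switch)
      readr::write_tsv(tibble::tibble(cell_id = names(env$axis$score),
                                      score = unname(env$axis$score)),
                       file.path(outdir, "axis.tsv"), progress = FALSE)
      readr::write_tsv(env$switch, file.path(outdir, "switch_de.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, c("axis.tsv", "switch_de.tsv")))
      stages$disease_axis <- list(component = env$axis$component_index,
                                  correlation = env$axis$case_control_correlation,
                                  n_significant = sum(env$switch$significant))
    }
    if ("bulk_de" %in% enabled) {
      p <- config$bulk_de
      env$bulk_de <- run_bulk_de(env$bulk$matrix, env$bulk$samples,
                                 fdr = p$fdr, exclude_donor = p$exclude_donor)
      readr::write_tsv(env$bulk_de, file.path(outdir, "bulk_de.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, "bulk_de.tsv"))
      stages$bulk_de <- list(n_significant = sum(env$bulk_de$significant),
                             excluded = p$exclude_donor)
    }
    if ("core_set" %in% enabled) {
      p <- config$core_set
      lg <- log2_tpm1(env$qc$matrix)
      # cluster on the variable genes used for the axis; markers are
      # evaluated over all endogenous genes
      lg_var <- subset_expr(lg, genes = attr(env$axis, "variable_genes"))
      if (is.null(p$k)) {
        ck <- choose_k(lg_var, k_range = p$k_range, seed = p$seed)
        clu <- ck$clustering
        stages$core_set_k <- list(k = ck$k)
      } else {
        clu <- consensus_cluster(lg_var, k = p$k, seed = p$seed)
      }
      env$markers <- detect_markers(lg, clu$labels)
      env$core <- intersect_core_set(env$bulk_de, env$switch, env$markers,
                                     fdr_bulk = p$fdr_bulk,
                                     fdr_switch = p$fdr_switch)
      readr::write_tsv(tibble::tibble(cell_id = names(clu$labels),
                                      cluster = unname(clu$labels)),
                       file.path(outdir, "cluster_labels.tsv"), progress = FALSE)
      readr::write_tsv(env$markers, file.path(outdir, "markers.tsv"),
                       progress = FALSE)
      readr::write_tsv(env$core, file.path(outdir, "core_set.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, c("cluster_labels.tsv", "markers.tsv",
                                            "core_set.tsv")))
      s <- attr(env$core, "summary")
      stages$core_set <- list(total = unname(s["total"]),
                              n_down = unname(s["n_down"]),
                              n_up = unname(s["n_up"]))
    }
    if ("pseudotime_switch" %in% enabled) {
      p <- config$pseudotime
      if (nrow(env$core) >= 5) {
        # normalize on the full transcriptome, then restrict to core genes
        sub <- subset_expr(log2_tpm1(env$qc$matrix), genes = env$core$gene_id)
        model <- fit_trajectory(sub, env$axis, n_restarts = p$n_restarts,
                                seed = p$seed)
        status <- stats::setNames(env$qc$cells$status, env$qc$cells$cell_id)
        model <- anchor_direction(model, status)
        env$trajectory <- model
        order_tab <- order_genes_by_switch(model)
        readr::write_tsv(model$pseudotime, file.path(outdir, "pseudotime.tsv"),
                         progress = FALSE)
        readr::write_tsv(order_tab, file.path(outdir, "gene_order.tsv"),
                         progress = FALSE)
        write_trajectory(model, file.path(outdir, "trajectory_model.json"))
        files <- c(files, file.path(outdir, c("pseudotime.tsv", "gene_order.tsv",
                                              "trajectory_model.json")))
        stages$pseudotime_switch <- list(log_posterior = model$log_posterior,
                                         n_genes = nrow(model$genes))
      } else {
        warning("core set too small for trajectory fitting; stage skipped")
        stages$pseudotime_switch <- list(skipped = TRUE)
      }
    }
    if ("convergence" %in% enabled) {
      p <- config$convergence
      truth_core <- env$sim$truth$switch_params$gene_id
      universe <- c(rownames(env$sim$matrix)[!spikein_mask(env$sim$matrix)],
                    default_pd_genes())
      network <- simulate_network(truth_core, default_pd_genes(), universe,
                                  planted_effect = p$planted_effect,
                                  seed = p$network_seed)
      core_genes <- if (nrow(env$core) >= 10) env$core$gene_id else truth_core
      conv <- run_convergence(env$qc$matrix, core_genes, network,
                              n_background = p$n_background, seed = p$seed,
                              zero_fill = p$zero_fill)
      env$convergence <- conv
      readr::write_tsv(tibble::tibble(gene_id = names(conv$weights),
                                      weight = unname(conv$weights)),
                       file.path(outdir, "inclusion_weights.tsv"), progress = FALSE)
      readr::write_tsv(tibble::tibble(gene_id = conv$sample$genes),
                       file.path(outdir, "background_sample.tsv"), progress = FALSE)
      readr::write_tsv(conv$comparison, file.path(outdir, "link_comparisons.tsv"),
                       progress = FALSE)
      files <- c(files, file.path(outdir, c("inclusion_weights.tsv",
                                            "background_sample.tsv",
                                            "link_comparisons.tsv")))
      stages$convergence <- list(
        p_core_core = conv$comparison$p[conv$comparison$comparison == "core-core vs bg-bg"],
        n_background = conv$sample$n)
    }
  }, warning = note)

  manifest <- tibble::tibble(file = sub(paste0("^", outdir, "/?"), "", files),
                             md5 = unname(tools::md5sum(files)))
  structure(list(stages = stages, manifest = manifest,
                 seeds = list(master = config$seed, sim = config$sim$seed,
                              core_set = config$core_set$seed,
                              pseudotime = config$pseudotime$seed,
                              convergence = config$convergence$seed,
                              network = config$convergence$network_seed),
                 warnings = warnings_log, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n stages:", paste(names(x$stages), collapse = ", "),
      "\n files:", nrow(x$manifest),
      "\n warnings:", length(x$warnings), "\n")
  invisible(x)
}
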