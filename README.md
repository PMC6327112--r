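# diseaseaxis

Case-control single-cell RNA-seq rarely yields two clean cell states.
More often, diseased and healthy cells are spread along a *continuous*
process — some patient cells still look control-like, others have
progressed further. `diseaseaxis` is an R package for analyzing exactly
that situation in plate-based (Smart-seq2-style) experiments with ERCC
spike-ins and blank wells, as in iPSC-derived neuron case-control studies.
It provides a tested, fully reproducible implementation of the analysis
arc from raw count matrices to an ordered disease trajectory:

1. **Quality control** — plate flagging by housekeeping expression, the
   blank-well rule (any cell whose reference-gene log2(TPM+1) falls
   strictly below the maximum observed in blank wells is removed), and
   robust per-plate MAD outlier filtering.
2. **Spike-in over-dispersion** — technical noise calibrated on spike-ins
   as CV² = a₁/mean + α; genes varying beyond it are flagged by a
   chi-squared test at 5% FDR, and pathway genes are ranked by rank-sum
   tests between donor groups (this is what stratifies an outlier
   patient).
3. **Disease axis** — PCA on the 500 most variable genes; the component
   most correlated with case/control status, oriented control → case, is
   the latent axis. Per-gene switch-like differential expression along it
   uses the sigmoid model μ(t) = 2·μ₀·logistic(k·(t − t₀)) with a
   likelihood-ratio test (df = 2).
4. **Bulk DE** — a transparent per-gene NB-GLM with median-of-ratios size
   factors, trend-shrunk moment dispersions, a technical-replicate
   covariate and a Wald test.
5. **Core gene set** — the three-way intersection of bulk hits, switch
   hits, and consensus-cluster marker genes (AUROC > 0.85), keeping only
   direction-consistent genes.
6. **Joint pseudotime** — a zero-inflated sigmoid factor model over the
   core genes: per-cell pseudotimes and all switch parameters are inferred
   together by MAP quasi-Newton ascent with restarts, anchored so
   control-like cells sit at t ≈ 0, and genes are ordered into early/late
   events by their switch time t₀.
7. **Functional convergence** — gamma fits to core and background mean
   expression, expression-matched background sampling by density ratio
   (1000 genes, without replacement), and one-sided rank-sum comparisons
   of link weights on a gene similarity network against known disease
   genes.

A first-class synthetic-data module (`simulate_cells()`, `simulate_bulk()`,
`simulate_network()`) generates datasets with this exact structure plus
ground truth, so every stage is validated by recovery, calibration and
power tests rather than on faith.

## A worked example

```r
library(diseaseaxis)

sim <- simulate_cells(sim_config(seed = 7))
sim$matrix
#> <expr_matrix> 2041 genes x 156 cells [counts]; 40 spike-ins, 6 blanks

qc <- run_qc(sim$matrix, sim$cells)
cat("retained", sum(qc$report$kept), "of", sum(!sim$cells$is_blank),
    "cells; blank threshold", round(qc$threshold, 2), "log2(TPM+1)\n")
#> retained 126 of 150 cells; blank threshold 10.06 log2(TPM+1)

status <- setNames(qc$cells$status, qc$cells$cell_id)
axis <- compute_disease_axis(qc$matrix, status)
glance(axis)
#> # A tibble: 1 × 3
#>   component_index orientation case_control_correlation
#>             <int>       <dbl>                    <dbl>
#> 1               1           1                    0.811

fit <- fit_technical_noise(qc$matrix)
glance(fit)
#> # A tibble: 1 × 4
#>      a1 alpha n_spikeins_used mean_floor
#>   <dbl> <dbl>           <int>      <dbl>
#> 1  1.04 0.109              37          1

res <- test_overdispersion(qc$matrix, fit)
cat(sum(res$over_dispersed), "of", sum(!is.na(res$q)),
    "genes over-dispersed at 5% FDR\n")
#> 133 of 2001 genes over-dispersed at 5% FDR
```

The QC stage removed the 6 blank wells, all 12 planted low-quality cells
(reference gene ablated, caught by the blank threshold of 10.06), and a
handful of MAD outliers. The axis here lands on the first principal
component — on these synthetic data the disease process is the dominant
source of variation — with point-biserial correlation 0.81 to
case/control status. The spike-in fit recovers the generating technical
noise (asymptotic CV² α ≈ 0.11 against a simulated NB dispersion of 0.1),
and the over-dispersion test flags 133/2001 genes, dominated by the
planted switch and outlier-pathway genes.

The whole arc, driven by one seeded configuration with plain-file
handoffs and a hashed output manifest:

```r
report <- run_pipeline(pipeline_config(outdir = "run1", seed = 7))
report$stages$core_set
#> $total   [1] 57
#> $n_down  [1] 50
#> $n_up    [1] 7
```

On this synthetic replicate the recovered core set (57 genes, 50 down /
7 up) overlaps the planted 60-gene truth at Jaccard 0.95 with every
direction call correct. `tidy()` / `glance()` methods and `plot_*()`
functions (`plot_technical_noise()`, `plot_axis()`, `plot_switch_gene()`,
`plot_gene_order()`, `plot_link_comparison()`) cover the result types.

See the methods vignette (`vignettes/disease-axis-methods.Rmd`) for the
models, priors, numerical choices, and what the synthetic data do and do
not establish.

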