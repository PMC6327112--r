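---
title: "Methods: the disease-axis model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the disease-axis model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(diseaseaxis)
```

# Overview

`diseaseaxis` implements a case-control single-cell analysis built around
one idea: when diseased and healthy cells differ along a *continuous*
process rather than falling into discrete states, the informative object is
a latent per-cell coordinate — a disease axis, formally identical to a
pseudotime — along which genes switch on or off. The pipeline stratifies
donors by spike-in-calibrated over-dispersion, finds the axis by PCA,
derives a core gene set by intersecting three independent lines of evidence
(bulk differential expression, switch-like differential expression along
the axis, cluster-discriminating markers), refines the axis by jointly
refitting pseudotimes and switch parameters on the core set alone, and
finally asks whether the core set is functionally coherent on a weighted
gene similarity network, using expression-matched background genes as the
null.

This vignette records the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish.

# The switch model

Per gene, expression on the log2(TPM+1) scale is modeled as a sigmoid in
the axis coordinate $t \in [0,1]$:

$$\mu(t) = 2\,\mu_0\,\mathrm{logistic}\big(k\,(t - t_0)\big)$$

so that $\mu(t_0) = \mu_0$ (half the plateau), the sign of $k$ gives the
direction of regulation and its magnitude the abruptness, and $t_0$ is the
switch time used to order genes into early and late events. Units: $\mu_0$
is in log2(TPM+1); $k$ is per unit of the rescaled axis; $t_0$ is on the
unit axis.

Two fitting regimes share this mean function:

* **Screening (`switch_de()`)** — the axis is fixed (a rescaled principal
  component); each gene is fit by maximum likelihood under Gaussian
  residuals and tested against the constant-mean model by a likelihood
  ratio with 2 extra parameters (chi-squared, df = 2). The likelihood is
  multi-modal in $(k, t_0)$, so optimization is multi-start: a $t_0$ grid
  of 0.1–0.9 with both activation signs, plus a flat start. Benjamini-
  Hochberg correction is applied across tested genes.
* **Refinement (`fit_trajectory()`)** — pseudotimes and all gene
  parameters are inferred *jointly* under a zero-inflated extension:
  an observation is exactly zero (dropout) with probability
  $\mathrm{logistic}(\beta_0 + \beta_1 \mu_{ng})$ and Gaussian around
  $\mu_{ng}$ otherwise. Priors: $t_n \sim N(0.5, 1)$ and
  $t_{0g} \sim N(0.5, 0.1^2)$, both truncated to $[0,1]$;
  $k_g \sim N(0, 50^2)$; $\mu_{0g} \sim N^+(0, 10^2)$; dropout
  coefficients $N(0, 10^2)$. The fit is maximum a posteriori, not full
  posterior inference: a deterministic, restartable optimum was preferred
  to MCMC for a pipeline whose contract is bit-reproducibility; the priors
  follow the published defaults of the Bayesian tool this stage models
  itself on, and are exposed via `trajectory_priors()`.

Numerically, parameters live on unconstrained scales (logistic transforms
for $t$ and $t_0$, softplus for $\mu_0$, log for $\sigma$) and the
posterior is maximized by limited-memory quasi-Newton ascent with an
Armijo backtracking line search, so every accepted step improves the
posterior; a restart is converged when the relative change drops below
1e-8, with a 5,000-iteration cap. Restart 0 starts at the rescaled disease
axis; the rest jitter it (sd 0.2). The objective and gradient are
implemented in compiled code with a pure-R reference implementation, and
the two are cross-checked to 1e-10 in the test suite. The model has an
exact label-switching symmetry $(t, t_0, k) \to (1-t, 1-t_0, -k)$;
`anchor_direction()` resolves it so control-like cells sit at $t \approx 0$.

The coordinate handed to `fit_trajectory()` must be normalized on the full
transcriptome *before* restricting to the core genes: TPM re-normalization
within a small panel rescales every cell by a different denominator and
distorts switch times.

# Quality control

Three filters run in a fixed order (plate, blank-reference, cell outlier),
mirroring the narrative order of the protocol the pipeline reproduces:

1. **Plate flagging** — per plate, the median log2(TPM+1) of a
   housekeeping panel; plates below `z_cut = -2` robust z-scores (MAD
   across plates) are flagged; an explicit blacklist overrides, since
   plate removal in any real study is ultimately a judgment call.
2. **Blank-reference rule** — the retention threshold is the *maximum*
   reference-gene (GAPDH) expression over blank wells on the log2(TPM+1)
   scale; non-blank cells strictly below it are removed. "Below" is read
   strictly, so a cell exactly at the threshold is retained. The scale is
   configurable because protocols differ on counts vs TPM vs log; log2(TPM+1)
   is the default used throughout this package.
3. **Cell outliers** — a transparent replacement for trained-classifier
   QC: log total counts, log detected genes and spike-in fraction, each
   compared to its plate's median; beyond `k_mad = 3` MADs removes the
   cell with a recorded reason. Zero-MAD features never trigger removal;
   plates with fewer than 5 cells fall back to global statistics with a
   warning. The rule is auditable and testable, which a shipped classifier
   with trained weights would not be.

# Spike-in over-dispersion

Technical noise is calibrated on spike-ins as
$\mathrm{CV}^2(\bar m) = a_1/\bar m + \alpha$, fit by iteratively
reweighted least squares over spike-ins with mean normalized count at or
above `mean_floor = 1` (below it the sample CV² is unstable). A negative
asymptote is clamped to zero with `a1` refit. Endogenous genes are
size-factor normalized by per-cell spike-in totals (spike-ins isolate the
technical scaling; endogenous totals are a configurable fallback), and a
gene's statistic $(n-1)\,\mathrm{CV}^2_g / (a_1/\bar m_g + \alpha)$ is
referred to the upper chi-squared tail with $n-1$ df, with BH correction
across tested genes only.

One subtlety matters for calibration: when the technical line is fit on
spike-ins normalized by totals that *include* the spike-in itself, its
variance is self-suppressed, the line sits too low, and endogenous genes —
which inherit the size-factor noise in full — are flagged at well above
the nominal rate. `fit_technical_noise()` therefore normalizes each
spike-in by leave-one-out spike-in totals by default. With this choice the
pure-technical null flags well under 1% of genes at a 5% FDR, and 4-fold
excess biological CV² on 5% of genes at mean 50 is detected with
essentially full power (both recomputed by `scripts/acceptance.R`).

The within-pathway ranking used to nominate validation genes is a
two-group Wilcoxon rank-sum test on log2(TPM+1), ordered by p-value with
ties broken by absolute median difference. The rank-sum p-value is exact
for tie-free pooled samples under 50 observations and otherwise uses the
tie-corrected normal approximation with continuity correction; fully tied
data return one-sided 0.5 by convention.

# Axis, bulk DE, and the core-set intersection

The axis is found among the first `K = 5` centered, unscaled principal
components of the 500 most variable genes (variance in log space) as the
component most correlated (point-biserial) with case/control status,
oriented so control cells score lower; the component index can be forced
for datasets where it is known. `axis_stability()` recomputes the PCA on
case cells alone and reports the best correlation with the full-data axis:
a high value argues the axis is a continuous within-case process rather
than a batch split between groups.

Bulk differential expression is a deliberately transparent NB-GLM:
median-of-ratios size factors (rescaled to median 1, so scaling one
library by c yields a factor of exactly c), a per-gene moment dispersion
estimate with residual-df correction shrunk 50/50 in log space toward a
log-linear mean-dispersion trend (floor 1e-8, ceiling 10), and a Wald test
on the status coefficient referred to a t distribution with residual df —
at three-versus-three samples the t reference keeps the null fraction of
p < 0.05 near nominal where a normal reference is anticonservative. The
model is fit to size-factor-normalized counts, which makes fold-change
estimates exactly invariant to rescaling any single library. Technical
replicates enter as a design covariate; a donor blacklist supports the
leave-the-outlier-out analysis. This stage is not a DESeq2 clone — no
outlier replacement, no shrunk fold changes — because the downstream
consumer is a thresholded intersection, not the fold changes themselves;
an independent DESeq2 fit is used in the test suite as a cross-check and
agrees on direction and magnitude.

Consensus clustering is a reduced SC3-style scheme: three cell-cell
distances (Euclidean, Pearson, Spearman) × spectral dimensionalities
d ∈ 4..7, each embedded by the first d principal components of the
distance matrix and clustered by k-means; the mean co-assignment matrix is
cut by complete-linkage hierarchical clustering at k. k defaults to the
silhouette-optimal value over 2..5 (overridable). Clustering runs on the
variable-gene panel — on the full matrix the signal drowns in noise genes.
Markers are one-vs-rest AUROC (folded to ≥ 0.5) with a rank-sum p, at the
cited tool's published defaults AUROC > 0.85, p < 0.01; both thresholds
are assumptions, exposed as arguments.

The core set is the plain three-way intersection of bulk hits, switch
hits, and markers, with direction assigned only when the bulk fold-change
sign and the switch sign agree; disagreeing genes are excluded and logged,
since a "consistent" set should not contain genes whose two assays point
in opposite directions.

# Functional convergence

Mean log2(TPM+1) of the core set and of all other genes are each fit by a
gamma law — maximum likelihood via Newton iteration on the profile score
for the shape (rate closed-form given shape), so the fitted mean equals
the sample mean exactly. Zeros are excluded with a logged count: a gene
never observed contributes no expression-matching information. Each
non-core gene receives an un-normalized inclusion weight equal to the
core-to-background density ratio at its mean (computed in log space,
clamped at exp(±700)), and 1000 distinct background genes are drawn
without replacement with probability proportional to the weight — a gene
*set* cannot contain duplicates. Link weights between classes (core,
matched background, and a 12-gene known-disease panel) are compared by
one-sided rank-sum tests; absent edges count as weight zero by default (a
linkage network stores positive evidence only), with exclusion as the
configurable alternative.

The matched-sampling calibration check deserves a caveat: sampling without
replacement can only match the target law when the candidate pool is deep
in the matched region. The check therefore runs at transcriptome scale
(19,000 candidates, core mean modestly above background, matching the
regime the method is designed for); with a small pool or an extreme
mean shift the matched tail is exhausted and the sampled distribution is
visibly truncated — a usage limit of the estimator, not a bug.

# The synthetic data

`simulate_cells()` generates the structure the analysis assumes: ~150
cells from six donors (three control, three case, one case donor an
outlier), a latent axis with 60 switch genes (52 down, 8 up) whose
parameters are drawn from documented ranges ($\mu_0 \in [2,5]$,
$|k| \in [6,15]$, $t_0 \in [0.25,0.75]$), pseudotimes Beta(2,5) for
controls and Beta(5,2) for cases (partial overlap along the axis),
negative-binomial counts (dispersion 0.1) at library depth 5e5 with
log-normal depth variation, logistic mean-dependent dropout
($\beta_0 = 2$, $\beta_1 = -1$ on log2 expression), spike-ins spanning
log2 levels 1–9 with purely technical noise, a coherently upregulated
20-gene module (+2 log2) in the outlier donor, blank wells, and planted
low-quality cells whose reference gene is ablated. The latent scale is
log2(TPM+1) directly — expected TPM is $2^\lambda - 1$ and background
genes are rescaled once so the transcriptome totals ~1e6 — so recovered
switch parameters are comparable to planted ones without per-gene offsets.

Two generator choices are worth flagging. Blank wells receive a *flat*
ambient rate per gene plus a guaranteed trace of the reference gene,
rather than ambient proportional to the cell profile: under per-cell TPM
normalization a proportional ambient profile would put blank reference
expression at the same level as real cells and the blank-threshold rule
could not be exercised. And the reference housekeeping gene is exempt from
dropout, so that intact cells are never spuriously removed by the blank
rule; at its expression level the modeled dropout probability is
negligible anyway. Bulk samples are NB resamples of the donor-averaged
expected profiles (no dropout — bulk RNA does not suffer single-cell
capture loss), with technical replicates sharing expectations exactly.

What passing on these data shows: the estimators recover the quantities
they target in a regime that matches their assumptions (NB noise,
logistic dropout, a single linear axis, sigmoid kinetics). What it does
not show: robustness to batch kinetics beyond plate labels, UMI chemistry,
branching or cyclic trajectories, non-NB technical noise, or misspecified
dropout — real-data features deliberately out of the generator's scope.

# Problem sizes and reproducibility

Every stochastic stage takes an explicit seed and the pipeline's contract
is bit-identical reruns (verified by manifest hashes). The test-suite and
acceptance-script simulations run at the study's own scale — 150 cells,
2,000 genes, 60 core genes, 3+3 bulk samples — with Monte-Carlo replicate
counts (10–50 seeds for calibration rates, 100–200 for distributional
checks) chosen to keep sampling error well inside the asserted margins.

# Known limitations

* The MAP trajectory fit reports point estimates only; no posterior
  uncertainty on switch times. A Metropolis sampler over the same
  posterior is a natural extension.
* The Gaussian residual model for log2(TPM+1) ignores the mean-variance
  relationship within a gene; the zero-inflation term absorbs most of the
  damage at low expression in the joint fit, but the screening stage has
  no dropout component (the simplest faithful form; a zero-inflated
  screen is an extension point).
* Whether the axis rescaling ahead of switch fitting matches the original
  analysis is unknowable from the text; rescaling to [0,1] was chosen so
  switch times are interpretable, and the likelihood-ratio statistic is
  invariant to that affine choice.
* The consensus scheme is a reduced variant (no graph-Laplacian
  transformation, k-means only); it is deterministic given its seed.
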