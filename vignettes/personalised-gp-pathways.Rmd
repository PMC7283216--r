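---
title: "Personalised GP differential expression and pathway enrichment: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised GP differential expression and pathway enrichment: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgpde)
```

# The modelling problem

`pgpde` targets longitudinal case-control studies in which each diseased
subject is matched to a healthy control and both are sampled a handful of
times (typically 3–12) at irregular, non-aligned ages. Two features of such
data drive the design:

1. **Sparse, uneven time courses.** Cross-sectional tests and spline fits
   are unreliable at these sample sizes; a Gaussian process regression
   borrows strength across time points, handles replicates and missing
   regions, and provides calibrated interpolation with uncertainty.
2. **Disease heterogeneity.** In complex diseases different pairs perturb
   different genes (or the same gene in different directions, or through
   different probe-sets). Pooling subjects before testing averages these
   signals away. `pgpde` therefore tests *within* each pair and aggregates
   only at the pathway level.

# Gene-level models

For one feature in one pair, let `x^A` and `x^B` be the case and control
series. The *separate* model fits independent GPs to `x^A` and `x^B`; the
*joint* model fits a single GP to the pooled series. Both use a zero-mean GP
with the squared-exponential kernel

$$k(t_i, t_j) = \sigma^2_{se} \exp\!\big(-(t_i - t_j)^2 / (2 \ell_{se}^2)\big)$$

plus iid Gaussian observation noise $\sigma^2_\epsilon$. Before each fit the
data are centred by their own mean — **independently** for the case, the
control and the pooled series. A consequence worth stating plainly: a level
shift common to both groups is invisible to every model, while a case-only
level shift survives inside the pooled series (the pooled mean splits the
difference) and therefore does raise the evidence for the separate model.
The method is direction-agnostic: mirroring both trajectories leaves all
scores unchanged.

## Hyperparameter priors

| parameter | prior | default | rationale |
|---|---|---|---|
| length-scale $\ell_{se}$ (weeks) | Normal(30, 6) | mean 30, var 6 | ~30-week dynamics; discourages wiggly fits that chase noise |
| signal sd $\sigma_{se}$ | half-Student-t(scale 1, df 20) | — | weakly informative on log-expression scale |
| noise variance $\sigma^2_\epsilon$ | scaled-inv-$\chi^2$(scale 0.01, df 1) | — | concentrates on small noise but heavy-tailed enough to absorb misfit |

Two conventions here were genuinely open and are configurable through
`hyper_priors()`:

* the "square-root Student-t" prior is read as a half-t on the signal
  *standard deviation* (scale 1, df 20);
* the scaled-inverse-$\chi^2$ parameter 0.01 is read as the *scale*
  parameter $\tau^2$ (not the variance of the distribution).

The tight length-scale prior is a modelling statement: trajectories are
expected to vary on a ~30-week scale. Signals much faster than that are
deliberately treated as noise — synthetic tests in this package generate
trajectories with length-scales of 20–30 weeks for exactly this reason.

## Marginal likelihood by central composite design

Type-II maximum likelihood is unstable at these sample sizes, so
hyperparameters are integrated out numerically. All integration happens on
the natural-log scale `w = log(ℓ, σ²_se, σ²_ε)`; priors are stated on the
natural scale, so the log-scale density includes the change-of-variables
Jacobian.

`find_mode()` maximises the unnormalised log posterior by multi-start BFGS
(5 starts around the prior-based initial point, analytic gradients, a fixed
RNG substream so results are independent of evaluation order), then takes a
central-difference Hessian of the analytic gradient. `build_ccd()` whitens
the space with the Hessian's eigendecomposition and places the mode, $2d$
star points and a full $2^d$ factorial at whitened radius
$r_0 = f\sqrt{d}$ with $f = 1.1$ ($d = 3$, so $R = 15$ points; clamping
hyperparameters reduces $d$). The integration weights are the standard CCD
choice that integrates a standard Gaussian exactly: the mode receives
$(2\pi)^{d/2}(1 - f^{-2})$ and each remaining point
$(2\pi)^{d/2} e^{r_0^2/2} / (n_p f^2)$. Along each half-axis a
split-Gaussian scale is found by bisection so that the *actual* log
posterior drops by $r_0^2/2$ at the design point; the points are stretched
accordingly, and each point's volume element carries the product of its
per-axis scales (half-axes not visited by a point contribute the average of
their two sides). The log marginal likelihood is the log-sum-exp of
`log joint + log Δ + log volume`; the degenerate single-point grid recovers
the mode's log joint exactly, and on one-dimensional toy problems the
estimate tracks fine-grid quadrature within a few hundredths of a nat (the
test suite enforces 0.5).

Predictions use the same grid: `predictive_distribution()` mixes the
fixed-hyperparameter posteriors with weights proportional to
$q(\theta_r)\Delta_r$ (split-Gaussian values), **renormalised to sum to
one** — without renormalisation the predictive mean would scale arbitrarily
with the unnormalised posterior. The mixture covariance is the weighted
average of the per-point covariances, deliberately *without* the
between-component mean-dispersion term of the law of total variance: the
method's defining equations state the plain weighted sum, and fidelity was
preferred to a variance inflation the downstream KL threshold would simply
re-absorb. This slightly understates predictive variance when the
hyperparameter posterior is diffuse.

## Scores and thresholds

* **BF score** (`bf_score_pair()`, driver `score_tc()`): log marginal
  likelihood of the separate models minus the joint model. The DE threshold
  is 4 (≈ 54.6 linear), the conventional "strong evidence" cut.
* **KL score** (`window_predictives()` + `kl_score()`, driver
  `score_window()`): the symmetric KL divergence between the separate
  model's stacked case/control predictive Gaussian (zero cross-covariance)
  and the joint model's duplicated predictive, over a 26-week window at
  weekly resolution **ending at and including the event week** (the window
  is "prior to the event"; anchoring is configurable). Both Gaussians have
  dimension `2 × 26 = 52`. The KL is computed in the group-centred
  coordinates the GPs were fit in — consistent with the BF path, shape
  differences rather than level differences carry the signal.
* **KL threshold calibration** (`calibrate_kl_threshold()`): KL scores have
  no absolute calibration, so the default 250 can be replaced by the mode of
  the KL scores of features whose BF score is within ±1 of the BF threshold
  (borderline DE). The mode of a continuous sample needs a density
  estimate: a Gaussian KDE with Silverman bandwidth on `log(1 + score)`,
  maximised on a 512-point grid. Fewer than 30 borderline features triggers
  the configured default with a warning. The pathway stage is robust to the
  exact value either way.
* **Probe-set collapsing** (`collapse_probesets()`): per pair, a gene is
  represented by its maximum-scoring probe-set; pairs may choose different
  probe-sets of the same gene.

# Pathway enrichment

The per-pathway statistic is the adjusted geometric mean of scaled overlaps
$f_{ij} = \mathrm{overlap}_{ij}/\mathrm{DEG}_j + \alpha$ with
$\alpha = 10^{-6}$; the geometric mean prevents a single DEG-rich pair from
dominating. The null distribution shuffles the feature labels of the score
matrix's rows — one shared permutation across all pairs per iteration,
preserving the cross-pair correlation of each feature's scores — and redoes
probe-set collapsing and thresholding inside every permutation (vectorised
as a threshold-then-`rowsum` collapse so 10^5 permutations are practical).
Empirical p-values use the add-one estimator $(1 + r)/(B + 1)$: the
observed statistic is counted into its own null, p-values can never be
zero, and the estimator is valid at any $B$. Pathways with no genes on the
platform are reported with p = 1 (flagged by `n_genes = 0`), never silently
dropped. A pair with zero DE genes makes the statistic undefined; this is
reported as a configuration error directing the user to drop the pair.
Benjamini–Hochberg correction is `stats::p.adjust`; results are annotated at
FDR < 0.1 and < 0.05 by default.

The combined baseline (`combined_de()`, `fisher_enrichment()`) pools all
cases and all controls into one pair, scores with the identical machinery
and the same thresholds, and tests pathways with the one-sided
hypergeometric tail against the platform universe (all genes represented
after probe-set mapping — the conservative choice; the universe is not
stated by convention and is configurable by passing a different set). For
combined window analyses the personalised KL threshold is reused.

# The synthetic-data generator

`simulate_expression()` emulates the study design, not the platform:

* matched pairs with 3–12 samples per individual at stratified
  visit-window times (one uniform draw per scheduled window, the way
  follow-up cohorts sample around planned visit ages); case and control
  times never coincide;
* null features: one latent GP draw per pair observed by both individuals
  through independent noise — the shared-draw correlation is what the joint
  model exploits;
* DE features: per-pair activation (default probability 0.15, chosen so
  that the expected pairwise DEG-overlap fraction sits in the ~15% regime
  characteristic of heterogeneous cohorts), a per-pair choice of carrier
  probe-set, and one of three mechanisms — an independent case draw, a
  smooth additive bump inside the pre-event window, or a sign flip — with a
  configurable direction-flip probability;
* planted pathways whose members are forced DE in a fresh random fraction
  (default 40%) of members per pair;
* defaults: 6 pairs, 104-week horizon, length-scale 20 weeks, signal
  variance 1, noise variance 0.25 (signal-to-noise 4).

It does **not** emulate probe-level microarray artefacts, batch effects,
normalisation, heavy-tailed noise, or gene-gene correlation beyond pathway
co-activation. Passing tests therefore demonstrate correctness of the
machinery and its operating characteristics under the generative model the
method assumes — not robustness to violations of that model on real data.

# Numerical choices

* **Jitter ladder**: Cholesky factorisations start at `1e-8 × mean(diag)`
  and escalate tenfold to `1e-2 × mean(diag)` before raising an error that
  names the offending feature and pair.
* **KL regularisation**: predictive covariances on a dense weekly grid are
  numerically rank-deficient. Both covariances receive the *same* ridge
  (escalated jointly), which keeps the divergence well-defined and
  nonnegative; regularising the two matrices independently produces
  arbitrary log-determinant offsets.
* **Non-PD Hessians** at the mode are projected to the nearest
  positive-definite matrix by eigenvalue clipping, with a warning.
* **Degenerate hyperparameters** (under- or overflow in the log joint)
  yield an explicit `-Inf`, never a silent `NA`.
* **Failure quarantine**: a feature/pair whose fit fails is recorded in the
  `rejects` attribute of the score table and excluded; a run never aborts on
  a single feature. Long-run checkpointing is not implemented — at the
  problem sizes this package targets a scoring run completes in minutes, and
  rerunning is cheaper than resume logic.
* **Determinism**: every stochastic step (restart jitter, permutations,
  simulation) runs in a preserved RNG substream seeded from its arguments,
  so results are byte-identical across reruns and independent of feature
  order and worker count (`threads` uses forked workers over features).

# Problem sizes in the test suite

The suite exercises the documented operating characteristics at sizes a
laptop handles in minutes, chosen as the smallest regimes where the
properties are informative: quadrature comparisons on 3-point series;
Monte-Carlo KL at 10^6 draws; exhaustive enumeration of all 120 row
permutations of a 5-feature matrix; null calibration with 500 pathways at
B = 2000; planted-pathway recovery with 6 pairs, 200 genes and 40% per-pair
member activation; and BF discrimination (ROC AUC > 0.9) at
signal-to-noise 4 with 8 time points per individual, 6 pairs and 200
features. `scripts/acceptance.R` recomputes all of these from a single
`--seed`.

# Known limitations

* Gaussian observation models only; heavy-tailed or count data need a
  different likelihood.
* One kernel (squared exponential); periodic or non-stationary dynamics are
  out of scope.
* The window analysis assumes the event time is known per pair.
* The combined window analysis inherits the personalised KL threshold
  rather than calibrating its own.
* Scores are computed feature-by-feature; no information is shared across
  features beyond the pathway stage.
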