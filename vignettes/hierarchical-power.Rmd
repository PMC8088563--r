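---
title: "Simulating nested single-cell data and estimating power for differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nested single-cell data and estimating power for differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a hierarchical simulator

In a multi-subject single-cell RNA-seq experiment the cells of one
individual are not independent replicates: they share that individual's
genetic background, environment and state, so expression values are
correlated within individuals. Any power calculation that simulates cells
independently treats the study as if it had thousands of independent
units when it really has ten or twenty, and the resulting "power" is
largely a disguised type-1 error. `nestedpower` simulates the nested
structure explicitly and evaluates analysis methods against it, so that
power is attributed to the right unit — the individual.

## The generative model

For gene $i$, individual $j$ and cell $k$:

1. **Grand mean.** $\mu_i \sim \mathrm{Gamma}(\text{shape}, \text{rate})$,
   the gene's expected expression on a TPM-like scale.
2. **Individual mean.** $\mu_{ij} = \max\{0,\; \mu_i + \delta_{ij}\}$ with
   $\delta_{ij} \sim N(0, f_1(\mu_i))$ and $f_1(\mu) = a_1 + b_1\mu$ the
   linear inter-individual variance trend ($f_1$ is floored at zero
   before use). Clamping at zero rather than redrawing preserves the
   additive-normal construction; its side effects on estimation are
   handled explicitly (below).
3. **Cell value.** $Y_{ijk} \sim \mathrm{NB}(\text{mean} = \mu_{ij},
   \text{size} = f_2(\mu_i))$ with $f_2(\mu) = a_2 + b_2\log\mu$, clamped
   to $[10^{-4}, 10^{6}]$. The size parameter is the classical
   negative-binomial dispersion in its `size` form: the within-individual
   variance is $\mu + \mu^2/\text{size}$, so the upper clamp is an
   explicit Poisson limit (no excess dispersion). Moment inversion gives
   $\text{size} = \mu^2/(\sigma^2 - \mu)$ for an overdispersed
   mean-variance pair; at or below the boundary $\sigma^2 \le \mu$ the
   cap is returned and flagged.
4. **Dropout.** Every value is zeroed independently with a per-gene
   probability drawn from a gamma distribution truncated to $[0,1]$
   (rejection sampling). Dropout is applied *on top of* the NB draws, so
   observed zeros are the union of sampling zeros and dropout zeros; the
   estimation side measures total zeros, and the simulated total zero
   fraction slightly exceeds the gamma draw for genes whose NB zero mass
   is not negligible.

Cells per individual follow one of three regimes: `fixed` (constant),
`poisson` (mild imbalance), or `negbin` with size 1 (strong imbalance,
variance $\mu + \mu^2$). Zero draws are redrawn, since an individual with
no cells is unobservable and would break the mixed models.

**Effects.** For two-group designs the user-specified fold change
multiplies the grand mean in one group; the affected group is chosen per
gene by a Bernoulli(0.5) draw so the direction of effect balances. The
fold change is applied *before* the individual means are drawn, so the
spiked group's inter-individual variance and dispersion are evaluated at
the spiked mean ($f_1(\mu_i \cdot FC)$, $f_2(\mu_i \cdot FC)$) — effects
propagate through the whole hierarchy, not just the mean. For continuous
phenotypes, each individual receives $P_j \sim N(m, s^2)$ (defaults 22
and 5, an arbitrary but plausible clinical scale) and, for effect genes,
the individual-level deviation is constructed jointly with the
standardized phenotype:
$\delta_{ij} = \sqrt{f_1(\mu_i)}\,(\rho z_j + \sqrt{1-\rho^2}\,e_{ij})$.
This makes $\rho$ the correlation between phenotype and *individual-level*
expression. The observable cell-level (or per-individual-average)
correlation is attenuated by within-individual sampling noise and by the
log transform used downstream; that attenuation is a property of real
data too and is deliberately not corrected.

**Determinism.** Every simulation consumes a single RNG stream in a fixed
stage order under one root seed, so a seed reproduces a dataset
bit-for-bit. The power engine derives one sub-seed per simulated gene
from its root seed by a fixed linear map (`derive_seed`), making grids
reproducible and extensible under partial re-runs.

## Estimating the model from pilot data

`estimate_model()` runs three steps.

**Pruning.** Genes are reduced to a mutually weakly-correlated subset:
genes are visited in a seeded random order and each visited survivor
removes all not-yet-visited genes with Spearman correlation above 0.25
(midranks for ties; constant genes have no defined correlation and are
not removed on that account). The visiting order is random because the
rule is order-dependent; the seed is recorded in the model provenance.

**Per-gene summaries** (`estimate_gene_params()`):

- *Dropout rate*: the fraction of exact zeros.
- *Grand mean*: the mean of 1000 resampled one-cell-per-individual
  averages, which decouples the estimate from unequal cell counts and
  within-individual correlation. Because the resampled average includes
  zeros, it estimates the observed (post-dropout) mean; the table also
  reports the dropout-corrected value, raw /(1 − dropout), which is what
  the model fits use. Without this correction the fitted model would
  describe the zero-inflated observed scale while the simulator applies
  dropout on top of latent draws — the estimate/simulate loop would not
  be self-consistent and closed-loop recovery would fail by construction.
- *Inter-individual variance*: the sample variance (denominator J′−1) of
  per-individual non-zero means, over individuals with at least one
  non-zero cell. A noise-adjusted version subtracts the average sampling
  variance of those means (the one-way method-of-moments correction),
  because each mean is estimated from finitely many cells and the raw
  variance is systematically inflated.
- *Within-individual dispersion*: per individual, the non-zero mean and
  variance give a moment-matched size; per gene, a pooled inverse-size is
  estimated as the weighted ratio
  $\hat\phi_i = \sum_j w_j(\hat\sigma^2_{ij}-\hat\mu_{ij}) / \sum_j w_j\hat\mu_{ij}^2$
  with $w_j = n_j - 1$. The ratio-of-sums form is stable and nearly
  unbiased where per-individual ratios are wild.

**Hyper-distribution fits** (`fit_model()`):

- *Grand means*: gamma by maximum likelihood (genes with zero corrected
  grand mean are excluded; gamma support is positive).
- *f1*: the default fit corrects for the zero-clamping of individual
  means. A gene whose latent individual mean clamps at zero contributes
  only zero cells for that individual, which silently removes the
  individual from the non-zero summaries; for low-expressed genes the
  observed quantities are therefore those of a *lower-truncated* normal —
  the estimated grand mean converges to $\mu + \sigma\lambda(r)$ and the
  observed between-individual variance to
  $\sigma^2(1 - r\lambda(r) - \lambda(r)^2)$, with $r = \mu/\sigma$ and
  $\lambda$ the inverse Mills ratio. The fit iterates between inverting
  the truncated-mean map per gene and refitting a weighted line on the
  de-truncated variances, excluding genes with dropout above 0.9 or
  $r < 0.3$ (too little latent information). A plain least-squares line
  is available as `f1_method = "ols"`; in closed-loop experiments during
  development it showed intercept errors of tens of percent, which is why
  the corrected fit is the default.
- *f2*: fitted on the inverse-size scale with a Gamma GLM and the
  canonical inverse link — exactly the model
  $1/\text{size} = 1/(a_2 + b_2\log\mu)$. Fitting sizes directly would
  propagate the Jensen bias of $1/\hat\phi$ into the trend.
  Poisson-capped genes are excluded so the cap cannot distort the line.
- *Dropout*: gamma by maximum likelihood on rates moved inward by
  $10^{-6}$ at the boundaries (a likelihood on (0,1) cannot take exact 0
  or 1); at simulation time samples are rejected until within $[0,1]$.
  The bounds and truncation scheme of the dropout distribution are a
  design choice; rejection sampling keeps the fitted shape/rate
  interpretable while guaranteeing valid probabilities.

## The tests

**Two-part hurdle.** On $\log(x+1)$ values, the discrete part is a
logistic regression of the expression indicator on the predictor and the
continuous part a Gaussian regression of the level on the predictor using
expressing cells only (the level model is explicitly conditional on
expression). With random effects, both parts carry a normally distributed
per-individual intercept. Each part is tested for the predictor by
likelihood ratio (default) or Wald; the statistics and degrees of freedom
are summed — the indicator and the conditional level are conditionally
independent, so the summed statistic remains asymptotically chi-squared.
Conventions:

- The mixed logistic part is fitted on per-individual binomial aggregates
  whenever the predictor is constant within individuals (always true
  here), which is likelihood-equivalent and much faster; the adaptive
  quadrature uses 10 points by default, validated against brute-force
  numerical integration in the test suite (agreement of the marginal
  log-likelihood to 1e-4 on a hand-sized fixture).
- Degenerate components — all-zero gene, all-expressed indicator, or a
  conditional part with fewer than three expressing cells or no predictor
  contrast — contribute statistic 0 with 0 degrees of freedom and are
  flagged; a fully degenerate gene gets p = 1. How to handle an
  uninformative discrete part is not fixed by convention; the 0-df choice
  simply lets the remaining component speak.
- A failed likelihood-ratio refit falls back to a Wald test for that
  component and records it. Boundary (zero) random-effect variance
  estimates are accepted as-is; no boundary-corrected null distribution
  is applied — the reference distributions are plain chi-squared.
- Non-converged fits in power loops count as non-rejections and are
  tallied separately; this is conservative and cannot inflate power.

**Naive hurdle.** The same two parts without random intercepts — the
cells-as-independent analysis whose inflation the package quantifies.

**Pseudo-bulk.** Each individual is collapsed to the mean of its
$\log(x+1)$ values (zeros included; `log_mean` and `nonzero_mean`
aggregations are available as options since the aggregation scale is a
genuine free choice), then a Welch t-test (binary) or Pearson correlation
test (continuous) is applied at the individual level.

## The power engine

`estimate_power()` simulates genes one at a time under the design — genes
are independent in the generative model, so one single-gene dataset per
replicate is equivalent to a multi-gene dataset and embarrassingly
parallel — applies the chosen test and reports the rejection proportion
at $\alpha$ (default 0.05) with its binomial Monte-Carlo standard error.
No multiple-testing correction is applied: power is per-test at fixed
$\alpha$. The default of 500 replicates bounds the Monte-Carlo standard
error by 0.023. `estimate_type1()` is the same loop with the effect
nullified, so type-1 error and power share one code path by construction.
`power_grid()` crosses designs with methods under one root seed and
returns a tidy table; `autoplot()` draws the curves.

## The synthetic default model and what validation shows

`default_model()` is a fully synthetic parameterization emulating a
moderately expressed gene panel in plate-based single-cell TPM data from
a homogeneous cell population: gamma(5, 0.05) grand means (mean 100, CV
0.45), $f_1 = 200 + 3\mu$ (between-individual CV ≈ 0.22 at 100 TPM),
$f_2 = -6 + 3\log\mu$ (size ≈ 7.8 at 100 TPM, overdispersion decreasing
with expression) and gamma(8, 16) dropout (mean 0.5, sd 0.18). Two
considerations fixed these constants: plausibility for the kind of data
described above, and *identifiability* — the closed-loop validation asks
every hyper-parameter to be recovered within 10% from a pilot of 5000
genes, 10 individuals and 100 cells, and with a strongly right-skewed
mean distribution or near-zero trend intercepts the intercepts are not
recoverable at that precision by any estimator at that problem size (the
regression intercepts' standard errors alone exceed the band). The
constants are fixture definitions, not estimates of any particular
dataset.

The generator deliberately omits several features of real data: gene-gene
correlation (genes are simulated independently; the pruning step makes
estimation consistent with that), cell-type mixtures, batch effects, and
library-size variation (values are treated as already normalized).
Passing the validation suite therefore shows that the pipeline is
internally consistent and that the analysis methods behave as claimed *on
data with a pure nested structure* — it does not certify behavior under
batch confounding or compositional shifts.

The validation suite (run with the package tests) checks, at scales
chosen to keep the whole suite in the minutes range: closed-loop recovery
of all hyper-parameters (5000 genes, 10 × 100 cells); type-1 error of the
mixed hurdle within three binomial standard errors of 0.05 over 400 null
genes (10/group, 50 cells) alongside the naive hurdle's inflation (its
realized type-1 error is ≈ 0.4 on the same nulls); exact additivity of
the hurdle combination and the chi-squared behavior of summed component
deviates; simulator moment checks for every stochastic stage; and the
qualitative power structure — power increasing in the number of
individuals (0.38 → 0.62 → 0.86 at fold change 1.3 for 5, 10, 20 per
group in the suite's configuration) with the naive analysis far above the
mixed one.

## Interface

The package's interface is its R functions; power studies are interactive
or scripted R work, so no shell entry point is shipped.
`scripts/acceptance.R` is a worked example of fully scripted use:
estimation, simulation, testing and power summaries driven by a single
seed, with JSON output.

## Limitations

- The hurdle models assume the predictor is shared by all cells of an
  individual (group or individual-level phenotype); cell-level covariates
  fall back to slower cell-level fits and are otherwise untested.
- Power for very small designs (≲ 4 individuals per group) rests on
  asymptotic chi-squared reference distributions; expect some level
  distortion there.
- The continuous-phenotype $\rho$ is an individual-level target;
  cell-level correlations are attenuated, so power for a given observable
  correlation is lower than a cell-level reading of $\rho$ would suggest.
- Run time is dominated by the mixed-model fits (roughly 0.1 s per gene
  at 20 individuals); pseudo-bulk is orders of magnitude faster and is a
  reasonable screen before refining a design with the mixed hurdle.
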