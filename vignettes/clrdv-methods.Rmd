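---
title: "Differential variability testing of RNA-seq counts with clrdv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variability testing of RNA-seq counts with clrdv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrdv)
```

## The problem

Most RNA-seq methods compare mean expression between conditions. But a
gene's expression *variability* can change without its mean moving —
for instance when a disease state constrains a regulatory program, so
expression across patients becomes tighter (or looser) than in
controls. Detecting such differentially variable (DV) genes requires a
test on a spread parameter, not a location parameter.

`clrdv` tests, for each gene, whether the standard deviation of its
(transformed) expression differs between two populations of samples,
irrespective of any mean difference.

## The model

### Counts as compositions

A sequencing run measures relative, not absolute, abundance: each
sample is a vector of counts constrained by its library size, i.e. a
composition. The centered log-ratio (CLR) transform maps a
composition to unconstrained Euclidean space. For gene $g$ in sample
$i$ with count $x_{gi}$ over $G$ retained genes,

$$\mathrm{CLR}(x_{gi}) = \log x_{gi} - \frac{1}{G}\sum_{g'=1}^{G}\log x_{g'i},$$

with natural logarithms. Zero cells are first replaced by a
pseudo-value of 0.5; nonzero counts are left untouched. Each
transformed sample sums to zero, and the transform is invariant to
rescaling a sample — so no between-sample normalization (TMM and the
like) is needed anywhere in the pipeline.

Two points were genuinely open in designing this step and are settled
as follows:

* **Pseudo-counts are per-cell.** The replacement applies only to the
  cells that are zero, not to every cell of an affected gene or
  sample. This leaves all observed counts untouched, which is the
  least invasive reading; a global offset would perturb every
  log-ratio.
* **The CLR is computed once, on the pooled filtered matrix**, and the
  columns are then split by group for model fitting. The dataset is a
  single composition per sample; transforming per group would make
  the two groups' CLR values live on different baselines and the SD
  comparison less interpretable.

### Gene filtering

Before the transform, genes are filtered on the pooled samples: a gene
is removed if its mean counts-per-million (CPM, computed against
pre-filter library sizes) is strictly below 0.5, or if it is zero in
at least 85% of samples. The boundary is deliberate — a gene with mean
CPM exactly 0.5 is kept. Both thresholds are exposed as parameters of
`filter_genes()`, `run_clrdv()` and the CLI. Filtering is idempotent
(removing genes only shrinks library sizes, so retained genes' CPM can
only rise), and the geometric mean in the CLR uses only the retained
genes.

### The skew-normal model in centered parameters

Per gene and group, CLR values are modeled as skew-normal. In the
direct parametrization (DP) the density is

$$f(y) = \frac{2}{\omega}\,\phi\!\left(\frac{y-\xi}{\omega}\right)
  \Phi\!\left(\alpha\,\frac{y-\xi}{\omega}\right),$$

with location $\xi$, scale $\omega > 0$ and shape $\alpha$; at
$\alpha = 0$ it is the normal density. The DP is convenient for
optimization but statistically awkward: its Fisher information is
singular at $\alpha = 0$. The centered parametrization (CP) —
mean $\mu$, standard deviation $\sigma$, skewness $\gamma$ — fixes
this, and $\sigma$ is exactly the quantity a variability test needs.
The CP skewness is bounded:
$|\gamma| < k = \sqrt{2}(4-\pi)/(\pi-2)^{3/2} \approx 0.9953$
(`sn_skewness_bound()`). The maps `dp_to_cp()` / `cp_to_dp()` are
exact inverses (round-trip error below $10^{-8}$ is tested).

### Estimation

`fit_sn_cp()` maximizes the likelihood numerically in
$(\xi, \log\omega, \alpha)$ from method-of-moments starting values
(sample skewness clamped to $\pm 0.95k$ before inversion). Standard
errors come from the inverse *observed* information of the
log-likelihood re-expressed in CP coordinates, by numerical
differentiation; observed information is preferred to expected because
it is what the data at hand support and it avoids fragile analytic
expected-information expressions near $\gamma = 0$. The penalty term
of a penalized fit is excluded from the information: it is not twice
differentiable in $\gamma$ at zero and would corrupt the $\gamma$
standard error.

Skew-normal likelihoods misbehave in two known ways: the shape
estimate can diverge to the boundary (e.g. on half-normal-like
samples), and the optimizer can stall. A three-rung ladder keeps every
returned fit finite and flagged:

1. plain MLE; accepted if the optimizer converges, $|\hat\alpha| \le 50$,
   and the CP information is positive definite;
2. otherwise, maximum penalized likelihood with the logarithmic shape
   penalty $c_1 \log(1 + c_2\alpha^2)$
   ($c_1 = 0.87591$, $c_2 = 0.85625$, the constants of the
   penalized-MLE literature), restarted from the fixed shape grid
   $\{-5, -1, 1, 5\}$;
3. otherwise, the normal submodel with $\hat\gamma = 0$ and
   closed-form standard errors.

The `method` field of the fit records which rung produced it. Fits are
deterministic given the data: the restart grid is fixed, and the
optimizer runs with parameter tolerance $10^{-8}$. The hard floor is
20 observations per group (below that the fit errors), with a warning
below 50, where $\sigma$ estimation becomes unreliable.

### The test

For gene $g$ with group fits $\hat\sigma_{g,1}, \hat\sigma_{g,2}$ and
their variances from the CP information,

$$Z_g = \frac{\hat\sigma_{g,2} - \hat\sigma_{g,1}}
  {\sqrt{\widehat{\mathrm{Var}}(\hat\sigma_{g,1}) +
         \widehat{\mathrm{Var}}(\hat\sigma_{g,2})}}$$

is asymptotically standard normal under equal SDs; the test is
two-sided ($p = 2(1-\Phi(|Z_g|))$) because variability can shrink or
grow under treatment. P-values are adjusted with the
Benjamini–Yekutieli (BY) step-up procedure, which controls the FDR
under arbitrary dependence — appropriate here because CLR values of
different genes are algebraically coupled through the per-sample
geometric mean. Genes whose fit fails in either group are reported
with `status = "fit_failed"` and excluded from the BY family rather
than silently dropped. The effect size is the SD ratio
$\hat\sigma_{\mathrm{treatment}}/\hat\sigma_{\mathrm{control}}$,
reported also as log2; genes with BY-adjusted $p < 0.05$ (the
configurable `alpha`) are flagged.

## The simulation protocol

`clrdv_benchmark()` implements the evaluation protocol the test was
designed against. Per-gene NB2 negative-binomial models (variance
$\mu + \phi\mu^2$, size $= 1/\phi$) generate counts; both groups share
parameters except a proportion `prop_dv` (default 10%) of genes whose
*size* parameter in the treatment group is multiplied by a fold $x$
drawn from $(0.25, 0.5) \cup (2, 4)$. Means are identical across
groups by construction, so any signal is pure variability:
$\phi' = \phi/x$, and $x > 1$ tightens the spiked group. Where the
protocol leaves details open, the generator chooses once: each
interval is picked with probability 1/2 and the fold is uniform within
it; the fold is drawn independently per spiked gene; the treatment
group is always the spiked one (all configurable).

`estimate_nb2()` fits NB2 parameters to real seed counts by maximum
likelihood with a method-of-moments fallback
($\hat\phi = \max(0, (s^2-\bar x)/\bar x^2)$, floored at $10^{-8}$).
When no seed dataset is available, `synth_nb2_params()` stands in: a
seeded closed-form generator with log-normal means (median 150
counts, log-sd 1.3, truncated to $[2, 5\times10^4]$ — spanning
roughly CPM 1–1,000 at the implied library sizes) and dispersions
following the familiar decreasing mean–dispersion trend
$0.1 + 4/\mu$ with log-normal noise (log-sd 0.35, capped at 5).
These values describe a generic bulk RNA-seq cohort; they are fixed
defaults, not tuning knobs. What the generator does *not* emulate:
library-size heterogeneity between samples, gene–gene correlation,
outlying samples, and batch structure. Passing benchmarks on this
generator therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to every artifact of
real data.

`score_calls()` computes the confusion summary with the conventions
FDR $= \mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$ (0 when nothing is
called) and Type II error $= \mathrm{FN}$ over the number of true DV
genes. The packaged experiment sizes — 2,000 genes, 100 samples per
group, 5 instances for the benchmark; 2,000 genes with 500 replicates
for goodness-of-fit — are the scales at which the method's operating
characteristics stabilize while keeping a full run in minutes on one
CPU.

## Goodness of fit

`clrdv_gof()` screens the skew-normal assumption per gene with a
one-sample Kolmogorov–Smirnov test against the fitted CDF (computed
via Owen's T function), asymptotic p-values, and the estimated
parameters plugged in. Plug-in KS is a diagnostic, not a calibrated
test: estimating parameters from the same sample makes it
conservative, so the pass proportion (`gof_summary()`, threshold
$p > 0.05$) should be read as a model-adequacy rate, and no
small-sample or bootstrap correction is applied — deliberately, since
the screening convention this package follows does the same. At the
packaged protocol scale the pass rate is in the high 90s percent
(recomputed by `scripts/acceptance.R`, never hard-coded).

## Numerical choices and degenerate inputs

* Skew-normal CDF via Owen's T with 48-node Gauss–Legendre quadrature
  after reflecting the second argument into $[0, 1]$; accurate to
  ~$10^{-10}$ against adaptive quadrature.
* Constant input vectors error (scale not estimable); all-zero genes
  are removed by filtering before any fit; a sample with zero library
  size errors by name.
* `nlminb`'s "singular convergence" at tight tolerances is accepted as
  convergence; every accepted optimum must still produce a positive
  definite CP information, otherwise the ladder advances.
* BY adjustment excludes missing p-values from the family size; the
  0/0 FDR convention is 0.
* All simulation randomness flows through explicit seeds;
  `synth_nb2_params()` and `simulate_two_groups()` are bit-reproducible
  given `(G, seed)`.

## Limitations

* Exactly two groups; no covariates, no longitudinal structure.
* The test is on $\sigma$ only — differential mean and differential
  skewness are out of scope.
* Asymptotics: group sizes below ~50 make $\sigma$ standard errors
  optimistic; the package warns but does not refuse (hard floor 20).
* The skew-normal is a model for *CLR-transformed* counts; very sparse
  genes that survive filtering can still fit poorly, which is exactly
  what the KS screen is for.
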