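---
title: "Propagating covariance uncertainty through recursive path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating covariance uncertainty through recursive path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprop)
```

## The scientific problem

Behavioural ecologists routinely find that individual animals differ
consistently in traits such as aggressiveness or how fast they explore a
novel environment ("animal personality"), that these traits are correlated
between individuals ("behavioural syndromes"), and that they covary with
fitness proxies. What is usually missing is the *mechanistic pathway*: does
aggressiveness lower fledgling production directly, or indirectly because
aggressive males feed their nestlings less, their partners compensate, and
partner provisioning is what keeps nestlings alive? Simple bivariate
correlations confound these routes; a recursive path model separates them.

`pathprop` implements the complete inference chain for this class of study
in a population with biparental care:

1. **Preprocessing** converts raw assays into analysis variables: approach
   latency into a stage-centred aggression score, feeding-visit counts into
   hourly provisioning rates.
2. **Repeatability** quantifies whether the behavioural assays measure a
   stable individual attribute at all, via a Bayesian random-intercept model.
3. **Covariance posterior**: a multivariate Gaussian model with missing-data
   augmentation yields 1,000 posterior draws of the trait covariance matrix.
4. **Path propagation**: every draw is fitted exactly as a recursive path
   model, so each direct and compound path carries the full estimation
   uncertainty of the covariance matrix.
5. A **synthetic generator** with known structural ground truth makes the
   whole chain testable by parameter recovery.

## The path model and its exact fit

A path diagram is a DAG over observed variables, optionally with
correlation edges between exogenous variables. On the correlation scale the
standardized coefficients of a *recursive* model have a closed form: for
each endogenous variable $y$ with parent set $P$,

$$\beta_y = R_{PP}^{-1}\, R_{Py}, \qquad \psi_y = 1 - R_{yP}\,\beta_y ,$$

the partial regression of $y$ on all of its parents simultaneously. No
iterative SEM optimization is involved, which is why fitting one matrix
costs microseconds and fitting 1,000 draws is cheap. The model-implied
correlation matrix is $(I-B)^{-1}\Psi (I-B)^{-\top}$, where
$B[\mathrm{child},\mathrm{parent}]=\beta$ and $\Psi$ holds residual
variances and exogenous correlations; entry $(i,j)$ equals the tracing-rule
sum over all admissible paths connecting $i$ and $j$. The test suite checks
this equivalence against an exhaustive path-enumeration oracle and checks
$\beta$ against standardized least squares on raw data, both to $10^{-10}$.

Compound (indirect) paths are labelled chains of edges; their coefficient is
the product of the component coefficients, computed **per posterior draw**
and only then summarized. The mean of per-draw products is not the product
of means whenever component draws covary, so collapsing the two would be a
methodological error; a test constructs a skewed example in which they
provably differ. Chains may start by traversing edges against their arrows
(e.g. exploration ← aggression → own feeding rate, the syndrome-mediated
indirect link labelled D): this is the standard tracing-rule traversal. A
forward edge followed by a reversed one is rejected.

## Covariance posterior under missing data

Field datasets of this kind have strongly varying pairwise coverage (here:
pairwise $n$ from the 30s to the 70s at 75 pairs), because each assay covers
a different subset of pairs. Pairwise-complete correlation estimates need
not form a positive-definite matrix, so the package instead fits one joint
Gaussian model by Gibbs data augmentation, alternating

* missing cells from their conditional Gaussians given the observed cells,
* $\mu$ from its Gaussian full conditional (prior variance $10^8$),
* $\Sigma$ from its inverse-Wishart full conditional.

The prior on $\Sigma$ is inverse-Wishart with $p+1$ degrees of freedom and
identity scale, applied after standardizing each variable to observed mean
0 and SD 1; on that scale the prior's marginal correlations are
near-uniform, and coefficients come out standardized, directly comparable
across paths. Missingness is treated as ignorable (MAR). The chain runs
13,000 iterations with 3,000 burn-in and thinning 10, retaining exactly
1,000 covariance draws; with complete data and a fixed mean the sampler
collapses to iid draws from the closed-form conjugate posterior, which the
suite verifies by Kolmogorov–Smirnov distance against direct
inverse-Wishart sampling.

Each draw is rescaled to a correlation matrix before path fitting. Draws
that are numerically indefinite are repaired by clipping eigenvalues at
$10^{-8}$ and renormalizing to unit diagonal — a no-op for well-conditioned
draws; draws with minimum eigenvalue below $-10^{-4}$ are rejected, and more
than 5% rejections aborts the run (it signals a broken input, not noise).

## Summaries and support classification

For every path and compound path the package reports:

* **point estimate**: the mode of a Gaussian KDE (Silverman bandwidth,
  512-point grid) of the 1,000 per-draw values — the "most likely"
  coefficient. Modes are bandwidth-sensitive, so the posterior **mean** is
  always reported alongside (and is what the recovery tests assert on).
* **95% credible interval**: equal-tailed empirical quantiles.
* **tail probability** $p = 2\min(\Pr>0, \Pr<0)$, floored at 1/draws. The
  doubling makes it comparable to a two-sided p-value; because "how often
  the estimate was positive or negative" is ambiguous about sidedness, the
  one-sided fraction is emitted in the CSV as well.
* **support class**: *strong* when the interval excludes zero, *some* when
  it overlaps zero but $p<0.05$, *none* otherwise. "Slightly overlapping
  zero" is operationalized purely as (overlaps and $p<0.05$), with no extra
  width criterion, since no quantitative definition of "slightly" exists.
  An interval touching zero exactly counts as overlapping.

## Repeatability

Repeated assay scores $y_{ij}$ are modelled as
$y_{ij} = x_{ij}^\top b + u_i + e_{ij}$ with
$u_i \sim N(0,\sigma^2_{\mathrm{ind}})$,
$e_{ij}\sim N(0,\sigma^2_{\mathrm{res}})$, flat priors on $b$ and
inverse-gamma(0.001, 0.001) on both variances — a weakly informative
convention for Gaussian variance components; prior and chain-length choices
vary across published analyses of this kind and are often undocumented, so
these defaults are declared as the package's own convention rather than
inferred from any particular study. Per draw,
$R = \sigma^2_{\mathrm{ind}}/(\sigma^2_{\mathrm{ind}}+\sigma^2_{\mathrm{res}})$,
summarized like any coefficient (KDE mode, mean, 95% interval). The sampler
is validated three independent ways: one-way ANOVA moment estimators,
`lme4::lmer` REML fits with a fixed covariate, and the closed-form
inverse-gamma conditional (the full mixed model with a flat fixed-effect
prior has no closed-form marginal, so conjugacy is checked on the exact
conditional the sampler uses).

## Preprocessing choices

Approach latency is strictly positive and right-skewed, so the aggression
score applies a Box-Cox transform *before* negation (negative values admit
no power transform; the operation order is forced) and then centres within
nest stage, because stage strongly affects how quickly males engage an
intruder. $\lambda$ is chosen by profile likelihood on a grid over
$[-2, 2]$ in steps of 0.01, with exact ties resolved toward 0 (the log
transform) for interpretability. Feeding rates are visits per 90-minute
window scaled to feeds/h and averaged over the two observation days; a bird
observed on one day uses that day alone.

## What the generator emulates — and what it does not

The generator draws standardized latent traits in topological order from a
configured DAG: exogenous variables jointly Gaussian, each endogenous
variable $\sum \beta\,\mathrm{parent} + \varepsilon$ with residual SD
$\sqrt{1-\beta^\top R_P \beta}$, so every latent has unit variance and the
generating coefficients are directly comparable to standardized estimates.
The shipped study-scale configurations use the reference male (19-path) and
female (14-path) coefficient sets, exploration repeatability 0.66, feeding
repeatability 0.78, and MCAR missingness rates chosen so pairwise $n$ falls
in the study's 33–73 range at 75 pairs.

Realism layers are deliberately thin and optional:

* latency $= \exp(\text{stage offset} - 0.5\cdot\text{aggression})\times 60$ s
  — an arbitrary monotone map; preprocessing inverts it up to rank, which is
  all that matters. Stage offsets default to 0, −0.3, −0.6 on the log scale
  across nest building, egg laying and incubation.
* counts and dates are affine maps of the latents rounded to integers, with
  fledgling number clamped to brood size. Rounding attenuates correlations,
  so parameter-recovery analyses use the latent columns
  (`observation_scale = FALSE`).
* raw exploration is emitted as a Gaussian-latent-based activity count; no
  explicit count distribution is imposed, since none is documented for the
  assay.
* missingness is MCAR only. The analysis assumes ignorable missingness;
  MAR/MNAR mechanisms would test a different assumption and are out of
  scope.

Consequently, passing recovery tests show that the *inference machinery* is
calibrated under the model's own assumptions (Gaussian latents, linear
effects, MCAR). They do not show robustness to skewed count distributions,
non-linear effects, or informative missingness in real field data.

## Problem sizes and numerical conventions

Parameter-recovery runs use 5,000 pairs and the default 1,000-draw chain —
large enough that sampling error (≈0.014 per correlation entry) stays well
inside the ±0.05 recovery band, small enough to run in seconds. The
repeatability recovery runs use 500 individuals × 2 measures; at that size a
single simulated dataset carries ≈0.02–0.04 SD of variance-decomposition
noise, so recovery fixtures rescale the simulated effects to their nominal
variances (the data realize the stated ICC exactly) and the bias property is
assessed as an average over replicates. Tie-breaks, floors and tolerances:
KDE modes are clamped to [0, 1] for repeatability; tail probabilities are
floored at 1/draws; Box-Cox ties go to the smallest $|\lambda|$;
`(I-B)^{-1}` is computed by dense solve (diagrams are small); all matrix
symmetrizations use $(A+A^\top)/2$.

## Known limitations

* The path fit is exact only for recursive (acyclic) diagrams;
  non-recursive models and latent measurement models are unsupported.
* No fit indices (χ², RMSEA) are computed: the intended use is propagating
  uncertainty through an *a priori* diagram, reporting the full model.
* The covariance model has a single residual level; random effects beyond
  it (e.g. year) must be handled upstream (as stage-centring does) or by
  subsetting.
* KDE modes on 1,000 draws move by a few hundredths with bandwidth; treat
  the mode/mean pair, not either alone, as the point summary.

## A worked micro-example

```{r example, eval = FALSE}
d <- parse_diagram(c("1: aggression -> feed_own",
                     "2: feed_own -> feed_partner"))
cfg <- generator_config(d, c("1" = -0.5, "2" = -0.6), n_pairs = 1000, seed = 1)
pop <- generate_population(cfg)
cd <- fit_mvn_missing(pop$table, vars = d$variables, seed = 2)
pd <- propagate(cd, d, compounds = list(AB = c("1", "2")))
path_report(pd)
```

The `analysis/` directory runs the same chain at study scale end to end:
simulation, preprocessing, repeatability, covariance posterior, and the
final coefficient table with its DOT graph of supported paths.
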