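---
title: "Partitioning behavioral variance among and within individuals"
author: "flexvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning behavioral variance among and within individuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexvar)
```

## The scientific question

Two populations can have identical average behavior and still differ
profoundly in how that behavior is organized. One population may consist of
individuals that each behave consistently but differ strongly from one
another (high among-individual variance $V_A$); another may consist of
near-interchangeable individuals that are each highly variable across
trials (high within-individual variance $V_W$, often read as behavioral
flexibility). In colonization and invasion biology both axes matter:
$V_A$ is the raw material selection can act on, while $V_W$ lets
individuals track novel conditions within their own lifetime. The canonical
summary of their balance is repeatability,

$$R = \frac{V_A}{V_A + V_W},$$

the fraction of phenotypic variance due to consistent individual
differences.

`flexvar` fits this decomposition to long-format behavioral trial data —
one row per individual per context, with each individual labelled by
population and sex — and asks, by formal model comparison, whether $V_A$
and/or $V_W$ differ among the four population-by-sex groups.

## The model and its candidate set

With $y_k$ the (preprocessed) trait value of individual $i(k)$ in group
$g$:

$$y_k = x_k^\top\beta + a_{i(k)} + \epsilon_k,\qquad
a_i \sim N(0, \sigma^2_{A,g(i)}),\qquad
\epsilon_k \sim N(0, \sigma^2_{W,g(k)}).$$

The mean model $x_k^\top\beta$ carries population, sex, their interaction,
and context (treatment coding, first context as baseline). The model is
*double-hierarchical*: not only the mean but also the residual SD has
predictor structure (a saturated group factor). Because that factor is
saturated, parameterizing the four group SDs directly is equivalent to a
log-link regression of $\sigma_W$ on group; the package stores the SDs
directly, which guarantees positivity and admits conjugate updates.

Four nested candidates differ only in which SDs are group-specific: M1
(both shared), M2 ($\sigma_A$ by group), M3 ($\sigma_W$ by group), M4
(both by group). In M2/M4 the random intercept is still a single intercept
per individual — its prior SD simply depends on the individual's group.
That is the statistical content of "among-individual variance varies by
group"; no individual-level slopes over context are fitted. At matched
parameter values forced equal across groups, M4's likelihood reduces
exactly to M1's (this nesting is asserted numerically in the test suite).

## Preprocessing

Traits are analysed on a standardized scale (whole-column mean 0, sample
SD 1; the n−1 convention), which makes fixed effects and variance
components comparable across traits. Skewed traits are first pulled toward
Gaussian shape by a Yeo-Johnson power transform with its parameter chosen
by maximum likelihood; Yeo-Johnson (rather than Box-Cox or a log) handles
the zero and negative values that standardized behavioral scores produce.
Individual trait-context series can be exempted from the transform via
`gaussianize_trait(exclude_context = ...)`, mirroring analyses in which
one series is already Gaussian-looking. The order of operations is
transform first, then standardize; both steps are recorded in
`preprocess_record` objects whose stored parameters invert the pipeline
exactly (round-trip accuracy is tested to 1e-8).

Unbalanced data are supported: trials missing completely at random are
dropped (and counted), and individuals with a single trial remain in the
analysis — they inform $V_A$ weakly and $V_W$ not at all, which the
mixed-model likelihood handles naturally.

## Priors

The study that motivated this design reported only that priors were weakly
informative, so the defaults follow common practice for standardized
responses:

* $\beta_j \sim N(0, 5)$ — essentially flat over the plausible range of a
  standardized trait;
* every SD ($\sigma_{A,g}$, $\sigma_{W,g}$) $\sim$ half-Student-t(3, 0, 2.5)
  — mass near zero, heavy enough tails not to truncate large variances.

All scales are configurable through `prior_config()`. Because the
defaults are a choice, the test suite includes a prior-sensitivity check in
the form of the simulation-based calibration experiment below, which is run
*under the model's own priors* and therefore validates the
prior-to-posterior mapping as a whole.

## Posterior computation

The sampler is a fully conjugate Gibbs scheme, chosen over generic HMC to
keep the package dependency-light and exactly testable against closed
forms:

1. $(\beta, a)$ jointly from their multivariate-normal full conditional
   given the SDs. The per-group cross-products of the combined design
   matrix are precomputed once, so each sweep costs one Cholesky
   factorization of a $(p+m)\times(p+m)$ matrix.
2. Each $\sigma^2_{W,g}$ from an inverse-gamma full conditional, using the
   standard scale-mixture identity: if
   $\sigma^2\mid\xi \sim \mathrm{IG}(\nu/2,\ \nu/\xi)$ and
   $\xi \sim \mathrm{IG}(1/2,\ 1/s^2)$, then marginally
   $\sigma \sim$ half-t$(\nu, s)$. The auxiliary $\xi$ gets its own
   conjugate update.
3. Each $\sigma^2_{A,g}$ likewise, from the individual intercepts of that
   group.

No step needs tuning, warmup draws are always discarded, and there is no
post-warmup adaptation, so retained chains are valid by construction.
Reproducibility is bit-exact: chain $c$ under master seed $s$ uses the
deterministic seed $(s + 104729c) \bmod 2147483629$. Observations are
internally sorted into a canonical (individual, context) order, so results
are exactly invariant to the row order of the input table.

Convergence is monitored with split-$\widehat R$ and rank-normalized,
split-chain bulk effective sample size, computed for every scalar
parameter including the individual intercepts; `fit_mcmc()` warns when the
model parameters miss $\widehat R \le 1.01$ or ESS $\ge 400$, and
`check_convergence()` produces the full report.

### Validation

Three layers of evidence back the sampler, all in the test suite:

* **Closed forms.** With the SDs held fixed the $\beta$ posterior is exactly
  Normal; sampled moments match it to three significant figures. With no
  data the sampler must reproduce its prior, and does.
* **Calibration.** The 95% interval for $\sigma_W$ on iid Gaussian data
  covers the truth at nominal rate across 100 seeded replicates.
* **Simulation-based calibration.** Drawing parameters from the prior,
  simulating a small hierarchical design (8 individuals × 2 trials),
  fitting, and ranking the truth among 19 thinned posterior draws yields
  rank histograms whose uniformity a $\chi^2$ test does not reject at
  $\alpha = 0.01$ over 200 replicates, for $\beta$, $\sigma_A$ and
  $\sigma_W$ simultaneously.

## Model comparison

WAIC and PSIS-LOO are computed from the matrix of *conditional* pointwise
log-likelihoods — the density of each observation given the fixed effects
and its individual's intercept. This is the convention of the standard
Bayesian regression toolchain, and it is stated explicitly because the
marginal-likelihood alternative (integrating the intercepts out) answers a
different predictive question and yields different numbers.

WAIC uses the pointwise-variance penalty ($p_{\text{waic2}}$). PSIS-LOO
forms importance ratios $\propto e^{-\ell_{sk}}$, fits a generalized
Pareto distribution to the largest $\min(0.2S,\ 3\sqrt S)$ ratios by the
Zhang–Stephens profile estimator (with the customary weak prior pulling
the shape toward 0.5), replaces the tail by fitted quantiles, truncates at
the raw maximum, and self-normalizes; the shape $\hat k$ is reported per
observation and values above 0.7 trigger a warning. Both criteria are
reported on the elpd and deviance ($-2\,\mathrm{elpd}$) scales.

Selection takes the maximal elpd with a parsimony tie-break: when the
difference to a simpler model (order M1 < M2 < M3 < M4) is smaller than
half the standard error of that difference, the simpler model wins. Both
WAIC- and LOO-based selections are reported and disagreement is flagged.
The WAIC implementation is tested against a direct formula oracle at
1e-10, and PSIS-LOO against exact leave-one-out refitting of a conjugate
toy model.

## Derived quantities

All derived quantities are computed **draw-wise**, never from summaries:
$V_A = \sigma_A^2$, $V_W = \sigma_W^2$ and $R = V_A/(V_A+V_W)$ per draw
and per group, with shared components broadcast so that, e.g., an M1 fit
yields four identical group summaries and exactly-zero contrasts. Pairwise
group contrasts ($\Delta V_W$, $\Delta R$) are differences of paired
draws, summarized by the posterior mean and the equal-tailed 95% credible
interval (not HPD, matching standard practice). The paired-draws point is
load-bearing: the mean of a contrast equals the difference of means, but
its interval is *not* the difference of marginal intervals — the test
suite asserts both facts.

Two reporting conventions were genuinely open and are resolved as follows:

* **"Substantial"** contrast = 95% equal-tailed interval excludes zero.
  This is the standard Bayesian-CI convention and matches how such tables
  are typically bolded.
* **NA entries for repeatability contrasts.** When a group's
  among-individual variance is indistinguishable from zero, its
  repeatability is not meaningful and contrasts involving it are flagged.
  Posterior draws of $V_A$ are strictly positive, so "indistinguishable
  from zero" is operationalized as the 2.5% quantile of $V_A$ falling
  below 1% of the group's posterior-median total variance. The raw
  contrast value is retained alongside the flag.

## The synthetic-study generator

`study_scenario()` / `simulate_study()` generate data with exactly the
structure the model assumes, serving as the stand-in for raw field data.
The defaults encode the study conditions the package was designed around:

* four population-by-sex groups of 27, 21, 16, 24 individuals (88 total),
  labelled PKF, PKM, PMF, PMM, three contexts each (novel environment,
  familiar environment, novel object), no missingness (a balanced design);
* null population, sex and interaction effects (the reference condition:
  no differences in average behavior between groups, so that any signal in
  the variance structure is not confounded with the mean model), and
  modest habituation effects of context (−0.3 for the familiar
  environment, −0.15 for the novel object, on the standardized scale) —
  magnitudes in the plausible range for open-field habituation, chosen
  once since no empirical values were available;
* a shared among-individual SD of 0.6 and group-specific within-individual
  SDs (0.67, 0.81, 0.87, 0.80). The squares (≈ 0.45, 0.65, 0.76, 0.64)
  sum with $V_A ≈ 0.36$ to a total variance near 1 (a standardized trait)
  and encode a heteroscedastic pattern in which the ancestral-population
  females are distinctly the least flexible and, with $V_A$ shared,
  the most repeatable.

What the generator does *not* emulate: non-Gaussian traits, context-specific
variances, measurement error distinct from within-individual variability,
non-random missingness, or any trajectory-level structure. Passing
recovery tests therefore demonstrates correctness of the inferential
machinery under the model's own assumptions — not robustness to real-data
violations of them.

`recovery_experiment()` wraps generate → fit → summarize over replicates
and reports per-parameter bias, RMSE and 95%-interval coverage, plus the
rate at which each pairwise $\Delta V_W$ contrast is flagged substantial —
the power of the design when group SDs truly differ, and a false-positive
rate when they do not. Under the null, the per-pair flag rate stays near
the nominal 5%; with one female group's $\sigma_W$ doubled, the
corresponding pairs are flagged at far higher rates. Notably, at the
default effect sizes (the subtler default pattern) and $n = 88$,
WAIC-based selection recovers the heteroscedastic model only part of the
time — a realistic statement about the power of a study of this size, not
a defect of the selection machinery, which recovers a 2:1 SD ratio at
well above 70% in the test suite.

## Numerical choices and problem sizes

* Cholesky-based joint updates; per-group cross-products precomputed once.
* Degenerate inputs fail fast with informative errors: constant trait
  columns, single-level factors (named in the rank-deficiency error),
  conflicting individual labels, duplicated trials, non-positive SDs.
* A Yeo-Johnson optimizer failure falls back to the identity transform
  with a warning rather than aborting a pipeline run.
* Tie-breaks in model selection are deterministic (parsimony order).
* Test and acceptance runs use deliberately reduced problem sizes —
  replicate counts of 10–200, chains of a few hundred draws, groups of
  6–25 individuals — sized so that each check is decisive for the property
  it probes while the whole suite stays desk-scale. Production analyses
  should use the defaults (4 chains × 2000 draws after 1000 warmup).

## Known limitations

* Gaussian likelihood only; heavy-tailed or zero-inflated traits must be
  transformed or are out of scope.
* One random-effect level (individual); no crossed or nested designs.
* The conditional-likelihood WAIC/LOO convention makes criteria
  comparable across the four candidates here, but not directly against
  marginal-likelihood implementations.
* PSIS-LOO reliability degrades when $\hat k > 0.7$ for many
  observations (typically very influential individuals); the package
  warns but does not refit those folds exactly.
* The four-group structure (two populations × two sexes) is assumed
  throughout the variance-structure candidates; other grouping factors
  require relabelling into that shape.
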