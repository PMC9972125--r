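---
title: "Model-based classification accuracy and consistency, with uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based classification accuracy and consistency, with uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sumclass)
library(dplyr)
```

## The problem

Screening instruments and short scales are routinely scored by summing item
responses and comparing the summed score $X^* = \sum_j X_{ij}$ to a
cutpoint: a respondent is flagged (for treatment, follow-up, selection) when
the score falls on one side of the cut. The decision we *wish* we could make
uses the latent trait $\eta$ itself — the construct the items measure — with
its own cutpoint. Because the summed score carries measurement error, the
two decisions disagree for some respondents. Two families of indices
describe the quality of summed-score decisions:

* **Classification accuracy (CA)** — agreement between the summed-score
  decision and the latent ("gold standard") decision: the overall
  *classification rate*, *sensitivity* (correct among latent positives) and
  *specificity* (correct among latent negatives).
* **Classification consistency (CC)** — the probability that two parallel
  administrations of the instrument produce the same decision, regardless
  of correctness.

When only a single administration is available, neither can be
cross-tabulated directly; both can, however, be computed from a fitted
**unidimensional linear factor model**
$$X_{ij} = \tau_j + \lambda_j \eta_i + \epsilon_{ij}, \qquad
  \eta_i \sim N(\kappa, \Phi), \quad \epsilon_{ij} \sim N(0, \psi_j),$$
identified by $\kappa = 0$, $\Phi = 1$. The model implies
$$\mu_{X^*} = \tau^* + \lambda^*\kappa, \qquad
  \sigma^2_{X^*} = \lambda^{*2}\Phi + \psi^*, \qquad
  \rho = \mathrm{Cor}(X^*, \eta) =
  \frac{\lambda^*\Phi^{1/2}}{(\lambda^{*2}\Phi + \psi^*)^{1/2}},$$
with starred quantities the sums of the item parameters, and
$\omega = \rho^2$ — coefficient omega, the model-based reliability of the
summed score, which is also the correlation between the summed scores of
two parallel administrations.

$(X^*, \eta)$ is bivariate normal with correlation $\rho$; cutting both
axes partitions it into four quadrants (true/false positives/negatives)
whose masses give the CA indices. $(X^*_1, X^*_2)$ for two parallel forms
is bivariate normal with correlation $\omega$ and a shared cut, giving the
CC index. Quadrant masses are obtained from the bivariate normal CDF:

```{r}
params <- lfm_params(loadings = rep(0.6, 5), intercepts = 3)
implied_moments(params)
classification_indices(params, cutpoints(cut_sd = 0))
```

At mean cuts these have closed forms — the both-positive orthant is
$1/4 + \arcsin(\rho)/(2\pi)$ — which the test suite uses as an oracle,
together with brute-force quadrature for off-center cuts.

### Cutpoints and direction

A `cutpoints()` specification carries the latent cut, the summed-score cut
(raw, or both derived from a shared standardized offset `cut_sd`), and a
`direction`: whether the *positive* (flagged) decision is above or below
the cut. Screening for a deficit ("select respondents at or below
$-1\,SD$") is `direction = "below"`; the quadrant labels reflect
accordingly, so sensitivity always refers to the flagged side. The
classification rate and consistency are invariant to this choice; which
margin is called sensitivity versus specificity is not, which is why the
direction is explicit rather than a convention buried in formulas.

Summed scores are discrete in practice; the model treats $X^*$ as
continuous and no continuity correction is applied. This is a deliberate,
known approximation.

## Propagating parameter uncertainty

Point estimates $\hat\tau, \hat\lambda, \hat\psi$ carry sampling
variability that plugging-in ignores. The package propagates it two ways,
both reducing to the same pipeline `parameters -> implied moments ->
quadrants -> indices` applied per draw:

* **Percentile bootstrap** (`bootstrap_indices()`): resample respondents
  with replacement, refit by maximum likelihood, recompute the indices;
  percentile intervals are read from the resulting empirical distribution.
  Respondents are the only exchangeable unit in the design, hence the
  resampling unit. Non-converged refits are discarded and redrawn (up to
  ten times the requested resamples, with the discard count recorded and a
  hard failure if more than 10% of resamples fail) so the returned draw
  matrix always has exactly the requested size and the failure rate is
  auditable.
* **Bayesian posterior** (`gibbs_lfm()` + `posterior_indices()`): a
  conjugate data-augmented Gibbs sampler draws $(\eta, \tau, \lambda,
  \psi)$ from their exact full conditionals; every retained draw is mapped
  through the index pipeline, giving posterior distributions for the four
  indices.

Both produce an `index_draws` tibble summarized by `summarize_draws()`
into medians, 95% equal-tail limits, and 95% highest-density limits.

When the cut is given as a standardized offset, it is resolved **once** —
against the full-sample ML fit (bootstrap) or the posterior-median
parameters (Bayes) — and held fixed across draws, mirroring a fixed
decision rule. `refit_cut = TRUE` re-resolves per resample as a
sensitivity analysis. In the simulation harness, cuts are resolved against
the *generating* parameters and held fixed across replications, so every
replication is scored against the same truth.

### Priors

`prior_diffuse()` encodes the wide default set: $\tau_j \sim N(3,\,
\mathrm{sd}\,10)$, $\lambda_j \sim N(1,\, \mathrm{sd}\,10)$, $\psi_j \sim
\mathrm{IG}(5, 10)$. Two conventions deserve emphasis:

* Normal prior spreads are **standard deviations** throughout this
  package. Precision-parameterized samplers (the JAGS family) write the
  same symbols with a precision second argument; a spread of 10 is diffuse
  as an SD and extremely informative as a precision, so the package states
  its convention explicitly and `lfm_prior()` takes SDs only.
* The inverse-gamma prior on residual variances is *not* scale-free:
  IG(5, 10) has prior mean 2.5 and behaves like a prior sample of about 10
  observations with variance around 2. On data whose residual variances
  are near 0.5 (as for standardized indicators), it pulls residual
  variances up, biasing $\omega$ and $\rho$ — and hence every index —
  downward. This is the mechanism behind the poor coverage of
  diffuse-prior credible intervals in the simulation harness: the
  narrower the index posterior (classification rate most of all), the more
  this fixed bias costs in coverage. Sensitivity and specificity, with
  wider posteriors, degrade more gently.

`prior_empirical()` centers normals at the ML estimates with SD 1 and
gives each residual variance an inverse gamma carrying a pseudo sample
size of 20 (shape $n_0/2$, scale $(n_0/2)\hat\psi_j$) — weakly
informative, deliberately wider than the ML standard errors.

### Sampler details

Identification fixes $\kappa = 0$, $\Phi = 1$; the likelihood is invariant
to jointly reflecting $\lambda$ and $\eta$. Positive-centered priors break
the tie in practice; as a guard, any chain whose mean summed loading is
negative is reflected post hoc, and a chain that mixes signs across
retained draws triggers a warning (with truly zero loadings the sign is
unidentified and the warning is expected). Latent scores are sampled but
not stored unless `store_eta = TRUE`, bounding memory at long schedules.

Convergence is monitored by the classic Gelman–Rubin potential scale
reduction factor (`psrf()`), without rank normalization, with the usual
$< 1.1$ criterion. The default schedule (3 chains × 5,000 iterations,
burn-in 1,000, thinning 4 → 3,000 retained draws) matches standard
practice for this model class; the simulation harness defaults to a
lighter 2 × 2,000 schedule with burn-in 500 and thinning 4 (750 retained
draws), chosen so that per-draw index propagation — two bivariate-normal
CDF evaluations per retained draw — stays proportionate at hundreds of
replications per condition.

### Interval constructions

Equal-tail limits are empirical quantiles under the type-7
(linear-interpolation) rule, so limits are bit-reproducible across
implementations; the reported median is the 50th percentile under the same
rule. The HPD interval is the shortest window of
$\lceil \mathrm{level} \cdot S \rceil$ consecutive order statistics; ties
between equally short windows break deterministically toward the lowest
lower limit. This empirical construction is meaningful for unimodal
samples only — split HPD regions are out of scope — and is verified in the
tests against exhaustive window search.

## The simulation harness

`run_condition()` reproduces one cell of a coverage study: draw one true
parameter set, hold it and the cutpoints fixed, then per replication
simulate data, build the chosen method's draw matrix, summarize, and score
both interval types against the truth. Outcomes per index × interval type:
coverage, balance (the shares of replications whose truth fell below or
above the interval, reported as `balance_left` and `balance_right`, with
coverage + left + right = 1 exactly), relative bias
of the mean median estimate $(\bar{\hat m} - \theta)/\theta$ (signed:
negative means underestimation), and mean width. The acceptability bands
used by `results_table()` are coverage in $[0.925, 0.975]$ and — for
reading results — |relative bias| ≤ 0.05.

### What the generator emulates, and what it does not

`sim_params()` draws loadings i.i.d. from $\mathrm{Uniform}(f - 0.2,
f + 0.2)$ around a target mean loading $f \in (0.2, 0.8)$, sets intercepts
to zero and residual variances to $1 - \lambda_j^2$, so every indicator
has total variance exactly 1 under the standard-normal trait. (With
per-item loadings, "residual variance $1 - f^2$" and "unit indicator
variance" conflict; the package enforces the latter exactly, treating the
former as its constant-loading shorthand.) `sim_responses()` then
generates exactly the model: continuous, conditionally normal, complete
responses from a single factor.

Real scale data are none of these things: items are discrete (Likert),
often skewed, sometimes multidimensional or locally dependent, and
missingness is common. Passing coverage tests under this generator
therefore demonstrates that the interval machinery is *internally*
calibrated — correct model, correct scoring — not that the indices are
robust to model misspecification, which is a separate question the
package does not address.

One root seed governs a run; nested work units (replications, resamples,
chains) receive child seeds from a documented spawning rule
(`spawn_seeds()`: `sample.int(2^31 - 2, n)` under the root seed), so any
unit can be reproduced in isolation and execution order is irrelevant.

### Problem sizes

The test suite and the acceptance script run reduced designs chosen to
keep Monte-Carlo error quantifiable while remaining desk-scale: 200
replications × 200 bootstrap resamples for the bootstrap cell (coverage
standard error ≈ 0.015 at a true coverage of 0.95), and 100 replications
with the 2 × 2,000 Gibbs schedule for the Bayesian cells (standard error
≈ 0.022). `run_condition(full_scale = TRUE)` restores 1,000 replications,
500 resamples and 3 × 5,000 chains.

## Numerical choices

* Bivariate normal CDF: `mvtnorm::pmvnorm` with the deterministic TVPACK
  algorithm (absolute error far below the package's 1e-8 contract); the
  four quadrant masses derive from one CDF call plus two univariate CDFs,
  so they sum to one up to CDF error by construction. Correlations of
  magnitude 1 are rejected as degenerate with advice to perturb the model.
* ML estimation: the normal-theory discrepancy is minimized by
  box-constrained quasi-Newton (L-BFGS-B) with analytic gradients;
  residual variances are parameterized as $\psi_j = e^{s_j}$ with $s_j$
  floored at $\log(0.005\,S_{jj})$, so every solution is admissible — a
  Heywood-prone resample lands *on* the floor rather than diverging, which
  keeps $\rho$ defined in every bootstrap refit and makes convergence
  decidable at the boundary (the projected gradient must vanish: interior
  coordinates to within 1e-6, floored coordinates pushing outward). Start
  values come from the leading eigenpair of $S$, residual starts floored
  at $0.05\,\mathrm{diag}(S)$; at most 500 iterations. If the summed
  loading is negative, all loadings are flipped (positive keying
  convention).
* A singular sample covariance (collinear or constant items) is an error
  naming the problem, not a silent pseudo-inverse.

## Known limitations

* Continuous treatment of discrete summed scores (no continuity
  correction); indices for genuinely discrete-item models are out of
  scope.
* No missing-data handling; complete cases only.
* No PPV/NPV (prevalence-dependent respondent-level predictive values),
  no ROC-style cutpoint sweeps, no fit indices for the factor model, no
  multi-factor structures.
* HPD intervals assume unimodal draw distributions.
* Diffuse-prior credible intervals inherit the scale sensitivity of the
  IG(5, 10) prior discussed above; on standardized data they should be
  expected to undercover, and the package reproduces exactly that
  behaviour in its simulation harness. The bootstrap is the recommended
  default for interval estimation.
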