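---
title: "A shared component model for gender-stratified spatial prevalence data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shared component model for gender-stratified spatial prevalence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Survey estimates of a common condition — hypertension among middle-aged and
elderly residents is the motivating case — are routinely reported per
administrative region and per gender. At the regional level the standardized
prevalence ratio SPR = O/E (observed over internally standardized expected
counts) is the maximum-likelihood relative-risk estimate, but with a few dozen
subjects per cell it is dominated by sampling noise: a single region with a
small expected count can produce an extreme, spurious map value. Joint
spatial smoothing addresses this by letting regions borrow strength from
their neighbors and by letting the two genders borrow strength from each
other where their risk surfaces genuinely co-vary.

## The model

For gender $j \in \{1 = \text{male}, 2 = \text{female}\}$ and region
$i = 1, \dots, R$,

$$O_{ji} \sim \mathrm{Bin}(n_{ji}, p_{ji}), \qquad
\mathrm{logit}(p_{ji}) = \alpha_j + \sum_k b_{jk}\, x_{jik} + \eta_{ji},$$

with a binomial rather than Poisson likelihood because the outcome is
non-rare. The spatial term is decomposed as

$$\eta_{1i} = \varphi_i\,\delta + \upsilon_{1i}, \qquad
\eta_{2i} = \varphi_i/\delta + \gamma_i + \upsilon_{2i},$$

where $\varphi$ is the shared component loaded with weight $\delta$ for
males and $1/\delta$ for females (their ratio is $\delta^2$, the relative
loading of the two genders), $\gamma$ is a spatially structured
gender-contrast surface, and $\upsilon_j$ are gender-specific residuals.
Both $\varphi$ and $\upsilon_j$ carry convolution (BYM) priors:
$\varphi = \mathrm{ush} + \mathrm{ssh}$ and
$\upsilon_j = \mathrm{bind}_j + \mathrm{bspat}_j$, i.i.d. normal plus
intrinsic CAR. The intrinsic CAR log-density for a component $v$ with
precision $\tau$ on a graph with $R$ regions, $C$ connected components and
edge set $E$ is

$$\tfrac{R - C}{2}\bigl(\log\tau - \log 2\pi\bigr)
  - \tfrac{\tau}{2} \sum_{(i,l) \in E} (v_i - v_l)^2 .$$

The shared-variance fractions summarize how much of each gender's spatial
variance the shared component explains:

$$\eta_1 = \frac{\mathrm{var}(\varphi\delta)}
  {\mathrm{var}(\varphi\delta) + \mathrm{var}(\upsilon_1)}, \qquad
\eta_2 = \frac{\mathrm{var}(\varphi/\delta)}
  {\mathrm{var}(\varphi/\delta) + \mathrm{var}(\gamma)
    + \mathrm{var}(\upsilon_2)}.$$

Variances here are empirical variances across regions within one parameter
state. We use the population convention (divide by $R$), matching the
`sd()`/`pow()` idiom of the classical disease-mapping toolchains;
`scm_control(variance_convention = "sample")` switches to the $R-1$
denominator. Both $\eta_j$ lie in $[0,1]$ for every draw by construction.

## Identifiability choices

Several choices here were genuinely open and are worth recording.

* **Sum-to-zero on all region-indexed components.** The intrinsic CAR is
  improper (invariant to constant shifts), so the structured components need
  a sum-to-zero constraint; we extend the same constraint to the
  unstructured components so that they cannot trade a constant against the
  intercepts. With the constraint in place, $\alpha_j$ is the sole
  gender-level intercept; a separate mean parameter for the unstructured
  specific component would be redundant under flat priors and is fixed at
  zero.
* **One name per object.** The model's covariate coefficients and its
  spatial gender-contrast surface are distinct objects that would both
  naturally be called "beta"; in code they are `b` and `gamma_contrast`.
* **Weights multiply to one.** The log-weights of the two genders sum to
  zero by construction ($\delta$ and $1/\delta$), which is what identifies
  the scale of $\varphi$.

## Priors

All seven precisions share one Gamma(shape, rate) prior in the WinBUGS
`dgamma` parameterization; the default is the weakly informative
Gamma(1, 1e-4) ("priors 1"), with Gamma(1000, 5e-7) and Gamma(5, 5e-5)
("priors 2", "priors 3") wired into `run_sensitivity()` as the conventional
alternatives. The prior for $\log\delta$ is N(0, 0.169) read as a
**variance**: only that reading gives the calibration that $\delta^2$ lies
in $[1/5, 5]$ with 95 % prior probability, which
`delta_sq_prior_coverage()` evaluates in closed form
($2\Phi(\log 5 / 2\sqrt{0.169}) - 1 = 0.9497$). Intercepts and covariate
coefficients carry improper flat priors.

## Covariate scaling

Regional covariates are stored as proportions in $[0,1]$ (share elderly,
share obese, share with waist-to-height ratio above 0.5) and are multiplied
by `scm_control()$covariate_scale` before entering the linear predictor. The
default scale of 100 expresses coefficients per **percentage point**, the
scale on which regional covariate relative risks of roughly 0.93–1.04 with
tight intervals are plausible; per-unit-proportion coefficients would be two
orders of magnitude larger. The scale is a configuration option because the
original analyses' units are not recoverable from their reports.

## The sampler

`run_mcmc()` is a seeded Metropolis-within-Gibbs sampler with the sweep
implemented in C++:

* intercepts, coefficients and $\log\delta$ move by adaptive random-walk
  Metropolis (adaptation toward 44 % acceptance, during burn-in only);
* each region-indexed component moves site by site with **sum-preserving
  redistribution proposals** — site $i$ gains $\varepsilon$, every other
  site loses $\varepsilon/(R-1)$. These proposals are symmetric and never
  leave the sum-to-zero subspace, so they target the constrained posterior
  exactly; the constraint therefore holds on every retained draw rather
  than being imposed by post-hoc re-centering (which would perturb the
  likelihood);
* the seven precisions are conjugate Gibbs draws, with degrees of freedom
  $(R-C)/2$ for CAR components and $R/2$ for the i.i.d. components,
  matching the log-prior term for term;
* missing regional covariates are treated as parameters with
  moment-matched normal priors (see below) and updated by random-walk
  Metropolis against their single cell's likelihood.

Internally the sampler centers each gender's covariate columns and lets the
intercept absorb the means — a pure reparameterization (the intercept prior
is flat) undone before draws are returned — because the raw intercept and
coefficients are otherwise so correlated that random-walk sweeps mix an
order of magnitude more slowly.

Chains start from overdispersed states: chain $c$ scales its start draws by
$1 + 2c$. Two chains of 50,000 burn-in plus 50,000 retained sweeps thinned
by 10 (10,000 retained draws) are the defaults, mirroring the usual
protocol for these models; at this problem size (22 cells, 11 regions) a
full default run takes a few seconds. Convergence is monitored with a
split-chain potential scale reduction factor (`bgr_diagnostic()`; each chain
is halved, which is stricter than the unsplit plot statistic and reportable
as a scalar) and sample autocorrelations (`autocorrelation()`). Model
comparison uses DIC with the plug-in at the posterior mean of each cell
probability (`dic()`); plug-in DIC can go negative in pathological fits, so
`pD < 0` warns rather than errors.

## Missing data rules

Two rules mirror the motivating analysis. A region flagged `substituted`
(the island prefecture, whose cell counts were unusable) has both genders'
observed counts and denominators replaced by the across-region average of
the remaining regions, rounded to the nearest integer so the binomial
likelihood stays well defined. A missing covariate entry receives a normal
prior whose mean and variance are the sample moments of that covariate's
observed entries (pooled over genders and regions) and is then sampled
within the MCMC rather than fixed, so its uncertainty propagates into the
posterior.

## The synthetic generator

`generate_regional()` draws covariates uniformly on ranges echoing the
motivating cohort (elderly share 0.30–0.70, obese 0.03–0.15, apple-shape
0.50–0.90), structured components from the intrinsic CAR via the graph
Laplacian's pseudo-inverse restricted to the sum-to-zero subspace (the
unique proper zero-mean Gaussian consistent with the improper fitting
density), unstructured components i.i.d. normal then centered, and case
counts binomially. The default truth uses covariate effects, $\delta$ and
component SDs at the magnitudes the motivating study reports, and cell
sizes of 55 males and 60 females per region (about 1265 subjects over 22
cells — survey scale). `generate_individual()` expands a regional dataset
into per-subject records whose covariates match the cell proportions in
expectation and whose case labels reproduce the cell counts exactly (cases
are assigned by sampling which subjects are cases, keeping the two files
consistent on round trip); per-subject draws are independent given the cell
proportions, so within-subject covariate correlation — present in real
data — is deliberately not emulated. Passing tests on these data therefore
demonstrate correctness of the machinery under the model's own assumptions,
not robustness to survey-design features (weights, clustering, nonresponse)
that the generator does not produce.

`recovery_experiment()` fits replicated synthetic datasets and reports
credible-interval coverage and bias for the fixed effects and $\delta$.
Recovery runs use 500 subjects per cell rather than survey scale: at a few
dozen subjects per cell the regional parameters are genuinely imprecise
(the motivating study itself recommends finer-scale analysis), and a
coverage experiment at that scale mostly measures prior influence. Twenty
replicates at 2 chains x (3000 + 3000, thin 3) complete in well under a
minute.

## Numerical choices

* Cell probabilities are clipped to the open unit interval at machine
  precision so extreme linear predictors produce large negative but finite
  log-likelihoods.
* Percentages reproduce printed tables with half-up rounding
  (`round_half_up()`); base R's round-half-even cannot reproduce
  conventionally rounded published tables.
* A region with no incident edges is permitted (warned about) and simply
  contributes nothing to CAR quadratic forms; a disconnected graph reduces
  the CAR degrees of freedom through the $R - C$ term and is handled per
  component in the generator.
* Ties at category boundaries follow the published conventions: BMI 28.0 is
  obese, waist-to-height ratio exactly 0.5 is "pear".
* The forward-stepwise entry criterion is a likelihood-ratio p-value below
  0.05 per step (the usual default where the original procedure's criterion
  is unstated), and univariate screening tests each variable jointly across
  its dummy levels at the conventional 0.06 threshold.

## Known limitations

* Exactly two groups are supported — the two-gender form of the model; the
  multi-disease generalization is out of scope.
* The descriptive arm reports both the sum-of-strata totals and per-cell
  counts; published survey tables whose strata do not cover the full cohort
  (missing covariate values reduce denominators) cannot be reconciled to
  headline figures computed on the full cohort, and no attempt is made to
  do so.
* Logistic models are unweighted; survey design weights are not supported.
* The smoothed relative-risk export is defined as posterior-mean fitted
  counts over internally standardized expected counts, which reduces to the
  SPR when the model saturates; other RR definitions (e.g. against an
  external reference) are not provided.
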