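# spscm

Shared component models for gender-stratified spatial prevalence analysis.

## What problem this solves

Regional prevalence estimates of a common condition — the motivating case is
self-reported hypertension among middle-aged and elderly residents of the 11
prefectures of Zhejiang Province, stratified by gender — are noisy at survey
scale: the standardized prevalence ratio SPR = O/E is the maximum-likelihood
regional relative-risk estimate but is unstable when a region has only a few
dozen subjects per cell. `spscm` implements a joint Bayesian disease-mapping
model that smooths both across neighboring regions and across the two
genders, and quantifies how much of the spatial risk surface the genders
share.

For gender *j* and region *i*:

```
O[j,i] ~ Binomial(n[j,i], p[j,i])
logit(p[j,i]) = alpha_j + sum_k b[j,k] * x[j,i,k] + eta[j,i]
eta[1,i] = phi[i] * delta          + upsilon[1,i]
eta[2,i] = phi[i] / delta + gamma[i] + upsilon[2,i]
```

`phi` is the shared spatial component (loaded with weight `delta` for males
and `1/delta` for females; `delta^2` is the ratio of loadings), `gamma` a
spatially structured gender contrast, `upsilon_j` gender-specific residuals.
`phi` and `upsilon_j` carry convolution (BYM) priors — i.i.d. normal plus
intrinsic CAR on the region adjacency graph — with sum-to-zero constraints;
regional covariates (share elderly, obese, apple-shaped) enter as
gender-specific fixed effects. The shared-variance fractions
`eta_1 = var(phi*delta) / (var(phi*delta) + var(upsilon_1))` (and the
analogue for females, which adds `var(gamma)`) summarize the shared
structure. Inference is seeded Metropolis-within-Gibbs MCMC with conjugate
precision updates; model comparison uses DIC. The package also carries the
two conventional comparison arms (stratified prevalence tables; univariate
screening plus forward-stepwise logistic regression with OR/CI tables and
VIF checks), and a synthetic-data generator with a parameter-recovery
harness standing in for the non-public survey microdata.

## Worked example

```r
library(spscm)

map <- zhejiang_map()                      # bundled 11-prefecture adjacency
gen <- generate_regional(map, seed = 2026) # survey-scale synthetic data
fit <- run_mcmc(gen$data,
                control = mcmc_control(burn_in = 8000, iterations = 8000,
                                       thin = 8, seed = 1))

s <- summary(fit)
s[match(c("eta_male", "eta_female", "delta", "sigma_str", "sigma_unstr"),
        s$parameter), ]
#>    parameter   mean     sd    q2.5     q50  q97.5 rhat
#>     eta_male 0.5269 0.2883 0.04061 0.53271 0.9742 1.00
#>   eta_female 0.4136 0.2872 0.01227 0.37140 0.9549 1.01
#>        delta 1.0897 0.4666 0.45941 0.99505 2.1808 1.00
#>    sigma_str 0.0131 0.0159 0.00270 0.00832 0.0643 1.03
#>  sigma_unstr 0.0102 0.0070 0.00351 0.00824 0.0297 1.00

covariate_rr(fit, "whtr", "male")   # RR per percentage point apple-shaped
#>  mean lower upper
#>  1.05  1.03  1.07

ic <- dic(fit)
sprintf("DIC = %.3f (pD = %.3f)", ic$DIC, ic$pD)
#> "DIC = 125.128 (pD = 8.348)"
```

About half of each gender's spatial variance is attributed to the shared
component (`eta` near 0.5), the shared weight `delta` is near 1 with a wide
interval (ratio parameters are imprecise at 11 regions), the component SDs
are of order 0.01 on the log-odds scale, and a higher regional share of
abdominal adiposity raises male hypertension risk by about 5 % per
percentage point in this synthetic draw. Raw SPRs for the same data
(`spr(expected_counts(gen$data))`) scatter widely — e.g. 0.28 to 1.74 across
the first four prefectures for males — which is exactly the instability the
model smooths away.

File-based pipeline stages wrap the same machinery: `run_simulate()`,
`run_describe()`, `run_logistic()`, `run_scm()`, `run_sensitivity()` read
and write plain delimited text with a manifest per stage.

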