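# Extended shared component model: data containers, parameter state,
# log-likelihood / log-prior / log-posterior, derived quantities, and the
# missing-data rules (region substitution, moment-matched normal imputation).

#' Model configuration
#'
#' @param covariate_scale multiplier applied to the regional covariate
#'   proportions before they enter the linear predictor. The default 100
#'   expresses covariates in percentage points, so fixed effects are log-RRs
#'   per percentage point (the scale on which regional covariate RRs of
#'   roughly 0.93-1.04 are plausible).
#' @param variance_convention `"population"` (divide by N; the WinBUGS
#'   `sd()`/`pow()` idiom) or `"sample"` (divide by N-1) for the empirical
#'   variances in the shared-variance fractions and component SDs.
#' @return list of class `scm_control`.
#' @export
scm_control <- function(covariate_scale = 100,
                        variance_convention = c("population", "sample")) {
  stopifnot(is.numeric(covariate_scale), covariate_scale > 0)
  structure(list(covariate_scale = covariate_scale,
                 variance_convention = match.arg(variance_convention)),
            class = "scm_control")
}

# empirical variance across regions under the configured convention
empirical_var <- function(x, convention = "population") {
  n <- length(x)
  if (n < 2L) return(0)
  v <- sum((x - mean(x))^2)
  if (convention == "population") v / n else v / (n - 1)
}

#' Hyperprior specification
#'
#' All seven precision parameters share one Gamma(shape, rate) prior
#' (WinBUGS `dgamma` parameterization). The default shape 1, rate 1e-4 is the
#' weakly informative baseline ("priors 1"); the log of the shared-component
#' weight delta has a N(0, variance 0.169) prior, the variance reading under
#' which delta^2 lies in \[1/5, 5\] with 95 percent prior probability.
#'
#' @param precision_shape,precision_rate Gamma shape and rate for every
#'   precision parameter.
#' @param log_delta_variance prior variance of log(delta).
#' @return list of class `scm_priors`.
#' @export
scm_priors <- function(precision_shape = 1, precision_rate = 1e-4,
                       log_delta_variance = 0.169) {
  stopifnot(precision_shape > 0, precision_rate > 0, log_delta_variance > 0)
  structure(list(precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 log_delta_variance = log_delta_variance),
            class = "scm_priors")
}

#' Prior probability that delta-squared lies in \[1/5, 5\]
#'
#' The calibration check behind the log-delta prior: under
#' `log(delta) ~ N(0, v)`, `delta^2` falls in \[1/5, 5\] with probability
#' `2 * pnorm(log(5) / (2 * sqrt(v))) - 1`. At the default v = 0.169 this is
#' 95 percent to the nearest percent.
#'
#' @param priors an [scm_priors] object.
#' @return probability in percent (not rounded).
#' @export
delta_sq_prior_coverage <- function(priors = scm_priors()) {
  v <- priors$log_delta_variance
  100 * (2 * pnorm(log(5) / (2 * sqrt(v))) - 1)
}

#' Regional shared-component-model data
#'
#' Per-region, per-gender case counts, denominators and regional covariates.
#' Covariates are stored as proportions in \[0, 1\]; `NA` entries are missing
#' covariates to be given moment-matched normal priors by [impute_missing()]
#' and sampled within the MCMC. Regions listed in `substituted` have their
#' counts replaced by across-region averages at imputation time (the rule the
#' study applied to Zhoushan).
#'
#' @param map a [region_map].
#' @param O,n 2 x R matrices (rows male, female) of case counts and
#'   denominators; `0 <= O <= n`. `n = 0` cells contribute nothing to the
#'   likelihood (used by prior-only runs).
#' @param x `NULL` (no covariates) or a 2 x R x K array of proportions with
#'   covariate names in the third dimnames slot; alternatively a list of two
#'   R x K matrices (male, female).
#' @param covariates optional covariate names when `x` carries none.
#' @param substituted region labels whose counts are replaced at imputation.
#' @return object of class `scm_data`.
#' @export
scm_data <- function(map, O, n, x = NULL, covariates = NULL,
                     substituted = character(0)) {
  stopifnot(inherits(map, "region_map"))
  R <- length(map$regions)
  O <- matrix(as.numeric(O), nrow = 2, ncol = R,
              dimnames = list(GENDERS, map$regions))
  n <- matrix(as.numeric(n), nrow = 2, ncol = R,
              dimnames = list(GENDERS, map$regions))
  if (any(n < 0) || any(O < 0)) stop("counts must be nonnegative")
  if (any(O > n)) {
    bad <- which(O > n, arr.ind = TRUE)[1, ]
    stop("cases exceed denominator for gender '", GENDERS[bad[1]],
         "', region '", map$regions[bad[2]], "'")
  }
  if (is.list(x) && !is.array(x)) {
    K <- ncol(x[[1]])
    covariates <- covariates %||% colnames(x[[1]])
    xa <- array(NA_real_, dim = c(2, R, K))
    xa[1, , ] <- as.matrix(x[[1]])
    xa[2, , ] <- as.matrix(x[[2]])
    x <- xa
  }
  if (is.null(x)) {
    x <- array(numeric(0), dim = c(2, R, 0))
    covariates <- character(0)
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[1] == 2L,
              dim(x)[2] == R)
    covariates <- covariates %||% dimnames(x)[[3]] %||%
      paste0("x", seq_len(dim(x)[3]))
  }
  dimnames(x) <- list(GENDERS, map$regions, covariates)
  ok <- !is.na(x)
  if (any(x[ok] < 0 | x[ok] > 1))
    stop("covariates must be proportions in [0, 1] before scaling")
  unknown <- setdiff(substituted, map$regions)
  if (length(unknown))
    stop("unknown substituted region(s): ", paste(unknown, collapse = ", "))
  structure(list(map = map, O = O, n = n, x = x, covariates = covariates,
                 substituted = substituted, imputation = NULL),
            class = "scm_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scm_data <- function(x, ...) {
  cat("scm_data:", length(x$map$regions), "regions x 2 genders,",
      length(x$covariates), "covariate(s)",
      if (length(x$covariates)) paste0("(", paste(x$covariates, collapse = ", "), ")"),
      "\n  total cases", sum(x$O), "of", sum(x$n), "\n")
  if (anyNA(x$x)) cat("  ", sum(is.na(x$x)), "missing covariate value(s)\n")
  if (length(x$substituted))
    cat("  substituted region(s):", paste(x$substituted, collapse = ", "), "\n")
  invisible(x)
}

# ordered names of the seven precision parameters
TAU_NAMES <- c("tau_ssh", "tau_bspat_male", "tau_bspat_female", "tau_gamma",
               "tau_ush", "tau_bind_male", "tau_bind_female")

#' One full parameter state of the extended SCM
#'
#' Fixed effects: per-gender intercepts `alpha` and covariate coefficients
#' `b` (log-odds per scaled covariate unit). Shared component
#' `phi = ush + ssh` (unstructured + structured), loaded with `delta` for
#' males and `1/delta` for females; gender-specific residuals
#' `upsilon_j = bind_j + bspat_j`; `gamma_contrast` is the spatially
#' structured gender-contrast term entering the female predictor. All
#' region-indexed components are centered to sum to zero (identifiability);
#' `center = TRUE` enforces this at construction.
#'
#' @param map a [region_map].
#' @param covariates covariate names (fixes the columns of `b`).
#' @param alpha length-2 intercepts (male, female).
#' @param b 2 x K coefficient matrix.
#' @param log_delta log of the shared-component weight.
#' @param ush,ssh length-R shared unstructured / structured components.
#' @param bind,bspat 2 x R gender-specific unstructured / structured
#'   components.
#' @param gamma_contrast length-R spatial gender contrast.
#' @param tau named length-7 vector of positive precisions (order
#'   `tau_ssh`, `tau_bspat_male`, `tau_bspat_female`, `tau_gamma`,
#'   `tau_ush`, `tau_bind_male`, `tau_bind_female`).
#' @param center center all region-indexed components to sum to zero.
#' @return object of class `scm_params`.
#' @export
scm_params <- function(map, covariates = character(0),
                       alpha = c(0, 0),
                       b = matrix(0, 2, length(covariates)),
                       log_delta = 0,
                       ush = numeric(length(map$regions)),
                       ssh = numeric(length(map$regions)),
                       bind = matrix(0, 2, length(map$regions)),
                       bspat = matrix(0, 2, length(map$regions)),
                       gamma_contrast = numeric(length(map$regions)),
                       tau = setNames(rep(1, 7), TAU_NAMES),
                       center = TRUE) {
  R <- length(map$regions)
  K <- length(covariates)
  b <- matrix(as.numeric(b), 2, K, dimnames = list(GENDERS, covariates))
  bind <- matrix(as.numeric(bind), 2, R, dimnames = list(GENDERS, map$regions))
  bspat <- matrix(as.numeric(bspat), 2, R, dimnames = list(GENDERS, map$regions))
  tau <- setNames(as.numeric(tau), TAU_NAMES)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all precisions must be positive and finite")
  ctr <- function(v) if (center && length(v) > 1L) v - mean(v) else v
  ctr_m <- function(m) if (center && R > 1L) m - rowMeans(m) else m
  p <- list(alpha = setNames(as.numeric(alpha), GENDERS), b = b,
            log_delta = as.numeric(log_delta),
            ush = ctr(setNames(as.numeric(ush), map$regions)),
            ssh = ctr(setNames(as.numeric(ssh), map$regions)),
            bind = ctr_m(bind),
            bspat = ctr_m(bspat),
            gamma_contrast = ctr(setNames(as.numeric(gamma_contrast),
                                          map$regions)),
            tau = tau, covariates = covariates)
  dimnames(p$bind) <- dimnames(p$bspat) <- list(GENDERS, map$regions)
  structure(p, class = "scm_params")
}

#' Cell probabilities from a parameter state
#'
#' Evaluates the model's linear predictor and inverse-logit:
#' `logit(p[j,i]) = alpha_j + sum_k b[j,k] x[j,i,k] * scale + eta[j,i]` with
#' `eta[1,i] = phi[i] * delta + upsilon[1,i]` and
#' `eta[2,i] = phi[i] / delta + gamma_contrast[i] + upsilon[2,i]`, where
#' `phi = ush + ssh` and `upsilon_j = bind_j + bspat_j`.
#'
#' @param params an [scm_params] state.
#' @param data an [scm_data] object with no remaining missing covariates.
#' @param control an [scm_control] (covariate scale).
#' @return 2 x R matrix of probabilities strictly inside (0, 1).
#' @export
linear_predictor <- function(params, data, control = scm_control()) {
  stopifnot(inherits(params, "scm_params"), inherits(data, "scm_data"))
  if (anyNA(data$x))
    stop("missing covariates present; run impute_missing() first")
  eta <- scm_eta(params)
  lp <- eta
  delta_ok <- is.finite(params$log_delta)
  if (!delta_ok || any(!is.finite(unlist(params[c("alpha", "b")]))))
    stop("non-finite parameter in state")
  K <- length(params$covariates)
  R <- length(data$map$regions)
  for (j in 1:2) {
    fe <- if (K) {
      as.numeric(matrix(data$x[j, , ], R, K) %*% params$b[j, ]) *
        control$covariate_scale
    } else 0
    lp[j, ] <- params$alpha[j] + fe + eta[j, ]
  }
  p <- plogis(lp)
  # keep strictly inside (0,1) so the binomial log-pmf stays finite
  eps <- .Machine$double.xmin
  pmin(pmax(p, eps), 1 - .Machine$double.eps)
}

# eta[j, i]: shared component with gender weights + specific terms
scm_eta <- function(params) {
  phi <- params$ush + params$ssh
  d <- exp(params$log_delta)
  rbind(male = phi * d + params$bind[1, ] + params$bspat[1, ],
        female = phi / d + params$gamma_contrast +
          params$bind[2, ] + params$bspat[2, ])
}

#' Binomial log-likelihood of an SCM state
#'
#' `sum over genders and regions of log Binomial(O[j,i] | n[j,i], p[j,i])`,
#' including the binomial coefficients (so deviances are on the same scale as
#' standard MCMC software reports). Cells with `n = 0` contribute zero.
#'
#' @inheritParams linear_predictor
#' @return a finite scalar.
#' @export
scm_log_likelihood <- function(params, data, control = scm_control()) {
  p <- linear_predictor(params, data, control)
  sum(dbinom(data$O, data$n, p, log = TRUE))
}

#' Log-prior of an SCM state
#'
#' Sum of: intrinsic CAR terms `(R - C)/2 * (log tau - log 2*pi) -
#' tau/2 * Q(v)` for `ssh`, each gender's `bspat`, and `gamma_contrast`
#' (R regions, C connected components, Q the pairwise-difference quadratic
#' form); independent zero-mean normal terms for `ush` and each gender's
#' `bind`; Gamma log-densities for the seven precisions; a normal
#' log-density for `log_delta`; and an improper flat contribution (zero) for
#' the intercepts and covariate coefficients.
#'
#' @param params an [scm_params] state.
#' @param priors an [scm_priors] object.
#' @param map a [region_map].
#' @return scalar log-prior density (improper overall; finite for valid
#'   states).
#' @export
scm_log_prior <- function(params, priors, map) {
  stopifnot(inherits(params, "scm_params"), inherits(priors, "scm_priors"),
            inherits(map, "region_map"))
  if (any(params$tau <= 0) || any(!is.finite(params$tau)))
    stop("nonpositive precision in state")
  R <- length(map$regions)
  C <- map$n_components
  car_term <- function(v, tau) {
    0.5 * (R - C) * (log(tau) - log(2 * pi)) -
      0.5 * tau * car_quadratic_form(v, map)
  }
  iid_term <- function(v, tau) sum(dnorm(v, 0, 1 / sqrt(tau), log = TRUE))
  lp <- car_term(params$ssh, params$tau["tau_ssh"]) +
    car_term(params$bspat[1, ], params$tau["tau_bspat_male"]) +
    car_term(params$bspat[2, ], params$tau["tau_bspat_female"]) +
    car_term(params$gamma_contrast, params$tau["tau_gamma"]) +
    iid_term(params$ush, params$tau["tau_ush"]) +
    iid_term(params$bind[1, ], params$tau["tau_bind_male"]) +
    iid_term(params$bind[2, ], params$tau["tau_bind_female"]) +
    sum(dgamma(params$tau, shape = priors$precision_shape,
               rate = priors$precision_rate, log = TRUE)) +
    dnorm(params$log_delta, 0, sqrt(priors$log_delta_variance), log = TRUE)
  unname(lp)
}

#' Log-posterior of an SCM state
#'
#' `scm_log_likelihood(params, data) + scm_log_prior(params, priors, map)` —
#' the target density of the sampler, exposed for oracle checks and start
#' validation.
#'
#' @inheritParams scm_log_likelihood
#' @param priors an [scm_priors] object.
#' @return scalar.
#' @export
scm_log_posterior <- function(params, data, priors, control = scm_control()) {
  scm_log_likelihood(params, data, control) +
    scm_log_prior(params, priors, data$map)
}

#' Shared variance fractions
#'
#' The proportion of each gender's spatial log-odds variance attributable to
#' the shared component, computed across regions within a single state:
#' `eta_1 = var(phi * delta) / (var(phi * delta) + var(upsilon_1))` and
#' `eta_2 = var(phi / delta) / (var(phi / delta) + var(gamma_contrast) +
#' var(upsilon_2))`. A state whose numerator and denominator both vanish
#' yields 0 with a `degenerate` attribute flag.
#'
#' @param params an [scm_params] state (needs >= 2 regions).
#' @param control an [scm_control] (variance convention).
#' @return named length-2 vector `c(eta_male, eta_female)`, each in \[0, 1\].
#' @export
variance_fractions <- function(params, control = scm_control()) {
  conv <- control$variance_convention
  phi <- params$ush + params$ssh
  d <- exp(params$log_delta)
  ups <- rbind(params$bind[1, ] + params$bspat[1, ],
               params$bind[2, ] + params$bspat[2, ])
  num1 <- empirical_var(phi * d, conv)
  den1 <- num1 + empirical_var(ups[1, ], conv)
  num2 <- empirical_var(phi / d, conv)
  den2 <- num2 + empirical_var(params$gamma_contrast, conv) +
    empirical_var(ups[2, ], conv)
  eta <- c(male = if (den1 > 0) num1 / den1 else 0,
           female = if (den2 > 0) num2 / den2 else 0)
  if (den1 == 0 || den2 == 0) attr(eta, "degenerate") <- TRUE
  eta
}

#' Component standard deviations of a state
#'
#' Empirical standard deviations across regions, under the configured
#' variance convention, of the structured shared (`sigma_str`), unstructured
#' shared (`sigma_unstr`), and per-gender unstructured (`sigma_ind`) and
#' structured (`sigma_spat`) specific components.
#'
#' @inheritParams variance_fractions
#' @return named numeric vector `sigma_str`, `sigma_unstr`,
#'   `sigma_ind_male`, `sigma_ind_female`, `sigma_spat_male`,
#'   `sigma_spat_female`.
#' @export
component_sds <- function(params, control = scm_control()) {
  conv <- control$variance_convention
  s <- function(v) sqrt(empirical_var(v, conv))
  c(sigma_str = s(params$ssh), sigma_unstr = s(params$ush),
    sigma_ind_male = s(params$bind[1, ]),
    sigma_ind_female = s(params$bind[2, ]),
    sigma_spat_male = s(params$bspat[1, ]),
    sigma_spat_female = s(params$bspat[2, ]))
}

#' Substitute flagged regions and attach imputation priors
#'
#' Applies the study's two missing-data rules. (1) For each region in
#' `data$substituted`, both genders' observed counts and denominators are
#' replaced by the across-region average of the remaining regions, rounded to
#' the nearest integer so the binomial likelihood stays well defined. (2)
#' Each missing covariate entry receives a normal imputation prior whose mean
#' and variance are the sample moments of the observed values of that
#' covariate (pooled over genders and regions); the entry is filled with the
#' prior mean for deterministic evaluation and is sampled from its full
#' posterior within the MCMC.
#'
#' @param data an [scm_data] object.
#' @return the data with counts substituted, covariates filled, and an
#'   `imputation` data frame (`gender`, `region`, `covariate`, `mean`,
#'   `var`) attached; identity when nothing is flagged.
#' @export
impute_missing <- function(data) {
  stopifnot(inherits(data, "scm_data"))
  regions <- data$map$regions
  if (length(data$substituted)) {
    keep <- !(regions %in% data$substituted)
    if (!any(keep)) stop("cannot substitute every region")
    for (j in 1:2) {
      O_bar <- round_half_up(mean(data$O[j, keep]), 0)
      n_bar <- round_half_up(mean(data$n[j, keep]), 0)
      data$O[j, !keep] <- min(O_bar, n_bar)
      data$n[j, !keep] <- n_bar
    }
  }
  if (anyNA(data$x)) {
    idx <- which(is.na(data$x), arr.ind = TRUE)
    imp <- data.frame(gender = GENDERS[idx[, 1]],
                      region = regions[idx[, 2]],
                      covariate = data$covariates[idx[, 3]],
                      mean = NA_real_, var = NA_real_,
                      stringsAsFactors = FALSE)
    x_obs <- data$x  # moments come from the originally observed entries only
    for (r in seq_len(nrow(idx))) {
      k <- idx[r, 3]
      obs <- x_obs[, , k][!is.na(x_obs[, , k])]
      if (!length(obs))
        stop("covariate '", data$covariates[k], "' is missing in all regions")
      imp$mean[r] <- mean(obs)
      imp$var[r] <- if (length(obs) > 1L) var(obs) else 0
      data$x[idx[r, 1], idx[r, 2], k] <- imp$mean[r]
    }
    data$imputation <- imp
  }
  data
}

#' Posterior relative risk of a regional covariate
#'
#' Per-draw exponentiation of the covariate coefficient times `delta_x`
#' scaled-covariate units (1 = one percentage point at the default scale),
#' then posterior mean and central 95 percent quantiles — quantiles of the
#' per-draw RR, not a transform of the posterior mean coefficient.
#'
#' @param samples an `scm_samples` object from [run_mcmc()].
#' @param covariate covariate name.
#' @param gender `"male"` or `"female"`.
#' @param delta_x covariate increment in scaled units.
#' @return named vector `mean`, `lower`, `upper`.
#' @export
covariate_rr <- function(samples, covariate, gender, delta_x = 1) {
  stopifnot(inherits(samples, "scm_samples"))
  col <- paste0("b_", gender, "_", covariate)
  draws <- pooled_draws(samples)
  if (!col %in% colnames(draws))
    stop("no sampled coefficient for covariate '", covariate,
         "', gender '", gender, "'")
  if (!nrow(draws)) stop("empty posterior sample")
  rr <- exp(draws[, col] * delta_x)
  c(mean = mean(rr), lower = unname(quantile(rr, 0.025)),
    upper = unname(quantile(rr, 0.975)))
}
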