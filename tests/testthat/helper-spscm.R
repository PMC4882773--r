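# shared fixtures and small oracles used across test files

path_map3 <- function() {
  region_map(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
}

# random valid SCM data + parameter state on a given map
random_state <- function(map, K = 2, seed = 1) {
  set.seed(seed)
  R <- length(map$regions)
  covs <- if (K) paste0("v", 1:K) else character(0)
  x <- array(runif(2 * R * K, 0.1, 0.9), dim = c(2, R, K))
  n <- matrix(sample(20:80, 2 * R, replace = TRUE), 2, R)
  O <- matrix(rbinom(2 * R, as.integer(n), 0.3), 2, R)
  data <- scm_data(map, O, n, x, covariates = covs)
  params <- scm_params(
    map, covs, alpha = rnorm(2, 0, 0.5),
    b = matrix(rnorm(2 * K, 0, 0.05), 2, K),
    log_delta = rnorm(1, 0, 0.3),
    ush = rnorm(R, 0, 0.3), ssh = rnorm(R, 0, 0.3),
    bind = matrix(rnorm(2 * R, 0, 0.3), 2, R),
    bspat = matrix(rnorm(2 * R, 0, 0.3), 2, R),
    gamma_contrast = rnorm(R, 0, 0.3),
    tau = setNames(runif(7, 0.5, 5), spscm:::TAU_NAMES))
  list(data = data, params = params)
}

# brute-force scalar log-posterior: written independently of the package's
# vectorized implementation, term by term from the model definition
oracle_log_posterior <- function(params, data, priors,
                                 control = scm_control()) {
  map <- data$map
  R <- length(map$regions)
  scale <- control$covariate_scale
  d <- exp(params$log_delta)
  ll <- 0
  for (j in 1:2) for (i in seq_len(R)) {
    lp <- params$alpha[j]
    for (k in seq_along(params$covariates))
      lp <- lp + params$b[j, k] * data$x[j, i, k] * scale
    phi_i <- params$ush[i] + params$ssh[i]
    if (j == 1) {
      lp <- lp + phi_i * d + params$bind[1, i] + params$bspat[1, i]
    } else {
      lp <- lp + phi_i / d + params$gamma_contrast[i] +
        params$bind[2, i] + params$bspat[2, i]
    }
    p <- 1 / (1 + exp(-lp))
    if (data$n[j, i] > 0)
      ll <- ll + lchoose(data$n[j, i], data$O[j, i]) +
        data$O[j, i] * log(p) + (data$n[j, i] - data$O[j, i]) * log(1 - p)
  }
  # priors, term by term
  C <- map$n_components
  qf <- function(v) {
    q <- 0
    for (e in seq_len(nrow(map$edges)))
      q <- q + (v[map$edges[e, 1]] - v[map$edges[e, 2]])^2
    q
  }
  car_t <- function(v, tau)
    (R - C) / 2 * (log(tau) - log(2 * pi)) - tau / 2 * qf(v)
  iid_t <- function(v, tau) {
    s <- 0
    for (vi in v)
      s <- s - 0.5 * log(2 * pi) + 0.5 * log(tau) - tau * vi^2 / 2
    s
  }
  lpr <- car_t(params$ssh, params$tau[["tau_ssh"]]) +
    car_t(params$bspat[1, ], params$tau[["tau_bspat_male"]]) +
    car_t(params$bspat[2, ], params$tau[["tau_bspat_female"]]) +
    car_t(params$gamma_contrast, params$tau[["tau_gamma"]]) +
    iid_t(params$ush, params$tau[["tau_ush"]]) +
    iid_t(params$bind[1, ], params$tau[["tau_bind_male"]]) +
    iid_t(params$bind[2, ], params$tau[["tau_bind_female"]])
  for (t in params$tau)
    lpr <- lpr + priors$precision_shape * log(priors$precision_rate) -
      lgamma(priors$precision_shape) +
      (priors$precision_shape - 1) * log(t) - priors$precision_rate * t
  v <- priors$log_delta_variance
  lpr <- lpr - 0.5 * log(2 * pi * v) - params$log_delta^2 / (2 * v)
  unname(ll + lpr)
}

# effective sample size from the empirical ACF (initial positive sequence)
ess <- function(x) {
  a <- autocorrelation(x, max_lag = min(200, length(x) - 1))[-1]
  neg <- which(a < 0)
  if (length(neg)) a <- a[seq_len(neg[1] - 1)]
  length(x) / (1 + 2 * sum(a))
}

mcse_mean <- function(x) sd(x) / sqrt(ess(x))

# quick sampler settings for tests that only need a rough posterior
quick_control <- function(seed = 1, burn_in = 1500, iterations = 1500,
                          thin = 3, n_chains = 2) {
  mcmc_control(n_chains = n_chains, burn_in = burn_in,
               iterations = iterations, thin = thin, seed = seed)
}

# subject records engineered to a given cases/denominator split in one cell
engineered_records <- function(n_male, cases_male, age = 50) {
  data.frame(region = "A", gender = "male", age = age,
             bmi = 22, waist = 75, height = 165, smoking = "never",
             alcohol = "never", sleep_night = 7, nap = 20,
             hypertension = rep(c(1L, 0L), c(cases_male, n_male - cases_male)),
             stringsAsFactors = FALSE)
}
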