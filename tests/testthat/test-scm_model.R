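test_that("linear predictor reproduces hand evaluation of the model equations", {
  m3 <- path_map3()
  d <- scm_data(m3, O = matrix(1, 2, 3), n = matrix(10, 2, 3))

  # all-zero state: p = 0.5 everywhere
  p0 <- linear_predictor(scm_params(m3), d)
  expect_true(all(p0 == 0.5))

  # delta = 1 with no specific terms: the gender predictors coincide
  pars <- scm_params(m3, ush = c(0.4, -0.1, -0.3), ssh = c(0.2, 0, -0.2),
                     log_delta = 0)
  p1 <- linear_predictor(pars, d)
  expect_equal(p1[1, ], p1[2, ])

  # 3-region toy against scalar hand arithmetic
  st <- random_state(m3, K = 2, seed = 5)
  p <- linear_predictor(st$params, st$data)
  for (j in 1:2) for (i in 1:3) {
    lp <- st$params$alpha[j] +
      sum(st$params$b[j, ] * st$data$x[j, i, ] * 100) +
      (st$params$ush[i] + st$params$ssh[i]) *
        exp(st$params$log_delta)^(ifelse(j == 1, 1, -1)) +
      (if (j == 2) st$params$gamma_contrast[i] else 0) +
      st$params$bind[j, i] + st$params$bspat[j, i]
    expect_equal(unname(p[j, i]), unname(1 / (1 + exp(-lp))),
                 tolerance = 1e-12)
  }

  bad <- st$params
  bad$alpha[1] <- NaN
  expect_error(linear_predictor(bad, st$data), "non-finite")
})

test_that("log likelihood equals a brute-force binomial sum and stays finite", {
  m3 <- path_map3()
  # single-cell closed form: O=1, n=2, p=0.5 -> log(0.5)
  m1 <- suppressWarnings(region_map("A"))
  d1 <- scm_data(m1, O = matrix(c(1, 0), 2, 1), n = matrix(c(2, 0), 2, 1))
  expect_equal(scm_log_likelihood(scm_params(m1), d1), log(0.5))

  for (s in 1:5) {
    st <- random_state(m3, K = 2, seed = 20 + s)
    p <- linear_predictor(st$params, st$data)
    ll_oracle <- 0
    for (j in 1:2) for (i in 1:3)
      ll_oracle <- ll_oracle + lchoose(st$data$n[j, i], st$data$O[j, i]) +
        st$data$O[j, i] * log(p[j, i]) +
        (st$data$n[j, i] - st$data$O[j, i]) * log(1 - p[j, i])
    expect_equal(scm_log_likelihood(st$params, st$data), ll_oracle,
                 tolerance = 1e-12)
  }

  # extreme linear predictors: clipped, large negative but finite
  extreme <- scm_params(m3, alpha = c(60, -60))
  d <- scm_data(m3, O = matrix(5, 2, 3), n = matrix(10, 2, 3))
  ll <- scm_log_likelihood(extreme, d)
  expect_true(is.finite(ll))
  expect_lt(ll, -100)
})

test_that("log prior matches a term-by-term oracle and CAR invariances hold", {
  m3 <- path_map3()
  priors <- scm_priors()

  # all components zero, unit precisions, log_delta 0: hand-computable value
  p0 <- scm_params(m3)
  R <- 3; C <- 1
  hand <- 4 * ((R - C) / 2 * (log(1) - log(2 * pi))) +    # four CAR terms
    3 * sum(dnorm(numeric(3), 0, 1, log = TRUE)) +        # ush, bind x2
    7 * dgamma(1, 1, rate = 1e-4, log = TRUE) +
    dnorm(0, 0, sqrt(0.169), log = TRUE)
  expect_equal(scm_log_prior(p0, priors, m3), hand, tolerance = 1e-12)

  # doubling tau_ssh with nonzero ssh changes the CAR exponent linearly
  ps <- scm_params(m3, ssh = c(1, -1, 0))
  Q <- car_quadratic_form(ps$ssh, m3)
  tau2 <- ps$tau; tau2["tau_ssh"] <- 2
  ps2 <- scm_params(m3, ssh = c(1, -1, 0), tau = tau2)
  diff_expected <- (R - C) / 2 * log(2) - (2 - 1) / 2 * Q +
    dgamma(2, 1, rate = 1e-4, log = TRUE) - dgamma(1, 1, rate = 1e-4, log = TRUE)
  expect_equal(scm_log_prior(ps2, priors, m3) - scm_log_prior(ps, priors, m3),
               diff_expected, tolerance = 1e-10)

  # intrinsic invariance: shifting before re-centering leaves the prior alone
  shifted <- scm_params(m3, ssh = c(1, -1, 0) + 5)  # constructor re-centers
  expect_equal(scm_log_prior(shifted, priors, m3),
               scm_log_prior(ps, priors, m3), tolerance = 1e-12)

  bad <- ps
  bad$tau["tau_ush"] <- -1
  expect_error(scm_log_prior(bad, priors, m3), "precision")
})

test_that("log posterior equals the independent full-formula oracle", {
  priors <- scm_priors()
  maps <- list(path_map3(), zhejiang_map())
  for (mi in seq_along(maps)) {
    for (s in 1:4) {
      st <- random_state(maps[[mi]], K = 2, seed = 40 + 10 * mi + s)
      lp <- scm_log_posterior(st$params, st$data, priors)
      expect_equal(lp, oracle_log_posterior(st$params, st$data, priors),
                   tolerance = 1e-10)
      expect_equal(lp, scm_log_likelihood(st$params, st$data) +
                     scm_log_prior(st$params, priors, st$data$map))
    }
  }
})

test_that("variance fractions and component SDs follow the variance convention", {
  m3 <- path_map3()
  # shared-only state: eta = 1 for both genders
  ps <- scm_params(m3, ush = c(1, -1, 0))
  expect_equal(unname(variance_fractions(ps)), c(1, 1))
  # constant shared component (centered to zero), nonzero specifics: eta = 0
  ps0 <- scm_params(m3, bind = rbind(c(1, -1, 0), c(0.5, 0, -0.5)))
  expect_equal(unname(variance_fractions(ps0)), c(0, 0))
  # hand case: phi = (1,-1,0), delta = 1, upsilon1 = (0.5,-0.5,0) -> 0.8
  ps8 <- scm_params(m3, ush = c(1, -1, 0),
                    bind = rbind(c(0.5, -0.5, 0), c(0, 0, 0)))
  expect_equal(unname(variance_fractions(ps8)["male"]), 0.8)
  # degenerate all-zero state: defined as 0 with a flag
  z <- variance_fractions(scm_params(m3))
  expect_equal(as.numeric(z), c(0, 0))
  expect_true(isTRUE(attr(z, "degenerate")))

  # population-variance convention: ssh = (1,-1,0) -> sd sqrt(2/3)
  sds <- component_sds(scm_params(m3, ssh = c(1, -1, 0)))
  expect_equal(unname(sds["sigma_str"]), sqrt(2 / 3))
  # sample convention switch gives the n-1 denominator instead
  sds_s <- component_sds(scm_params(m3, ssh = c(1, -1, 0)),
                         scm_control(variance_convention = "sample"))
  expect_equal(unname(sds_s["sigma_str"]), 1)
  # scaling a component scales its SD
  expect_equal(unname(component_sds(scm_params(m3, ssh = c(3, -3, 0)))["sigma_str"]),
               3 * sqrt(2 / 3))
  # eta stays in [0,1] across random states
  for (s in 1:10) {
    st <- random_state(m3, seed = 60 + s)
    e <- variance_fractions(st$params)
    expect_true(all(e >= 0 & e <= 1))
  }
})

test_that("gender swap with delta inversion preserves the likelihood at zero contrast", {
  m <- zhejiang_map()
  for (s in 1:4) {
    st <- random_state(m, K = 2, seed = 80 + s)
    pars <- st$params
    pars$gamma_contrast[] <- 0
    ll <- scm_log_likelihood(pars, st$data)
    # swap genders everywhere and negate log delta
    sw <- pars
    sw$alpha <- rev(pars$alpha)
    sw$b <- pars$b[2:1, , drop = FALSE]
    sw$bind <- pars$bind[2:1, ]
    sw$bspat <- pars$bspat[2:1, ]
    sw$log_delta <- -pars$log_delta
    dimnames(sw$b) <- dimnames(pars$b)
    dimnames(sw$bind) <- dimnames(pars$bind)
    dimnames(sw$bspat) <- dimnames(pars$bspat)
    dsw <- st$data
    dsw$O <- st$data$O[2:1, ]
    dsw$n <- st$data$n[2:1, ]
    dsw$x <- st$data$x[2:1, , , drop = FALSE]
    dimnames(dsw$O) <- dimnames(st$data$O)
    dimnames(dsw$n) <- dimnames(st$data$n)
    dimnames(dsw$x) <- dimnames(st$data$x)
    expect_equal(scm_log_likelihood(sw, dsw), ll, tolerance = 1e-10)
    # the two gender weights multiply to 1 by construction
    expect_equal(exp(pars$log_delta) * exp(-pars$log_delta), 1)
  }
})

test_that("imputation attaches moment-matched priors and substitutes averaged counts", {
  m3 <- path_map3()
  x <- array(c(0.2, 0.2, 0.4, 0.4, NA, 0.3), dim = c(2, 3, 1))
  d <- scm_data(m3, O = matrix(2, 2, 3), n = matrix(10, 2, 3), x = x,
                covariates = "v1")
  imp <- impute_missing(d)
  # observed values (0.2, 0.2, 0.4, 0.4, 0.3): the flagged entry gets the
  # pooled moments
  expect_equal(imp$imputation$mean, 0.3)
  expect_equal(imp$imputation$var, 0.01)
  expect_equal(imp$x[1, 3, 1], 0.3)
  # two observed values (0.2, 0.4) give Normal(0.3, 0.02)
  x2 <- array(c(0.2, NA, 0.4, NA, NA, NA), dim = c(2, 3, 1))
  d2 <- scm_data(m3, O = matrix(2, 2, 3), n = matrix(10, 2, 3), x = x2,
                 covariates = "v1")
  imp2 <- impute_missing(d2)
  expect_equal(unique(imp2$imputation$mean), 0.3)
  expect_equal(unique(imp2$imputation$var), 0.02, tolerance = 1e-12)

  # no flags: identity
  d3 <- scm_data(m3, O = matrix(2, 2, 3), n = matrix(10, 2, 3))
  expect_identical(impute_missing(d3)$O, d3$O)

  # substituted region gets rounded across-region averages
  d4 <- scm_data(m3, O = rbind(c(10, 15, 0), c(8, 9, 0)),
                 n = rbind(c(40, 51, 0), c(30, 45, 0)), substituted = "C")
  s4 <- impute_missing(d4)
  expect_equal(unname(s4$O[, 3]), c(round(12.5 + 1e-9), 9))  # half-up: 13, 9
  expect_equal(unname(s4$n[, 3]), c(46, 38))                 # 45.5 -> 46
  expect_equal(unname(s4$O[, 1:2]), unname(d4$O[, 1:2]))

  # a covariate missing everywhere is an input error
  xall <- array(NA_real_, dim = c(2, 3, 1))
  dall <- scm_data(m3, O = matrix(1, 2, 3), n = matrix(5, 2, 3), x = xall,
                   covariates = "v1")
  expect_error(impute_missing(dall), "missing in all regions")
})

test_that("posterior covariate RRs follow the lognormal closed form", {
  m3 <- path_map3()
  d <- scm_data(m3, O = matrix(1, 2, 3), n = matrix(4, 2, 3),
                x = array(0.5, c(2, 3, 1)), covariates = "v1")
  fake <- function(bdraws) {
    cols <- spscm:::scm_param_names(d)
    mat <- matrix(0, length(bdraws), length(cols),
                  dimnames = list(NULL, cols))
    mat[, "b_male_v1"] <- bdraws
    structure(list(chains = list(mat),
                   derived = list(matrix(0, length(bdraws), 0)),
                   p = list(), deviance = list()),
              class = "scm_samples")
  }
  # all draws zero: RR exactly 1 with a degenerate interval at 1
  z <- covariate_rr(fake(rep(0, 100)), "v1", "male")
  expect_equal(unname(z), c(1, 1, 1))
  # normal draws: posterior mean matches exp(mu + sigma^2/2)
  set.seed(9)
  mu <- 0.03; sig <- 0.01
  rr <- covariate_rr(fake(rnorm(40000, mu, sig)), "v1", "male")
  expect_equal(unname(rr["mean"]), exp(mu + sig^2 / 2), tolerance = 1e-3)
  expect_equal(unname(rr["lower"]), exp(mu - 1.96 * sig), tolerance = 1e-3)
  expect_error(covariate_rr(fake(numeric(0)), "v1", "male"), "empty")
  expect_error(covariate_rr(fake(0), "nope", "male"), "no sampled")
})
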