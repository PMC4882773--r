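test_that("seeded runs are bit-reproducible and seeds matter", {
  m <- path_map3()
  st <- random_state(m, K = 1, seed = 3)
  ctl <- quick_control(seed = 10, burn_in = 300, iterations = 300, thin = 3)
  f1 <- suppressWarnings(run_mcmc(st$data, control = ctl))
  f2 <- suppressWarnings(run_mcmc(st$data, control = ctl))
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
  ctl$seed <- 11L
  f3 <- suppressWarnings(run_mcmc(st$data, control = ctl))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("the degenerate one-region posterior matches the conjugate closed form", {
  # one region: sum-to-zero pins every spatial/specific component at zero,
  # leaving only the flat-prior intercepts. A flat prior on alpha = logit(p)
  # with O = 7 of n = 10 gives p ~ Beta(7, 3) exactly.
  m1 <- suppressWarnings(region_map("A"))
  d1 <- scm_data(m1, O = matrix(c(7, 7), 2, 1), n = matrix(c(10, 10), 2, 1))
  fit <- suppressWarnings(run_mcmc(
    d1, control = mcmc_control(burn_in = 3000, iterations = 16000, thin = 2,
                               seed = 2)))
  p <- do.call(rbind, fit$p)
  m_true <- 7 / 10
  sd_true <- sqrt(7 * 3 / (10^2 * 11))
  for (j in 1:2) {
    se <- mcse_mean(p[, j])
    expect_lt(abs(mean(p[, j]) - m_true), 3 * se)
    # sd of the posterior: MC error of a sample sd is roughly sd/sqrt(2*ess)
    se_sd <- sd_true / sqrt(2 * ess(p[, j]))
    expect_lt(abs(sd(p[, j]) - sd_true), 3 * se_sd)
  }
  # every component draw honors the sum-to-zero degeneracy
  expect_true(all(abs(fit$chains[[1]][, "ssh_A"]) < 1e-12))

  # effective parameters: closed-form pD for the Beta(7,3) posterior,
  # 2 * { E[D] - D(pbar) } per gender via digamma identities
  pD_g <- -2 * (7 * (digamma(7) - digamma(10)) +
                  3 * (digamma(3) - digamma(10))) +
    2 * (7 * log(0.7) + 3 * log(0.3))
  ic <- dic(fit)
  expect_lt(abs(ic$pD - 2 * pD_g), 0.35)
  expect_gt(ic$pD, 0)
})

test_that("a prior-only run recovers the log-delta prior spread", {
  m1 <- suppressWarnings(region_map("A"))
  d0 <- scm_data(m1, O = matrix(0, 2, 1), n = matrix(0, 2, 1))
  fit <- suppressWarnings(run_mcmc(
    d0, control = mcmc_control(burn_in = 2000, iterations = 16000, thin = 2,
                               seed = 3)))
  ld <- pooled_draws(fit)[, "log_delta"]
  target <- sqrt(0.169)
  se_sd <- target / sqrt(2 * ess(ld))
  expect_lt(abs(sd(ld) - target), 3 * se_sd)
  expect_lt(abs(mean(ld)), 3 * mcse_mean(ld))
})

test_that("split R-hat separates converged from divergent chains", {
  set.seed(5)
  mk <- function(center) {
    m <- matrix(rnorm(4000, center), ncol = 1)
    colnames(m) <- "theta"
    m
  }
  same <- bgr_diagnostic(list(mk(0), mk(0)), "theta")
  expect_lt(same, 1.01)
  apart <- bgr_diagnostic(list(mk(0), mk(10)), "theta")
  expect_gt(apart, 1.1)
  const <- list(matrix(1, 100, 1, dimnames = list(NULL, "theta")),
                matrix(1, 100, 1, dimnames = list(NULL, "theta")))
  rc <- bgr_diagnostic(const, "theta")
  expect_equal(as.numeric(rc), 1)
  expect_equal(attr(rc, "degenerate"), "theta")
  expect_error(bgr_diagnostic(list(mk(0)), "theta"), "two chains")
})

test_that("autocorrelation matches process oracles", {
  set.seed(6)
  wn <- rnorm(10000)
  a <- autocorrelation(wn, 5)
  expect_equal(a[1], 1)
  expect_lt(abs(a[2]), 0.05)
  # AR(1) with coefficient 0.5
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 20000))
  expect_equal(autocorrelation(x, 3)[2], 0.5, tolerance = 0.05)
  expect_warning(z <- autocorrelation(rep(2, 100), 5), "zero-variance")
  expect_true(all(is.na(z)))
  expect_error(autocorrelation(1:5, 10))
})

test_that("DIC collapses to the plug-in deviance for a point-mass posterior", {
  m <- path_map3()
  st <- random_state(m, K = 0, seed = 8)
  fit <- suppressWarnings(run_mcmc(st$data, control = quick_control(
    seed = 4, burn_in = 400, iterations = 200, thin = 2)))
  # freeze every retained draw of every chain at one state: point mass
  for (ch in seq_along(fit$chains)) {
    fit$chains[[ch]] <- fit$chains[[1]][rep(1, 50), ]
    fit$p[[ch]] <- fit$p[[1]][rep(1, 50), ]
    fit$deviance[[ch]] <- rep(fit$deviance[[1]][1], 50)
  }
  ic <- dic(fit)
  expect_equal(ic$pD, 0, tolerance = 1e-8)
  expect_equal(ic$DIC, fit$deviance[[1]][1], tolerance = 1e-8)
})

test_that("sensitivity runs are reproducible and exclusions reindex cleanly", {
  m <- zhejiang_map()
  gen <- generate_regional(m, n_per_cell = c(male = 40, female = 40),
                           seed = 12)
  ctl <- quick_control(seed = 7, burn_in = 600, iterations = 600, thin = 6)
  # identical priors listed twice with the same seeds give identical rows
  comp <- suppressWarnings(sensitivity_run(
    gen$data, list(a = scm_priors(), b = scm_priors()), ctl))
  ra <- comp[comp$prior == "a", c("parameter", "mean", "lower", "upper")]
  rb <- comp[comp$prior == "b", c("parameter", "mean", "lower", "upper")]
  rownames(ra) <- rownames(rb) <- NULL
  expect_identical(ra, rb)

  # excluding a region drops it from all structures
  red <- exclude_region(gen$data, "Zhoushan")
  expect_length(red$map$regions, 10L)
  expect_false("Zhoushan" %in% red$map$regions)
  expect_equal(ncol(red$O), 10L)
  expect_equal(dim(red$x)[2], 10L)
  expect_false(any(red$map$edges > 10L))
  # Zhoushan's only link was to Ningbo, so one edge disappears
  expect_equal(nrow(red$map$edges), nrow(gen$data$map$edges) - 1L)
  expect_error(exclude_region(gen$data, "Atlantis"), "unknown region")
})

test_that("acceptance-rate pathologies trigger the warning channel", {
  # a prior-only run accepts flat-prior proposals almost always
  m1 <- suppressWarnings(region_map("A"))
  d0 <- scm_data(m1, O = matrix(0, 2, 1), n = matrix(0, 2, 1))
  expect_warning(
    run_mcmc(d0, control = mcmc_control(burn_in = 200, iterations = 200,
                                        thin = 2, seed = 1)),
    "acceptance")
})
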