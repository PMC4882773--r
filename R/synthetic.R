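# Synthetic-data generator: regional and individual-level data with the
# statistical structure the SCM assumes, plus the parameter-recovery harness.
# This module stands in for the study's non-public survey microdata.

#' Default generating truth
#'
#' A parameter state at the magnitudes the motivating application reports:
#' per-percentage-point covariate log-RRs of roughly -0.075 to +0.034
#' (elderly, obese and apple-shape proportions), a shared-component weight
#' delta of 1.094, component precisions giving component SDs near 0.017-0.018
#' on the log-odds scale, and intercepts placed so the marginal prevalences at
#' mid-range covariates are about 30.6 percent (males) and 35.5 percent
#' (females). Region-indexed components are zero here; [generate_regional()]
#' draws them from their priors at these precisions.
#'
#' @param map a [region_map].
#' @param model an [scm_control]; coefficients are expressed per scaled
#'   covariate unit.
#' @return an [scm_params] state with covariates `elderly`, `obese`, `whtr`.
#' @export
default_truth <- function(map, model = scm_control()) {
  covs <- c("elderly", "obese", "whtr")
  # log-RR per percentage point, rescaled if the covariate scale differs
  b_pp <- rbind(male = log(c(0.965, 0.928, 1.035)),
                female = log(c(1.012, 1.019, 1.020)))
  b <- b_pp * 100 / model$covariate_scale
  mid <- c(elderly = 0.5, obese = 0.09, whtr = 0.7) * model$covariate_scale
  alpha <- qlogis(c(0.306, 0.355)) - as.numeric(b %*% mid)
  tau_spat <- 1 / 0.018^2
  tau_iid <- 1 / 0.017^2
  scm_params(map, covs, alpha = alpha, b = b, log_delta = log(1.094),
             tau = setNames(c(tau_spat, tau_spat, tau_spat, tau_spat,
                              tau_iid, tau_iid, tau_iid), TAU_NAMES))
}

#' Draw an intrinsic CAR field
#'
#' Zero-mean Gaussian field with precision `tau * L` (L the graph Laplacian)
#' restricted to the sum-to-zero subspace — i.e. covariance equal to the
#' Laplacian pseudo-inverse over `tau`, the unique proper distribution
#' consistent with the improper intrinsic CAR density used in fitting. On a
#' disconnected map each component is handled separately (centered within
#' itself) with a warning.
#'
#' @param map a [region_map].
#' @param tau positive precision.
#' @return length-R named vector summing to zero (per component).
#' @export
car_draw <- function(map, tau) {
  stopifnot(tau > 0)
  R <- length(map$regions)
  if (R < 2) return(setNames(numeric(R), map$regions))
  if (map$n_components > 1)
    warning("map is disconnected; CAR field drawn per connected component")
  eig <- eigen(laplacian(map), symmetric = TRUE)
  pos <- eig$values > 1e-8 * max(eig$values, 1)
  z <- rnorm(sum(pos), 0, 1 / sqrt(eig$values[pos] * tau))
  setNames(as.numeric(eig$vectors[, pos, drop = FALSE] %*% z), map$regions)
}

#' Generate regional SCM data from a generating truth
#'
#' Covariates are drawn uniformly within `ranges` (defaults echoing the
#' magnitudes observed in the motivating cohort: elderly proportion 0.30-0.70,
#' obese 0.03-0.15, apple-shape 0.50-0.90), structured components from the
#' intrinsic CAR at the truth's precisions, unstructured components i.i.d.
#' normal then centered; cell probabilities come from [linear_predictor()]
#' and case counts from a binomial draw. Deterministic under `seed`.
#'
#' @param map a [region_map].
#' @param truth an [scm_params] state supplying fixed effects, log-delta and
#'   precisions (its component values are ignored; fresh fields are drawn).
#' @param n_per_cell denominators: a scalar, a length-2 vector (male,
#'   female), or a full 2 x R matrix. The default (55, 60) mirrors the
#'   motivating survey's roughly 1265 subjects over 11 regions x 2 genders.
#' @param seed integer seed.
#' @param ranges named list of length-2 covariate ranges.
#' @param model an [scm_control].
#' @return list with elements `data` (an [scm_data]) and `truth` (class
#'   `scm_truth`: the realized full parameter state plus the generator
#'   config).
#' @export
generate_regional <- function(map, truth = default_truth(map, model),
                              n_per_cell = c(male = 55, female = 60),
                              seed = 1,
                              ranges = list(elderly = c(0.30, 0.70),
                                            obese = c(0.03, 0.15),
                                            whtr = c(0.50, 0.90)),
                              model = scm_control()) {
  stopifnot(inherits(map, "region_map"), inherits(truth, "scm_params"))
  R <- length(map$regions)
  covs <- truth$covariates
  set.seed(as.integer(seed))

  x <- array(NA_real_, dim = c(2, R, length(covs)),
             dimnames = list(GENDERS, map$regions, covs))
  for (k in seq_along(covs)) {
    rg <- ranges[[covs[k]]]
    if (is.null(rg)) stop("no range configured for covariate '", covs[k], "'")
    if (rg[1] < 0 || rg[2] > 1 || rg[1] >= rg[2])
      stop("invalid range for covariate '", covs[k], "'")
    x[, , k] <- runif(2 * R, rg[1], rg[2])
  }

  iid_draw <- function(tau) {
    v <- rnorm(R, 0, 1 / sqrt(tau))
    setNames(v - mean(v), map$regions)
  }
  params <- scm_params(
    map, covs, alpha = truth$alpha, b = truth$b,
    log_delta = truth$log_delta,
    ush = iid_draw(truth$tau["tau_ush"]),
    ssh = car_draw(map, truth$tau["tau_ssh"]),
    bind = rbind(iid_draw(truth$tau["tau_bind_male"]),
                 iid_draw(truth$tau["tau_bind_female"])),
    bspat = rbind(car_draw(map, truth$tau["tau_bspat_male"]),
                  car_draw(map, truth$tau["tau_bspat_female"])),
    gamma_contrast = car_draw(map, truth$tau["tau_gamma"]),
    tau = truth$tau)

  if (is.matrix(n_per_cell)) {
    n <- matrix(n_per_cell, 2, R)
  } else if (length(n_per_cell) == 2L) {
    n <- matrix(rep(n_per_cell, R), 2, R)
  } else {
    n <- matrix(n_per_cell, 2, R)
  }
  storage.mode(n) <- "double"
  if (any(n <= 0)) stop("n_per_cell must be positive")

  dat <- scm_data(map, O = matrix(0, 2, R), n = n, x = x, covariates = covs)
  p <- linear_predictor(params, dat, model)
  O <- matrix(0, 2, R)
  for (j in 1:2) O[j, ] <- rbinom(R, as.integer(n[j, ]), p[j, ])
  dat$O <- matrix(as.numeric(O), 2, R, dimnames = dimnames(dat$O))

  truth_rec <- structure(list(params = params, p = p,
                              config = list(n_per_cell = n, ranges = ranges,
                                            seed = seed,
                                            covariate_scale =
                                              model$covariate_scale)),
                         class = "scm_truth")
  list(data = dat, truth = truth_rec)
}

#' Generate individual-level records consistent with regional data
#'
#' For every (gender, region) cell, draws `n[j,i]` subjects whose covariates
#' match the cell's regional proportions in expectation — age band from the
#' elderly proportion, BMI from the obesity proportion, waist/height from the
#' apple-shape proportion, gender-typical smoking/alcohol prevalences, and
#' sleep/nap habits — and assigns exactly `O[j,i]` of them as hypertension
#' cases, so the individual file aggregates back to the regional file
#' exactly. Per-subject draws are independent given the cell proportions (no
#' within-subject correlation structure).
#'
#' @param data an [scm_data] produced by [generate_regional()] (covariates
#'   `elderly`, `obese`, `whtr`).
#' @param seed integer seed.
#' @param lifestyle per-gender current-smoking and current-drinking
#'   probabilities.
#' @return data frame of subject records (see [read_subjects()] schema).
#' @export
generate_individual <- function(data, seed = 1,
                                lifestyle = list(
                                  male = c(smoking = 0.704, alcohol = 0.315),
                                  female = c(smoking = 0.021, alcohol = 0.095))) {
  stopifnot(inherits(data, "scm_data"))
  needed <- c("elderly", "obese", "whtr")
  if (!all(needed %in% data$covariates))
    stop("individual-level generation needs covariates ",
         paste(needed, collapse = ", "))
  if (anyNA(data$x)) stop("missing covariates; impute or regenerate first")
  set.seed(as.integer(seed))
  rows <- list()
  for (j in 1:2) for (i in seq_along(data$map$regions)) {
    n <- as.integer(data$n[j, i])
    if (n == 0L) next
    g <- GENDERS[j]
    eld <- rbinom(n, 1, data$x[j, i, "elderly"]) == 1L
    old75 <- eld & (runif(n) < 0.25)
    age <- integer(n)
    age[!eld] <- sample(45:59, sum(!eld), replace = TRUE)
    age[eld & !old75] <- sample(60:74, sum(eld & !old75), replace = TRUE)
    age[old75] <- sample(75:90, sum(old75), replace = TRUE)
    obese <- rbinom(n, 1, data$x[j, i, "obese"]) == 1L
    bmi <- ifelse(obese, runif(n, 28, 34), runif(n, 17.5, 27.9))
    apple <- rbinom(n, 1, data$x[j, i, "whtr"]) == 1L
    height <- runif(n, 150, 178)
    ratio <- ifelse(apple, runif(n, 0.505, 0.68), runif(n, 0.40, 0.50))
    waist <- ratio * height
    ls <- lifestyle[[g]]
    smoking <- ifelse(runif(n) < ls["smoking"], "current", "never")
    alcohol <- ifelse(runif(n) < ls["alcohol"], "current", "never")
    sleep <- pmin(pmax(round(rnorm(n, 7, 1), 1), 4), 10)
    nap <- pmax(round(rnorm(n, if (g == "male") 40.8 else 28.9, 15)), 0)
    hyp <- integer(n)
    hyp[sample.int(n, as.integer(data$O[j, i]))] <- 1L
    rows[[length(rows) + 1L]] <- data.frame(
      region = data$map$regions[i], gender = g, age = age,
      bmi = round(bmi, 1), waist = round(waist, 1),
      height = round(height, 1), smoking = smoking, alcohol = alcohol,
      sleep_night = sleep, nap = nap, hypertension = hyp,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates regional data from a fixed truth, fits the model, and
#' records whether each true fixed-effect coefficient and delta lies inside
#' its central 95 percent credible interval. Replicates whose fixed-effect or
#' log-delta split R-hat exceeds 1.1 are excluded from coverage and counted.
#'
#' @param map a [region_map].
#' @param truth generating [scm_params].
#' @param n_per_cell denominator per cell (larger than survey scale by
#'   default: regional estimates at survey-scale denominators are imprecise).
#' @param n_reps number of replicates.
#' @param priors an [scm_priors].
#' @param control an [mcmc_control] (reduced chain lengths are adequate at
#'   these cell sizes).
#' @param model an [scm_control].
#' @param seed integer base seed; replicate r uses `seed + r` for data and
#'   `seed + 10000 + r` for the sampler.
#' @return data frame of class `scm_recovery`: one row per monitored
#'   parameter with `truth`, `mean_estimate`, `mean_bias`, `coverage`,
#'   `n_converged`, `n_reps`.
#' @export
recovery_experiment <- function(map, truth = default_truth(map, model),
                                n_per_cell = 500, n_reps = 20,
                                priors = scm_priors(),
                                control = mcmc_control(burn_in = 4000,
                                                       iterations = 4000,
                                                       thin = 4),
                                model = scm_control(), seed = 1) {
  stopifnot(n_reps >= 1)
  K <- length(truth$covariates)
  pars <- c(paste0("b_male_", truth$covariates),
            paste0("b_female_", truth$covariates), "delta")
  true_vals <- c(truth$b[1, ], truth$b[2, ], exp(truth$log_delta))
  names(true_vals) <- pars
  hits <- matrix(NA, n_reps, length(pars), dimnames = list(NULL, pars))
  ests <- matrix(NA_real_, n_reps, length(pars), dimnames = list(NULL, pars))
  converged <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    gen <- generate_regional(map, truth, n_per_cell = n_per_cell,
                             seed = seed + r, model = model)
    ctl <- control
    ctl$seed <- as.integer(seed + 10000 + r)
    fit <- run_mcmc(gen$data, priors, ctl, model)
    monitor <- c("alpha_male", "alpha_female",
                 paste0("b_male_", truth$covariates),
                 paste0("b_female_", truth$covariates), "log_delta")
    rh <- if (length(fit$chains) >= 2)
      suppressWarnings(bgr_diagnostic(fit, monitor)) else 1
    converged[r] <- all(is.finite(rh)) && max(rh) <= 1.1
    pooled <- pooled_draws(fit)
    for (pn in pars) {
      dr <- pooled[, pn]
      ci <- quantile(dr, c(0.025, 0.975))
      hits[r, pn] <- true_vals[pn] >= ci[1] && true_vals[pn] <= ci[2]
      ests[r, pn] <- mean(dr)
    }
  }
  use <- converged
  out <- data.frame(
    parameter = pars, truth = true_vals,
    mean_estimate = colMeans(ests[use, , drop = FALSE]),
    mean_bias = colMeans(ests[use, , drop = FALSE]) - true_vals,
    coverage = if (any(use)) colMeans(hits[use, , drop = FALSE]) else NA_real_,
    n_converged = sum(use), n_reps = n_reps, row.names = NULL)
  class(out) <- c("scm_recovery", "data.frame")
  out
}
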